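#' Akaike information criterion
#'
#' `aic()` computes AIC = 2k - 2logL; `aicc()` adds the small-sample
#' correction 2k(k+1)/(n-k-1) and tends to AIC as `n` grows.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips for phylogenetic models).
#' @return A numeric scalar (vectorized over its arguments).
#' @examples
#' aic(-111.63, 8)   # 239.26
#' aicc(-151.01, 2, 54)
#' @export
aic <- function(loglik, k) {
  2 * k - 2 * loglik
}

#' @rdname aic
#' @export
aicc <- function(loglik, k, n) {
  if (any(n - k - 1 <= 0)) {
    abort("AICc undefined: need n > k + 1.")
  }
  aic(loglik, k) + 2 * k * (k + 1) / (n - k - 1)
}

#' Model-comparison table with delta-AIC and Akaike weights
#'
#' Takes one row per candidate model and appends `aic` (or `aicc` when `n` is
#' supplied), `delta` (difference to the best model) and `weight` (Akaike
#' weight, normalized to sum to one). Ties on the information criterion are
#' broken in favour of the model with fewer parameters when flagging the best
#' model.
#'
#' @param rows A data frame with at least columns `model`, `n_params`,
#'   `loglik`. Extra columns are carried through.
#' @param n Optional sample size; when given, AICc is used instead of AIC.
#' @param criterion Column name to rank on, `"aic"` (default) or `"aicc"`.
#' @return A tibble sorted by the criterion, with columns `aic` (and `aicc`
#'   when `n` is given), `delta`, `weight`, `weight_pct` and logical `best`.
#' @export
akaike_table <- function(rows, n = NULL, criterion = if (is.null(n)) "aic" else "aicc") {
  rows <- as_tibble(rows)
  stopifnot(all(c("model", "n_params", "loglik") %in% names(rows)))
  rows$aic <- aic(rows$loglik, rows$n_params)
  if (!is.null(n)) {
    rows$aicc <- aicc(rows$loglik, rows$n_params, n)
  }
  crit <- rows[[criterion]]
  ok <- is.finite(crit)
  if (!any(ok)) abort("akaike_table(): no model has a finite criterion value.")
  rows$delta <- crit - min(crit[ok])
  w <- exp(-rows$delta / 2)
  w[!ok] <- 0
  rows$weight <- w / sum(w)
  rows$weight_pct <- 100 * rows$weight
  # best: smallest criterion, ties to fewer parameters
  ord <- order(rows$delta, rows$n_params)
  rows$best <- FALSE
  rows$best[ord[1]] <- TRUE
  rows[order(rows$delta, rows$n_params), , drop = FALSE]
}

#' Likelihood-ratio test between nested models
#'
#' @param loglik0 Log-likelihood of the restricted (null) model.
#' @param loglik1 Log-likelihood of the more general model; must be at least
#'   `loglik0` up to numerical noise.
#' @param df Difference in the number of free parameters.
#' @return A tibble with columns `statistic` (the chi-squared statistic
#'   2(logL1 - logL0)), `df` and `p_value`.
#' @examples
#' lrt(-100, -94, 3)  # statistic 12, p ~ 0.0073
#' @export
lrt <- function(loglik0, loglik1, df) {
  stat <- 2 * (loglik1 - loglik0)
  if (any(stat < -1e-6)) {
    abort("lrt(): loglik1 < loglik0 beyond tolerance; models are not nested or fits failed.")
  }
  stat <- pmax(stat, 0)
  tibble(
    statistic = stat,
    df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE)
  )
}
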