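#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a time/env birth-death fit table
#'
#' One row per fitted model with estimates and model-selection columns.
#'
#' @param x A `bd_fits` tibble from [fit_bd_family()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bd_fits <- function(x, ...) {
  as_tibble(x)[, c(
    "model", "n_params", "loglik", "aic", "delta", "weight",
    "lambda0", "alpha", "mu0", "beta"
  )]
}

#' @rdname tidy.bd_fits
#' @export
glance.bd_fits <- function(x, ...) {
  b <- x[x$best, ][1, ]
  tibble(
    best_model = b$model, loglik = b$loglik, aic = b$aic,
    weight = b$weight, n_models = nrow(x)
  )
}

#' Tidy an episodic shift-fit table
#'
#' @param x An `episodic_fits` tibble from [fit_shifts()].
#' @param ... Unused.
#' @return A tibble with one row per interval of each fitted shift count,
#'   carrying `rate` (net diversification), `turnover` and the interval's
#'   older boundary (`shift_time`, `NA` for the oldest interval).
#' @export
tidy.episodic_fits <- function(x, ...) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    st <- x$shift_times[[i]]
    tibble(
      model = x$model[i],
      n_shifts = x$n_shifts[i],
      interval = seq_len(x$n_shifts[i] + 1),
      rate = x$rates[[i]],
      turnover = x$turnovers[[i]],
      shift_time = c(st, NA_real_)
    )
  })
  bind_rows(rows)
}

#' @rdname tidy.episodic_fits
#' @export
glance.episodic_fits <- function(x, ...) {
  tibble(
    n_models = nrow(x),
    best_aic = min(x$aic),
    best_model = x$model[which.min(x$aic)]
  )
}

#' Tidy a diversity-dependent fit table
#'
#' @param x A `dd_fits` tibble from [fit_dd_family()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dd_fits <- function(x, ...) {
  as_tibble(x)[, c("model", "n_params", "loglik", "aic", "lambda0", "mu0", "K", "x")]
}

#' @rdname tidy.dd_fits
#' @export
glance.dd_fits <- function(x, ...) {
  b <- x[which.min(x$aic), ]
  tibble(best_model = b$model, loglik = b$loglik, aic = b$aic, n_models = nrow(x))
}

#' Tidy an SSE fit
#'
#' @param x An `sse_fit` from [fit_sse()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.sse_fit <- function(x, ...) {
  if (is.null(x$pars)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  lam_names <- switch(x$spec$dependence,
    ETD = paste0("lambda_", habitat_levels()),
    CTD = paste0("lambda_concealed", seq_len(x$spec$d)),
    CR = "lambda"
  )
  tibble(
    term = c(
      lam_names, "mu",
      paste0("q_examined", seq_along(x$pars$q_examined)),
      if (length(x$pars$q_concealed)) "q_concealed"
    ),
    estimate = c(x$pars$lambda, x$pars$mu, x$pars$q_examined, x$pars$q_concealed)
  )
}

#' @rdname tidy.sse_fit
#' @export
glance.sse_fit <- function(x, ...) {
  tibble(
    model = paste(x$spec$dependence, x$spec$inheritance, x$spec$structure, sep = "-"),
    n_params = x$n_params, loglik = x$loglik, aic = x$aic, aicc = x$aicc,
    converged = x$converged
  )
}
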