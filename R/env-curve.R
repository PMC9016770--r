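#' Build a continuous interpolator for a paleoenvironmental proxy curve
#'
#' Produces a continuous function of age (Ma before present) from sampled
#' proxy values. With `smooth_df` equal to the number of samples the curve
#' interpolates the samples exactly (natural cubic spline); smaller values
#' give a cubic smoothing spline with that many equivalent degrees of
#' freedom. Queries outside the sampled age range clamp to the boundary
#' values, so likelihoods never extrapolate a proxy.
#'
#' @param samples A data frame with columns `age_Ma` (strictly increasing)
#'   and `value`, or a two-column numeric matrix in that order.
#' @param smooth_df Equivalent degrees of freedom for smoothing; default
#'   `min(n_samples, 50)`. Values `>= n_samples` mean exact interpolation.
#' @return An object of class `env_curve`: callable as `curve(age)`, with
#'   fields `range` (sampled age range), `smooth_df`, and the original
#'   `samples` tibble.
#' @export
env_curve <- function(samples, smooth_df = NULL) {
  samples <- as.data.frame(samples)
  if (ncol(samples) < 2) abort("env_curve(): need two columns (age_Ma, value).")
  names(samples)[1:2] <- c("age_Ma", "value")
  age <- as.numeric(samples$age_Ma)
  val <- as.numeric(samples$value)
  if (length(age) < 2) abort("env_curve(): need at least 2 samples.")
  if (anyDuplicated(age)) abort("env_curve(): duplicate ages in samples.")
  if (is.unsorted(age, strictly = TRUE)) {
    ord <- order(age)
    age <- age[ord]
    val <- val[ord]
  }
  n <- length(age)
  if (is.null(smooth_df)) smooth_df <- min(n, 50)
  if (smooth_df >= n || n < 4) {
    base_fn <- splinefun(age, val, method = "natural")
  } else {
    sp <- smooth.spline(age, val, df = smooth_df)
    base_fn <- function(x) predict(sp, x)$y
  }
  lo <- age[1]
  hi <- age[n]
  fn <- function(t) {
    base_fn(pmin(pmax(t, lo), hi))
  }
  structure(
    list(
      fn = fn,
      range = c(lo, hi),
      smooth_df = smooth_df,
      samples = tibble(age_Ma = age, value = val)
    ),
    class = "env_curve"
  )
}

#' @export
print.env_curve <- function(x, ...) {
  cat(
    "<env_curve> ", nrow(x$samples), " samples on [",
    format(x$range[1]), ", ", format(x$range[2]), "] Ma, smooth_df = ",
    x$smooth_df, "\n",
    sep = ""
  )
  invisible(x)
}

# evaluate an env curve at ages t
eval_env <- function(env, t) {
  stopifnot(inherits(env, "env_curve"))
  env$fn(t)
}

#' Read a paleoenvironment CSV (columns `age_Ma,value`)
#'
#' @param path Path to a CSV file with a header line `age_Ma,value`.
#' @param smooth_df Passed to [env_curve()].
#' @return An `env_curve`.
#' @export
read_env_csv <- function(path, smooth_df = NULL) {
  df <- read.csv(path)
  if (!all(c("age_Ma", "value") %in% names(df))) {
    abort("Env CSV must have header columns 'age_Ma,value'.")
  }
  env_curve(df[, c("age_Ma", "value")], smooth_df = smooth_df)
}
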