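#' @importFrom ggplot2 autoplot
NULL

#' Lineage-through-time plot
#'
#' @param tree A validated ultrametric `phylo` (or a tibble from
#'   [ltt_points()]).
#' @param log_counts Plot the lineage count on a log scale (default TRUE).
#' @return A ggplot object.
#' @export
plot_ltt <- function(tree, log_counts = TRUE) {
  pts <- if (inherits(tree, "phylo")) ltt_points(tree) else tree
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = -.data$age, y = .data$n_lineages)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_x_continuous(labels = function(x) -x) +
    ggplot2::labs(x = "Age (Ma)", y = "Lineages") +
    ggplot2::theme_minimal()
  if (log_counts) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.env_curve <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = -.data$age_Ma, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) -x) +
    ggplot2::labs(x = "Age (Ma)", y = "Proxy value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectral_profile <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$log_eigenvalue, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "log eigenvalue", y = "Spectral density",
      subtitle = paste0("k* = ", object$k_star)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bd_fits <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$model, -.data$weight),
    y = .data$weight
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Rate-through-time curve of a fitted model row
#'
#' @param fits A `bd_fits` table.
#' @param model Model name (default: the best model).
#' @param ages Ages (Ma) at which to evaluate, descending from the crown.
#' @param env Env curve (required for env-family fits).
#' @return A tibble with `age`, `lambda`, `mu`, `net_div`.
#' @export
rate_through_time <- function(fits, model = NULL, ages, env = NULL) {
  fam <- attr(fits, "family") %||% "time"
  row <- if (is.null(model)) fits[fits$best, ][1, ] else fits[fits$model == model, ][1, ]
  lamk <- if (grepl("^bvar|^benv", row$model)) "exp" else "constant"
  muk <- if (row$model %in% c("yule", "bvar", "benv")) {
    "none"
  } else if (grepl("dvar$|denv$", row$model)) "exp" else "constant"
  driver <- if (fam == "env") {
    if (is.null(env)) abort("env curve required for env-family rates")
    function(t) eval_env(env, t)
  } else {
    function(t) t
  }
  lam <- if (lamk == "constant") {
    rep(row$lambda0, length(ages))
  } else {
    row$lambda0 * exp(row$alpha * driver(ages))
  }
  mu <- switch(muk,
    none = rep(0, length(ages)),
    constant = rep(row$mu0, length(ages)),
    exp = row$mu0 * exp(row$beta * driver(ages))
  )
  tibble(age = ages, lambda = lam, mu = mu, net_div = lam - mu)
}
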