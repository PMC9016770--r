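## Episodic (piecewise-constant) birth-death models with tree-wide shifts.
## Parameterized by per-interval net diversification r_i = lambda_i - mu_i
## and turnover eps_i = mu_i / lambda_i in [0, 1), present-to-past order,
## matching the "Rate" / "Turn" columns of standard episodic model tables.

#' Episodic birth-death model
#'
#' @param shift_times Ascending shift ages (Ma), strictly inside
#'   `(0, crown age)`; length `s` between 0 and 4.
#' @param rates Net diversification rates `r_i = lambda_i - mu_i` per
#'   interval (length `s + 1`, most recent interval first); must be > 0 so
#'   that `lambda_i = r_i / (1 - eps_i)` is positive.
#' @param turnovers Turnovers `eps_i = mu_i / lambda_i` in `[0, 1)`
#'   (length `s + 1`).
#' @param f Sampling fraction in (0, 1].
#' @return An `episodic_model` list with derived `lambda` and `mu` vectors.
#' @export
episodic_model <- function(shift_times, rates, turnovers, f = 1) {
  shift_times <- sort(as.numeric(shift_times))
  s <- length(shift_times)
  if (s > 0 && any(shift_times <= 0)) abort("Shift times must be positive ages.")
  if (length(rates) != s + 1 || length(turnovers) != s + 1) {
    abort("Need length(shift_times) + 1 rates and turnovers.")
  }
  if (any(rates <= 0)) abort("Net diversification rates must be > 0.")
  if (any(turnovers < 0 | turnovers >= 1)) abort("Turnovers must lie in [0, 1).")
  lambda <- rates / (1 - turnovers)
  mu <- lambda * turnovers
  structure(
    list(
      shift_times = shift_times, rates = rates, turnovers = turnovers,
      lambda = lambda, mu = mu, f = f, n_shifts = s
    ),
    class = "episodic_model"
  )
}

#' Convert between (rate, turnover) and (lambda, mu) parameterizations
#'
#' @param rates,turnovers Net diversification and turnover vectors.
#' @param lambda,mu Speciation and extinction vectors.
#' @return A tibble with both parameterizations.
#' @export
rt_to_lm <- function(rates, turnovers) {
  lambda <- rates / (1 - turnovers)
  tibble(rate = rates, turnover = turnovers, lambda = lambda, mu = lambda * turnovers)
}

#' @rdname rt_to_lm
#' @export
lm_to_rt <- function(lambda, mu) {
  tibble(lambda = lambda, mu = mu, rate = lambda - mu, turnover = mu / lambda)
}

# shared core: piecewise-constant likelihood from closed forms
episodic_loglik_core <- function(bt, shift_times, lambda, mu, f, conditioning) {
  crown <- bt[1]
  if (length(shift_times) && any(shift_times >= crown)) {
    abort("Shift times must lie strictly inside (0, crown age).")
  }
  bt_asc <- sort(bt)
  ei <- bd_piecewise_EI(bt_asc, shift_times, lambda, mu, f)
  if (any(!is.finite(ei$E)) || any(ei$E >= 1)) {
    return(-Inf)
  }
  # lambda at each branching age; a node exactly at a shift belongs to the
  # older interval
  idx <- findInterval(bt, shift_times) + 1L
  bd_combine_loglik(bt, ei$E, ei$I, log(lambda[idx]), f, conditioning)
}

#' Episodic birth-death log-likelihood
#'
#' Piecewise-constant speciation/extinction likelihood of the branching
#' times, with the extinction/likelihood recursions solved in closed form
#' and segmented exactly at the shift times. With zero shifts this equals
#' the constant-rate [bd_loglik()].
#'
#' @param bt Branching times (descending) or a `phylo`.
#' @param model An [episodic_model()].
#' @param conditioning `"crown_survival"` or `"none"`.
#' @return Log-likelihood scalar.
#' @export
episodic_loglik <- function(bt, model, conditioning = c("crown_survival", "none")) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(model, "episodic_model"))
  bt <- as_branching_times(bt)
  episodic_loglik_core(
    bt, model$shift_times, model$lambda, model$mu,
    model$f, conditioning
  )
}

# fit interval rates for fixed shift times; returns list(loglik, rates, turnovers)
fit_episodic_rates <- function(bt, shift_times, f, conditioning, start = NULL,
                               n_starts = 1, seed = NULL, polish = TRUE) {
  s <- length(shift_times)
  np <- s + 1
  crown <- bt[1]
  n <- length(bt) + 1
  objfn <- function(par) {
    r <- exp(par[seq_len(np)])
    eps <- plogis_vec(par[np + seq_len(np)]) * 0.999
    ll <- episodic_loglik_core(bt, shift_times, r / (1 - eps), r * eps / (1 - eps),
      f,
      conditioning = conditioning
    )
    if (!is.finite(ll)) 1e10 else -ll
  }
  r0 <- max(log(n / 2) / crown, 0.02)
  starts <- list()
  if (!is.null(start)) starts[[length(starts) + 1]] <- start
  if (is.null(seed)) seed <- 1
  set.seed(seed)
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <- c(
      log(r0) + runif(np, -0.7, 0.7),
      qlogis_vec(runif(np, 0.05, 0.6))
    )
  }
  best <- NULL
  for (st in starts) {
    fit <- optim(st, objfn,
      method = "Nelder-Mead",
      control = list(maxit = if (polish) 600 else 300, reltol = 1e-10)
    )
    if (polish) {
      fit2 <- tryCatch(
        optim(fit$par, objfn,
          method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-12)
        ),
        error = function(e) fit
      )
      if (fit2$value < fit$value) fit <- fit2
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  r <- exp(best$par[seq_len(np)])
  eps <- plogis_vec(best$par[np + seq_len(np)]) * 0.999
  list(
    loglik = -best$value, rates = r, turnovers = eps,
    par = best$par, converged = is.finite(best$value) && best$value < 1e9
  )
}

plogis_vec <- function(x) 1 / (1 + exp(-x))
qlogis_vec <- function(p) log(p / (1 - p))

#' Fit episodic birth-death models with 0 to `max_shifts` shifts
#'
#' Shift placement follows a greedy sequential grid search in the spirit of
#' TreePar's `bd.shifts.optim`: for each additional shift, every age on a
#' regular grid (step `grid_step`, excluding ages within one step of the
#' present and of the crown age, where shifts are unidentifiable) is tried
#' conditional on the previously accepted shift times, all interval rates
#' being re-optimized each time; the best placement is then polished and
#' accepted.
#'
#' @param bt Branching times (descending) or a `phylo`.
#' @param max_shifts Maximum number of shifts (<= 4).
#' @param grid_step Grid resolution in Myr (default 0.1).
#' @param f Sampling fraction.
#' @param conditioning Passed to the likelihood.
#' @param n_starts Random starts for the rate optimization at each level.
#' @param seed Seed for start jitter.
#' @return A tibble with one row per shift count `s`: `n_shifts`, `n_params`
#'   (3s + 2: one rate and one turnover per interval plus one age per
#'   shift), `loglik`, `aic`, `converged`, and list-columns `shift_times`,
#'   `rates`, `turnovers`.
#' @export
fit_shifts <- function(bt, max_shifts = 4, grid_step = 0.1, f = 1,
                       conditioning = c("crown_survival", "none"),
                       n_starts = 3, seed = 1) {
  conditioning <- match.arg(conditioning)
  bt <- as_branching_times(bt)
  if (max_shifts > 4) abort("max_shifts must be <= 4.")
  if (grid_step <= 0) abort("grid_step must be positive.")
  crown <- bt[1]
  grid <- seq(grid_step, crown - grid_step, by = grid_step)
  rows <- list()
  # s = 0
  fit0 <- fit_episodic_rates(bt, numeric(0), f, conditioning,
    n_starts = n_starts, seed = seed
  )
  rows[[1]] <- tibble(
    n_shifts = 0L, n_params = 2, loglik = fit0$loglik,
    converged = fit0$converged,
    shift_times = list(numeric(0)), rates = list(fit0$rates),
    turnovers = list(fit0$turnovers)
  )
  accepted <- numeric(0)
  prev <- fit0
  for (s in seq_len(max_shifts)) {
    if (length(bt) < 3 * s + 2) {
      warn(paste0("Skipping s = ", s, ": fewer branching times than parameters."))
      break
    }
    cand <- setdiff(grid, accepted)
    if (!length(cand)) break
    best_cand <- NULL
    # warm start: previous interval parameters with the new interval copied
    for (g in cand) {
      sh <- sort(c(accepted, g))
      pos <- which(sort(c(accepted, g)) == g)[1]
      np_prev <- s
      wpar <- warm_start_par(prev, pos)
      fit <- fit_episodic_rates(bt, sh, f, conditioning,
        start = wpar,
        n_starts = 1, seed = seed, polish = FALSE
      )
      if (is.null(best_cand) || fit$loglik > best_cand$loglik) {
        best_cand <- c(fit, list(g = g, shift_times = sh))
      }
    }
    # polish the winning placement with multi-starts
    fitp <- fit_episodic_rates(bt, best_cand$shift_times, f, conditioning,
      start = best_cand$par, n_starts = n_starts, seed = seed + s
    )
    accepted <- best_cand$shift_times
    prev <- fitp
    rows[[s + 1]] <- tibble(
      n_shifts = as.integer(s), n_params = 3 * s + 2, loglik = fitp$loglik,
      converged = fitp$converged,
      shift_times = list(accepted), rates = list(fitp$rates),
      turnovers = list(fitp$turnovers)
    )
  }
  out <- bind_rows(rows)
  out$aic <- aic(out$loglik, out$n_params)
  out$model <- ifelse(out$n_shifts == 0, "BD-constant",
    paste0("BD-", out$n_shifts, " shift", ifelse(out$n_shifts > 1, "s", ""))
  )
  structure(out[, c(
    "model", "n_shifts", "n_params", "loglik", "aic", "converged",
    "shift_times", "rates", "turnovers"
  )], class = c("episodic_fits", class(out)))
}

# duplicate the interval parameters around the inserted shift position
warm_start_par <- function(prev_fit, pos) {
  np <- length(prev_fit$rates)
  logr <- log(prev_fit$rates)
  leps <- qlogis_vec(pmin(pmax(prev_fit$turnovers / 0.999, 1e-6), 1 - 1e-6))
  c(append(logr, logr[pos], after = pos), append(leps, leps[pos], after = pos))
}

#' Select the number of episodic shifts by sequential likelihood-ratio tests
#'
#' Starting from zero shifts, each additional shift is accepted only when
#' the likelihood-ratio test against the previous level is significant at
#' `alpha` (chi-squared with `df = 3` per added shift: one shift time, one
#' rate, one turnover). Returns the chosen number of shifts together with
#' the LRT/AIC table.
#'
#' @param fits Output of [fit_shifts()].
#' @param alpha Significance level (default 0.05).
#' @param df_per_shift Degrees of freedom per added shift (default 3).
#' @return A list with `n_shifts` (chosen) and `table` (tibble with LRT
#'   p-values and AIC columns).
#' @export
select_num_shifts <- function(fits, alpha = 0.05, df_per_shift = 3) {
  fits <- fits[order(fits$n_shifts), ]
  ll <- fits$loglik
  p <- rep(NA_real_, nrow(fits))
  for (i in seq_len(nrow(fits) - 1)) {
    stat <- max(2 * (ll[i + 1] - ll[i]), 0)
    p[i + 1] <- pchisq(stat, df = df_per_shift, lower.tail = FALSE)
  }
  chosen <- 0L
  for (i in seq_len(nrow(fits) - 1)) {
    if (!is.na(p[i + 1]) && p[i + 1] < alpha) chosen <- fits$n_shifts[i + 1] else break
  }
  tab <- fits
  tab$lrt_p <- p
  tab$delta <- tab$aic - min(tab$aic)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  list(n_shifts = chosen, table = tab)
}
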