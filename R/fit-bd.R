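## Multi-start ML fitting of the time-dependent family (6 models) and the
## paleoenvironment-dependent family (4 models per proxy).

bd_time_models <- function() {
  tibble(
    model = c("yule", "bcst_dcst", "bvar", "bvar_dcst", "bcst_dvar", "bvar_dvar"),
    description = c(
      "constant speciation, no extinction",
      "constant speciation and extinction",
      "time-varying speciation, no extinction",
      "time-varying speciation, constant extinction",
      "constant speciation, time-varying extinction",
      "time-varying speciation and extinction"
    ),
    lambda_kind = c("constant", "constant", "exp", "exp", "constant", "exp"),
    mu_kind = c("none", "constant", "none", "constant", "exp", "exp")
  )
}

bd_env_models <- function() {
  tibble(
    model = c("benv", "benv_dcst", "bcst_denv", "benv_denv"),
    description = c(
      "env-varying speciation, no extinction",
      "env-varying speciation, constant extinction",
      "constant speciation, env-varying extinction",
      "env-varying speciation and extinction"
    ),
    lambda_kind = c("exp", "exp", "constant", "exp"),
    mu_kind = c("none", "constant", "exp", "exp")
  )
}

bd_build_spec <- function(family, lambda_kind, mu_kind, pars, env, f, conditioning) {
  mk_rate <- function(kind, rate0, alpha) {
    if (kind == "constant") {
      rate_constant(rate0)
    } else if (family == "time") {
      rate_exp_time(rate0, alpha)
    } else {
      rate_exp_env(rate0, alpha, env)
    }
  }
  lam <- mk_rate(lambda_kind, pars[["lambda0"]], pars[["alpha"]])
  mu <- switch(mu_kind,
    none = NULL,
    constant = rate_constant(pars[["mu0"]]),
    exp = mk_rate("exp", pars[["mu0"]], pars[["beta"]])
  )
  bd_model_spec(lam, mu, f = f, conditioning = conditioning)
}

bd_free_params <- function(lambda_kind, mu_kind) {
  c(
    "lambda0",
    if (lambda_kind == "exp") "alpha",
    if (mu_kind != "none") "mu0",
    if (mu_kind == "exp") "beta"
  )
}

#' Fit the time-dependent or environment-dependent birth-death family
#'
#' Six time models (pure birth and birth-death, each with constant or
#' exponentially time-varying rates) or four environment models
#' (exponential dependence of speciation and/or extinction on an
#' interpolated proxy). Every model is fitted by bounded multi-start local
#' optimization (Nelder-Mead polished by a bounded quasi-Newton step;
#' bounds lambda0 in [1e-6, 10], mu0 in [0, 10], alpha/beta in [-2, 2]);
#' the best model is flagged by lowest AIC, ties broken toward fewer
#' parameters.
#'
#' @param bt Branching times (descending) or a `phylo`.
#' @param family `"time"` or `"env"`.
#' @param env An [env_curve()] (required for the env family).
#' @param f Sampling fraction.
#' @param conditioning `"crown_survival"` or `"none"`.
#' @param n_starts Starts per model (default 3).
#' @param seed Seed for start jitter.
#' @return A tibble with one row per model: `model`, `n_params`, `loglik`,
#'   `aic`, `delta`, `weight`, `best`, `converged`, `n_starts_used` and
#'   parameter columns `lambda0`, `alpha`, `mu0`, `beta`.
#' @export
fit_bd_family <- function(bt, family = c("time", "env"), env = NULL, f = 1,
                          conditioning = c("crown_survival", "none"),
                          n_starts = 3, seed = 1) {
  family <- match.arg(family)
  conditioning <- match.arg(conditioning)
  bt <- as_branching_times(bt)
  if (family == "env") {
    if (is.null(env)) abort("family = 'env' requires an env curve.")
    if (bt[1] > env$range[2] + 1e-9) {
      warn("Crown age exceeds the env curve range; values clamp to the oldest sample.")
    }
  }
  models <- if (family == "time") bd_time_models() else bd_env_models()
  n <- length(bt) + 1
  crown <- bt[1]
  lam_init <- max(log(n / 2) / crown, 0.02)
  rows <- list()
  for (i in seq_len(nrow(models))) {
    lk <- models$lambda_kind[i]
    mk <- models$mu_kind[i]
    free <- bd_free_params(lk, mk)
    np <- length(free)
    objfn <- function(par) {
      pars <- bd_untransform(free, par)
      spec <- tryCatch(
        bd_build_spec(family, lk, mk, pars, env, f, conditioning),
        error = function(e) NULL
      )
      if (is.null(spec)) return(1e10)
      ll <- tryCatch(bd_loglik(bt, spec), error = function(e) -Inf)
      if (!is.finite(ll)) 1e10 else -ll
    }
    set.seed(seed + i)
    best <- NULL
    used <- 0
    for (s in seq_len(n_starts)) {
      st <- bd_start(free, lam_init)
      fit <- tryCatch(
        {
          f1 <- if (np == 1) {
            optim(st, objfn,
              method = "Brent", lower = bd_bounds(free)$lower,
              upper = bd_bounds(free)$upper, control = list(reltol = 1e-12)
            )
          } else {
            optim(st, objfn,
              method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10)
            )
          }
          f2 <- tryCatch(
            nlminb(f1$par, objfn,
              lower = bd_bounds(free)$lower,
              upper = bd_bounds(free)$upper
            ),
            error = function(e) NULL
          )
          if (!is.null(f2) && f2$objective < f1$value) {
            list(par = f2$par, value = f2$objective)
          } else {
            f1[c("par", "value")]
          }
        },
        error = function(e) NULL
      )
      if (!is.null(fit)) used <- used + 1
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    pars <- bd_untransform(free, best$par)
    rows[[i]] <- tibble(
      model = models$model[i],
      n_params = np,
      loglik = -best$value,
      converged = is.finite(best$value) && best$value < 1e9,
      n_starts_used = used,
      lambda0 = pars[["lambda0"]],
      alpha = if ("alpha" %in% free) pars[["alpha"]] else NA_real_,
      mu0 = if ("mu0" %in% free) pars[["mu0"]] else 0,
      beta = if ("beta" %in% free) pars[["beta"]] else NA_real_
    )
  }
  out <- bind_rows(rows)
  out$aic <- aic(out$loglik, out$n_params)
  ok <- out$converged & is.finite(out$aic)
  out$delta <- out$aic - min(out$aic[ok])
  w <- exp(-out$delta / 2)
  w[!ok] <- 0
  out$weight <- w / sum(w)
  out$best <- FALSE
  sel <- which(ok)[order(out$delta[ok], out$n_params[ok])][1]
  out$best[sel] <- TRUE
  if (!all(ok)) {
    warn(paste0(
      "Models excluded from best-model selection (non-converged): ",
      paste(out$model[!ok], collapse = ", ")
    ))
  }
  structure(
    out[, c(
      "model", "n_params", "loglik", "aic", "delta", "weight", "best",
      "converged", "n_starts_used", "lambda0", "alpha", "mu0", "beta"
    )],
    class = c("bd_fits", class(out)), family = family
  )
}

# transformed scale: log(lambda0), log(mu0); alpha/beta natural
bd_untransform <- function(free, par) {
  names(par) <- free
  out <- list(lambda0 = NA, alpha = 0, mu0 = 0, beta = 0)
  out$lambda0 <- min(exp(par[["lambda0"]]), 10)
  if ("alpha" %in% free) out$alpha <- max(min(par[["alpha"]], 2), -2)
  if ("mu0" %in% free) out$mu0 <- min(exp(par[["mu0"]]), 10)
  if ("beta" %in% free) out$beta <- max(min(par[["beta"]], 2), -2)
  out
}

bd_start <- function(free, lam_init) {
  st <- c(lambda0 = log(lam_init) + runif(1, -0.7, 0.7))
  if ("alpha" %in% free) st <- c(st, alpha = runif(1, -0.25, 0.25))
  if ("mu0" %in% free) st <- c(st, mu0 = log(lam_init) + runif(1, -3, -0.7))
  if ("beta" %in% free) st <- c(st, beta = runif(1, -0.25, 0.25))
  st[free]
}

bd_bounds <- function(free) {
  lower <- c(lambda0 = log(1e-6), alpha = -2, mu0 = log(1e-9), beta = -2)
  upper <- c(lambda0 = log(10), alpha = 2, mu0 = log(10), beta = 2)
  list(lower = lower[free], upper = upper[free])
}
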