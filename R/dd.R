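## Diversity-dependent birth-death likelihood via the species-count master
## equation. Between consecutive branching times the probability vector over
## the number m of "missing" species (lineages alive at that time without
## sampled descendants) evolves under
##   dp_m/dt = lambda(k+m-1) (2k+m-1) p_{m-1} + mu(k+m+1) (m+1) p_{m+1}
##             - (lambda(k+m) + mu(k+m)) (k+m) p_m
## where k is the number of observed lineages. The 2k factor on births from
## observed lineages carries the two daughter orderings of the standard
## reconstructed-tree (Nee/Morlon) likelihood, so in the
## diversity-independent limit this reproduces bd_loglik() exactly. Each
## observed branching multiplies p_m by lambda(k+m); at the present the
## entry with the known number of unsampled extant species is read off.
## Crown-survival conditioning integrates a two-type (per-crown-subtree)
## master equation for the probability that both crown lineages leave
## extant descendants.

#' Diversity-dependent model specification
#'
#' Functional forms (n is the standing species number):
#' * `DDL` / `DDL+E`: `lambda(n) = lambda0 - (lambda0 - mu0) n / K`
#'   (clamped at 0), `mu(n) = mu0`; `DDL` forces `mu0 = 0`.
#' * `DDX+E`: `lambda(n) = lambda0 * n^-x`, `mu(n) = mu0`.
#' * `DD+EL`: `lambda(n) = lambda0`, `mu(n) = mu0 + (lambda0 - mu0) n / K`.
#' * `DD+EX`: `lambda(n) = lambda0`, `mu(n) = mu0 * n^x`.
#'
#' `K` is the carrying capacity (equilibrium diversity for the linear
#' forms); `x` the exponent of the power-law forms.
#'
#' @param variant One of `"DDL"`, `"DDL+E"`, `"DDX+E"`, `"DD+EL"`,
#'   `"DD+EX"`.
#' @param lambda0 Intrinsic speciation rate (>= 0).
#' @param mu0 Intrinsic extinction rate (0 for DDL).
#' @param K Carrying capacity (> 1; linear variants).
#' @param x Exponent (power-law variants).
#' @param f Sampling fraction in (0, 1].
#' @return A `dd_model` list.
#' @export
dd_model <- function(variant = c("DDL", "DDL+E", "DDX+E", "DD+EL", "DD+EX"),
                     lambda0, mu0 = 0, K = NULL, x = NULL, f = 1) {
  variant <- match.arg(variant)
  if (variant == "DDL" && mu0 != 0) abort("DDL has no extinction (mu0 must be 0).")
  if (variant %in% c("DDL", "DDL+E", "DD+EL")) {
    if (is.null(K) || K <= 1) abort("Linear variants need carrying capacity K > 1.")
  }
  if (variant %in% c("DDX+E", "DD+EX")) {
    if (is.null(x)) abort("Power-law variants need exponent x.")
  }
  stopifnot(lambda0 >= 0, mu0 >= 0, f > 0, f <= 1)
  structure(
    list(variant = variant, lambda0 = lambda0, mu0 = mu0, K = K, x = x, f = f),
    class = "dd_model"
  )
}

# per-lineage rates as functions of standing diversity n (vectorized)
dd_lambda_n <- function(model, n) {
  with(model, switch(variant,
    "DDL" = ,
    "DDL+E" = pmax(lambda0 - (lambda0 - mu0) * n / K, 0),
    "DDX+E" = lambda0 * n^(-x),
    "DD+EL" = ,
    "DD+EX" = rep(lambda0, length(n))
  ))
}

dd_mu_n <- function(model, n) {
  with(model, switch(variant,
    "DDL" = ,
    "DDL+E" = ,
    "DDX+E" = rep(mu0, length(n)),
    "DD+EL" = pmax(mu0 + (lambda0 - mu0) * n / K, 0),
    "DD+EX" = mu0 * n^x
  ))
}

# propagate p (length M+1, m = 0..M) over dt with k observed lineages,
# by uniformization of the truncated master equation (C++ kernel)
dd_propagate <- function(p, k, dt, model) {
  if (dt <= 0) return(p)
  M <- length(p) - 1L
  m <- 0:M
  n <- k + m
  lam <- dd_lambda_n(model, n)
  mu <- dd_mu_n(model, n)
  diagloss <- (lam + mu) * n
  # absurd rate regions (deep in power-law tails) are numerically hopeless
  # and biologically impossible; flag them instead of grinding through
  if (max(diagloss) * dt > 1e5) {
    return(NULL)
  }
  dd_propagate_cpp(
    p,
    up = lam * (2 * k + m), # m -> m + 1
    down = mu * m, # m -> m - 1
    diagloss = diagloss,
    dt = dt
  )
}

#' Diversity-dependent log-likelihood of branching times
#'
#' Evolves the probability vector over the number of unobserved species
#' between consecutive branching times under the truncated master equation
#' with diversity-dependent rates, multiplies in the observed branching
#' events, reads off the entry with the known number of unsampled extant
#' species, and conditions on survival of both crown lineages.
#'
#' The truncation starts at `max(ceiling(2K), n_tips + 200)` missing-species
#' states (or `n_tips + 200` for power-law variants) and doubles
#' automatically (up to a cap) whenever the probability mass adjacent to the
#' boundary exceeds 1e-8 of the total.
#'
#' @param bt Branching times (descending) or a `phylo`.
#' @param model A [dd_model()].
#' @param n_missing Number of extant species absent from the tree (default
#'   0; set `known_species - n_tips` to emulate incomplete sampling).
#' @param conditioning `"crown_survival"` or `"none"`.
#' @param truncation Optional initial truncation override.
#' @return Log-likelihood scalar (possibly `-Inf` for impossible data, e.g.
#'   clamped speciation before the last observed branching).
#' @export
dd_loglik <- function(bt, model, n_missing = 0,
                      conditioning = c("crown_survival", "none"),
                      truncation = NULL) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(model, "dd_model"))
  bt <- as_branching_times(bt)
  n_tips <- length(bt) + 1
  # the state space tracks *missing* lineages only; their probability mass
  # stays near zero (they must die or be among the unsampled), so the
  # truncation scales with the tree, not with K, and doubles on demand
  M0 <- if (!is.null(truncation)) truncation else max(n_tips + 200, 4 * n_missing)
  M <- as.integer(M0)
  # boundary mass that keeps growing past a few doublings signals a
  # degenerate parameter point (runaway missing-lineage production), not an
  # undersized grid; refuse rather than grind
  cap <- max(4L * M, 1200L)
  repeat {
    res <- dd_loglik_try(bt, model, n_missing, conditioning, M)
    if (!identical(res, "truncation")) {
      return(res)
    }
    if (M >= cap) abort("dd_loglik(): truncation cap exceeded.")
    M <- M * 2L
  }
}

dd_loglik_try <- function(bt, model, n_missing, conditioning, M) {
  n_tips <- length(bt) + 1
  ages <- c(bt, 0) # descending, crown first, present last
  p <- c(1, numeric(M))
  logscale <- 0
  k <- 2L
  for (i in seq_len(length(ages) - 1)) {
    dt <- ages[i] - ages[i + 1]
    p <- dd_propagate(p, k, dt, model)
    if (is.null(p)) {
      return(-Inf)
    }
    tot <- sum(p)
    if (!is.finite(tot) || tot <= 0) {
      return(-Inf)
    }
    # boundary mass check (relative)
    if (sum(p[(M - 1):(M + 1)]) > 1e-8 * tot) {
      return("truncation")
    }
    if (i < length(ages) - 1) {
      # observed branching at ages[i + 1]
      lam_branch <- dd_lambda_n(model, k + 0:M)
      p <- p * lam_branch
      k <- k + 1L
      tot <- sum(p)
      if (!is.finite(tot) || tot <= 0) {
        return(-Inf)
      }
    }
    logscale <- logscale + log(tot)
    p <- p / tot
  }
  if (n_missing > M) {
    return("truncation")
  }
  lik <- p[n_missing + 1]
  if (!is.finite(lik) || lik <= 0) {
    return(-Inf)
  }
  ll <- logscale + log(lik) + n_tips * log(model$f)
  if (conditioning == "crown_survival") {
    pc <- dd_crown_survival_prob(model, bt[1])
    if (is.na(pc)) {
      return(-Inf)
    }
    ll <- ll - log(pc)
  }
  ll
}

# probability that both crown lineages leave extant descendants, via a
# two-type master equation on (n_A, n_B) counts of the two crown subtrees.
# The grid size adapts to the realized diversity (linear-lambda models
# cannot exceed K by more than one; otherwise grown until the boundary
# mass is negligible), and the linear system is integrated with lsoda.
dd_crown_survival_prob <- function(model, crown_age, S = NULL) {
  # pure-birth variants: no lineage ever dies, survival is certain
  if (model$mu0 == 0 && model$variant %in% c("DDL", "DDL+E", "DDX+E")) {
    return(1)
  }
  if (is.null(S)) {
    # supremum of realized diversity: linear-lambda models clamp speciation
    # at K, DD+EL equilibrates near K; power-law models get a pure-birth
    # growth bound with a hard cap (the reflecting boundary counts overflow
    # as alive, a negligible bias exactly where populations explode)
    S_K <- if (!is.null(model$K) && model$variant %in% c("DDL", "DDL+E")) {
      ceiling(1.05 * model$K) + 5
    } else if (!is.null(model$K)) {
      ceiling(1.6 * model$K) + 10
    } else {
      Inf
    }
    S_growth <- max(40, ceiling(8 * exp(min(model$lambda0 * crown_age, 3))))
    S <- min(S_K, S_growth)
  }
  S <- min(S, 250)
  repeat {
    Si <- as.integer(S)
    nvec <- 1:(2 * Si)
    lamn <- dd_lambda_n(model, nvec)
    mun <- dd_mu_n(model, nvec)
    if (max(nvec * (lamn + mun)) * crown_age > 2e4) {
      return(NA_real_) # numerically hopeless rate region
    }
    res <- dd_crown_survival_cpp(
      lamn, mun,
      Si, crown_age,
      boundary_tol = if (S >= 250) Inf else 1e-3
    )
    # boundary states are overwhelmingly alive, so reflecting them biases
    # the survival probability negligibly; accept once the cap is reached
    if (res >= 0) {
      return(res)
    }
    S <- ceiling(S * 1.5)
  }
}

#' Fit the five standard diversity-dependent models
#'
#' Fits `DDL`, `DDL+E`, `DDX+E`, `DD+EL`, `DD+EX` by bounded multi-start
#' maximum likelihood (3 starts each), with
#' the initial carrying capacity set to the clade's known species count.
#'
#' @param bt Branching times (descending) or a `phylo`.
#' @param f Sampling fraction (recorded; missing species enter through
#'   `known_species`).
#' @param known_species Known extant species count of the clade
#'   (>= number of tips); `known_species - n_tips` species are treated as
#'   unsampled at present.
#' @param variants Subset of variants to fit (default all five).
#' @param n_starts Starts per variant.
#' @param seed Seed for start jitter.
#' @param conditioning Passed to [dd_loglik()].
#' @return A tibble with one row per variant: `model`, `n_params`,
#'   `loglik`, `aic`, `converged`, `n_starts_used` and parameter columns
#'   `lambda0`, `mu0`, `K`, `x`.
#' @export
fit_dd_family <- function(bt, f = 1, known_species = NULL,
                          variants = c("DDL", "DDL+E", "DDX+E", "DD+EL", "DD+EX"),
                          n_starts = 3, seed = 1,
                          conditioning = "crown_survival") {
  bt <- as_branching_times(bt)
  n_tips <- length(bt) + 1
  if (is.null(known_species)) known_species <- n_tips
  if (known_species < n_tips) abort("known_species must be >= the number of tips.")
  n_missing <- known_species - n_tips
  crown <- bt[1]
  lam_init <- max(log(n_tips / 2) / crown * 1.5, 0.05)
  rows <- list()
  for (v in variants) {
    free <- switch(v,
      "DDL" = c("lambda0", "K"),
      "DDL+E" = c("lambda0", "mu0", "K"),
      "DDX+E" = c("lambda0", "mu0", "x"),
      "DD+EL" = c("lambda0", "mu0", "K"),
      "DD+EX" = c("lambda0", "mu0", "x")
    )
    np <- length(free)
    objfn <- function(par) {
      pars <- setNames(exp(par), free)
      if ("x" %in% free) pars["x"] <- par[which(free == "x")] # x on natural scale
      # caps keep the optimizer inside the biologically meaningful region
      # (and the master-equation state space bounded)
      m <- tryCatch(
        dd_model(v,
          lambda0 = min(pars[["lambda0"]], 2),
          mu0 = if ("mu0" %in% free) min(pars[["mu0"]], 2) else 0,
          K = if ("K" %in% free) min(pars[["K"]], 1500) else NULL,
          x = if ("x" %in% free) max(min(pars[["x"]], 1.5), -1.5) else NULL,
          f = f
        ),
        error = function(e) NULL
      )
      if (is.null(m)) return(1e10)
      ll <- tryCatch(
        dd_loglik(bt, m, n_missing = n_missing, conditioning = conditioning),
        error = function(e) -Inf
      )
      if (!is.finite(ll)) 1e10 else -ll
    }
    set.seed(seed + match(v, variants))
    best <- NULL
    used <- 0
    for (s in seq_len(n_starts)) {
      st <- setNames(numeric(np), free)
      st["lambda0"] <- log(lam_init) + runif(1, -0.6, 0.6)
      if ("mu0" %in% free) st["mu0"] <- log(lam_init) + runif(1, -3, -1)
      if ("K" %in% free) st["K"] <- log(known_species * runif(1, 0.9, 1.6))
      if ("x" %in% free) st["x"] <- runif(1, 0.05, 0.4)
      fit <- tryCatch(
        {
          f1 <- optim(st, objfn,
            method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-9)
          )
          used <- used + 1
          f1
        },
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    pars <- setNames(exp(best$par), free)
    if ("x" %in% free) pars["x"] <- best$par[which(free == "x")]
    rows[[v]] <- tibble(
      model = v,
      n_params = np,
      loglik = -best$value,
      converged = is.finite(best$value) && best$value < 1e9,
      n_starts_used = used,
      lambda0 = unname(pars["lambda0"]),
      mu0 = if ("mu0" %in% free) unname(pars["mu0"]) else 0,
      K = if ("K" %in% free) unname(pars["K"]) else NA_real_,
      x = if ("x" %in% free) unname(pars["x"]) else NA_real_
    )
  }
  out <- bind_rows(rows)
  out$aic <- aic(out$loglik, out$n_params)
  structure(out, class = c("dd_fits", class(out)))
}
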