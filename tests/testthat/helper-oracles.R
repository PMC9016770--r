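# Independent brute-force oracles used across the test files. These share
# no code with the package implementations they check: fixed-step
# Runge-Kutta integration, dense matrix exponentials and exhaustive state
# enumeration.

# fine-grid (midpoint RK2) integration of the trait-free birth-death
# E/log-D equations for arbitrary rate functions of age
# (midpoint RK2 at h = 5e-4 has O(h^2) error ~ 1e-7, far inside the 1e-4
# comparison tolerance)
oracle_bd_loglik <- function(bt, lam_f, mu_f, f, conditioning = "crown_survival",
                             h = 5e-4) {
  bt <- sort(bt, decreasing = TRUE)
  Tc <- bt[1]
  ts <- seq(0, Tc, by = h)
  E <- numeric(length(ts))
  I <- numeric(length(ts))
  E[1] <- 1 - f
  for (i in seq_len(length(ts) - 1)) {
    l <- lam_f(ts[i])
    m <- mu_f(ts[i])
    k1E <- m - (l + m) * E[i] + l * E[i]^2
    lm <- lam_f(ts[i] + h / 2)
    mm <- mu_f(ts[i] + h / 2)
    Em <- E[i] + h / 2 * k1E
    E[i + 1] <- E[i] + h * (mm - (lm + mm) * Em + lm * Em^2)
    I[i + 1] <- I[i] + h * (lm + mm - 2 * lm * Em)
  }
  Ef <- approxfun(ts, E)
  If <- approxfun(ts, I)
  n <- length(bt) + 1
  bt_asc <- sort(bt)
  Ifull <- c(0, If(bt_asc))
  k <- seq(n, 2)
  ll <- n * log(f) - sum(k * diff(Ifull)) + sum(log(lam_f(bt[-1])))
  if (conditioning == "crown_survival") ll <- ll - 2 * log(1 - Ef(Tc))
  ll
}

# dense matrix-exponential propagation of the diversity-dependent master
# equation (uses Matrix::expm, not the package's uniformization)
oracle_dd_loglik <- function(bt, model, M = 80) {
  ages <- c(sort(bt, decreasing = TRUE), 0)
  p <- c(1, numeric(M))
  k <- 2
  ll <- 0
  for (i in seq_len(length(ages) - 1)) {
    dt <- ages[i] - ages[i + 1]
    m <- 0:M
    n <- k + m
    lam <- paleodiv:::dd_lambda_n(model, n)
    mu <- paleodiv:::dd_mu_n(model, n)
    A <- matrix(0, M + 1, M + 1)
    for (mm in 0:M) {
      if (mm < M) A[mm + 2, mm + 1] <- lam[mm + 1] * (2 * k + mm)
      if (mm > 0) A[mm, mm + 1] <- mu[mm + 1] * mm
      A[mm + 1, mm + 1] <- -(lam[mm + 1] + mu[mm + 1]) * (k + mm)
    }
    p <- as.vector(Matrix::expm(A * dt) %*% p)
    if (i < length(ages) - 1) {
      p <- p * paleodiv:::dd_lambda_n(model, k + 0:M)
      k <- k + 1
    }
    sc <- sum(p)
    ll <- ll + log(sc)
    p <- p / sc
  }
  ll + log(p[1])
}

# series matrix exponential (independent of the package's eigen route)
oracle_expm <- function(A) {
  s <- max(0, ceiling(log2(max(sum(abs(A)), 1e-12))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:20) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# exhaustive enumeration of internal-state assignments for the Mk
# likelihood and marginals on small trees
oracle_mk_enum <- function(tree, states, Q, prior = rep(1 / 3, 3)) {
  n <- length(tree$tip.label)
  si <- paleodiv:::as_tip_states(states, tree)
  edge <- tree$edge
  Ps <- lapply(tree$edge.length, function(t) oracle_expm(Q * t))
  grid <- expand.grid(rep(list(1:3), tree$Nnode))
  tot <- 0
  marg <- matrix(0, n + tree$Nnode, 3)
  for (g in seq_len(nrow(grid))) {
    assign <- c(si, as.integer(grid[g, ]))
    p <- prior[assign[n + 1]]
    for (e in seq_len(nrow(edge))) {
      p <- p * Ps[[e]][assign[edge[e, 1]], assign[edge[e, 2]]]
    }
    p <- unname(p)
    tot <- tot + p
    marg[cbind(seq_along(assign), assign)] <-
      marg[cbind(seq_along(assign), assign)] + p
  }
  list(loglik = log(tot), marginals = marg / tot)
}

# fixed-step Euler pruning for a 3-tip SSE model ((A,B),C), arbitrary k
# states, dual or single inheritance via the alternatives list
oracle_sse_3tip <- function(tree, states_int, lambda, mu, Q, f, h = 2e-4,
                            single = FALSE, alts = NULL) {
  k <- length(lambda)
  ages <- node_ages(tree)
  step <- function(y, dt) {
    E <- y[1:k]
    D <- y[k + 1:k]
    dE <- mu - (lambda + mu) * E + as.vector(Q %*% E)
    dD <- -(lambda + mu) * D + as.vector(Q %*% D)
    if (!single) {
      dE <- dE + lambda * E * E
      dD <- dD + 2 * lambda * E * D
    } else {
      for (s in 1:k) {
        a <- alts[[s]]
        r <- lambda[s] / (2 * length(a))
        for (x in a) {
          dE[s] <- dE[s] + 2 * r * E[s] * E[x]
          dD[s] <- dD[s] + 2 * r * (E[s] * D[x] + D[s] * E[x])
        }
      }
    }
    y + dt * c(dE, dD)
  }
  integrate_branch <- function(y, t0, t1) {
    nstep <- max(2, ceiling((t1 - t0) / h))
    dt <- (t1 - t0) / nstep
    for (i in seq_len(nstep)) y <- step(y, dt)
    y
  }
  combine <- function(y1, y2, at_root = FALSE) {
    D <- numeric(k)
    E <- 0.5 * (y1[1:k] + y2[1:k])
    for (s in 1:k) {
      if (!single) {
        D[s] <- y1[k + s] * y2[k + s] * if (at_root) 1 else lambda[s]
      } else {
        a <- alts[[s]]
        r <- if (at_root) 1 / (2 * length(a)) else lambda[s] / (2 * length(a))
        for (x in a) {
          D[s] <- D[s] + r * (y1[k + s] * y2[k + x] + y1[k + x] * y2[k + s])
        }
      }
    }
    c(E, D)
  }
  lab <- tree$tip.label
  n <- length(lab)
  tipy <- function(i) c(rep(1 - f, k), as.numeric(states_int[lab[i]] == 1:k) * f)
  t_ab <- ages[n + 2]
  t_root <- ages[n + 1]
  yA <- integrate_branch(tipy(1), 0, t_ab)
  yB <- integrate_branch(tipy(2), 0, t_ab)
  yab <- integrate_branch(combine(yA, yB), t_ab, t_root)
  yC <- integrate_branch(tipy(3), 0, t_root)
  yr <- combine(yab, yC, at_root = TRUE)
  D <- yr[k + 1:k]
  E <- yr[1:k]
  w <- D / sum(D)
  log(sum(w * D)) - log(sum(w * (1 - E)^2))
}

# small deterministic ultrametric trees used across tests
tree_4tip <- function() parse_newick("((A:2,B:2):6,(C:5,D:5):3);")
tree_5tip <- function() parse_newick("(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,E:3);")

# two clearly separated clusters joined by long stems
make_two_cluster_tree <- function(seed = 3, n1 = 20, n2 = 20, stem = 20) {
  s1 <- simulate_bd_tree(bd_model_spec(rate_constant(0.5), NULL, f = 1),
    crown_age = 5, seed = seed, n_tips_range = c(n1, n1)
  )
  s2 <- simulate_bd_tree(bd_model_spec(rate_constant(0.5), NULL, f = 1),
    crown_age = 5, seed = seed + 1, n_tips_range = c(n2, n2)
  )
  t1 <- s1$tree
  t2 <- s2$tree
  t1$tip.label <- paste0("a", seq_len(n1))
  t2$tip.label <- paste0("b", seq_len(n2))
  nw1 <- sub(";$", "", write_newick(t1))
  nw2 <- sub(";$", "", write_newick(t2))
  parse_newick(paste0("(", nw1, ":", stem, ",", nw2, ":", stem, ");"))
}

# quick constant-rate birth-death ML fit on branching times (closed form
# likelihood through the episodic s = 0 machinery)
fit_constant_bd <- function(bt, f = 1, seed = 1) {
  fit <- paleodiv:::fit_episodic_rates(bt, numeric(0), f,
    conditioning = "crown_survival", n_starts = 2, seed = seed
  )
  list(loglik = fit$loglik, n_params = 2, aic = 2 * 2 - 2 * fit$loglik)
}

# one-parameter pure-birth (Yule) ML fit with crown-survival conditioning
fit_yule_bd <- function(bt, f = 1) {
  nll <- function(loglam) {
    -paleodiv:::episodic_loglik_core(bt, numeric(0), exp(loglam), 0, f,
      conditioning = "crown_survival"
    )
  }
  opt <- optimize(nll, c(-8, 3))
  list(
    loglik = -opt$objective, lambda = exp(opt$minimum), n_params = 1,
    aic = 2 * 1 + 2 * opt$objective
  )
}
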