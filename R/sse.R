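## Hidden-state trait-dependent speciation-extinction models: 3 examined
## habitat states x d concealed states, ETD/CTD/CR rate dependence, six
## habitat-transition structures, and dual or single cladogenetic
## inheritance of the habitat state. The pruning likelihood runs in C++
## (see src/sse.cpp); an R/deSolve engine is kept for cross-validation.

sse_structures <- function() {
  c(
    "Unconstrained1", "Unconstrained6", "Constrained1",
    "Constrained4", "ConstrainedSpecialist", "ConstrainedOpenness"
  )
}

# parameter-index template for the 3x3 examined transition matrix;
# 0 = forbidden transition. States ordered forest, intermediate, open.
examined_template <- function(structure) {
  M <- matrix(0L, 3, 3, dimnames = list(habitat_levels(), habitat_levels()))
  switch(structure,
    Unconstrained1 = {
      M[row(M) != col(M)] <- 1L
    },
    Unconstrained6 = {
      M[1, 2] <- 1L; M[1, 3] <- 2L; M[2, 1] <- 3L
      M[2, 3] <- 4L; M[3, 1] <- 5L; M[3, 2] <- 6L
    },
    Constrained1 = {
      M[1, 2] <- M[2, 1] <- M[2, 3] <- M[3, 2] <- 1L
    },
    Constrained4 = {
      M[1, 2] <- 1L; M[2, 1] <- 2L; M[3, 2] <- 3L; M[2, 3] <- 4L
    },
    ConstrainedSpecialist = {
      # becoming a specialist (intermediate -> forest/open) vs generalist
      M[2, 1] <- M[2, 3] <- 1L
      M[1, 2] <- M[3, 2] <- 2L
    },
    ConstrainedOpenness = {
      # toward open habitats vs toward dense habitats
      M[1, 2] <- M[2, 3] <- 1L
      M[2, 1] <- M[3, 2] <- 2L
    },
    abort(paste0("Unknown structure: ", structure))
  )
  M
}

n_examined_params <- function(structure) {
  max(examined_template(structure))
}

# permitted single-inheritance alternatives per examined state
examined_alternatives <- function(structure) {
  M <- examined_template(structure)
  lapply(1:3, function(s) which(M[s, ] > 0L))
}

#' Hidden-state SSE model specification
#'
#' Combined state space of 3 examined habitat states times `d` concealed
#' states. Speciation depends on the examined state (`ETD`: one rate per
#' habitat, shared across concealed states), the concealed state (`CTD`:
#' one rate per concealed state, shared across habitats), or nothing
#' (`CR`). Extinction is a single shared rate. Anagenetic transitions
#' combine an examined-state structure (see Details) with one shared
#' concealed-state rate; simultaneous examined+concealed changes are
#' forbidden. Cladogenesis passes the parental combined state to both
#' daughters (`dual`) or to exactly one daughter (`single`), the other
#' daughter taking a permitted alternative examined state, the total
#' speciation rate being split equally among alternatives.
#'
#' Structures: `Unconstrained1` (any move, 1 rate), `Unconstrained6` (any
#' move, 6 rates), `Constrained1` (no direct forest-open moves, 1 rate),
#' `Constrained4` (no direct forest-open, 4 rates), `ConstrainedSpecialist`
#' (no direct forest-open; specializing vs generalizing rates),
#' `ConstrainedOpenness` (no direct forest-open; toward-open vs
#' toward-dense rates).
#'
#' @param dependence `"ETD"`, `"CTD"` or `"CR"`.
#' @param inheritance `"dual"` or `"single"`.
#' @param structure One of the six transition structures.
#' @param d Number of concealed states (default 3, mirroring the examined
#'   count).
#' @param f Sampling fraction, scalar or per-examined-state vector.
#' @return An `sse_model_spec` with the free-parameter count attached.
#' @export
sse_model_spec <- function(dependence = c("ETD", "CTD", "CR"),
                           inheritance = c("dual", "single"),
                           structure = sse_structures(), d = 3, f = 0.92) {
  dependence <- match.arg(dependence)
  inheritance <- match.arg(inheritance)
  structure <- match.arg(structure)
  stopifnot(d >= 1)
  if (length(f) == 1) f <- rep(f, 3)
  stopifnot(length(f) == 3, all(f > 0), all(f <= 1))
  n_lambda <- switch(dependence, ETD = 3L, CTD = as.integer(d), CR = 1L)
  np <- n_lambda + 1L + n_examined_params(structure) + (d > 1)
  structure(
    list(
      dependence = dependence, inheritance = inheritance,
      structure = structure, d = d, f = f,
      n_lambda = n_lambda, n_params = as.integer(np)
    ),
    class = "sse_model_spec"
  )
}

#' @export
print.sse_model_spec <- function(x, ...) {
  cat("<sse_model_spec> ", x$dependence, "-", x$inheritance, "-", x$structure,
    ", d = ", x$d, ", ", x$n_params, " free parameters\n",
    sep = ""
  )
  invisible(x)
}

#' Enumerate the 36-model SSE space
#'
#' All combinations of trait dependence (ETD, CTD, CR), cladogenetic
#' inheritance (dual, single) and the six transition structures.
#'
#' @param d Concealed-state count.
#' @param f Sampling fraction.
#' @return A tibble of 36 rows with a `spec` list-column and `n_params`.
#' @export
enumerate_model_space <- function(d = 3, f = 0.92) {
  grid <- expand.grid(
    dependence = c("ETD", "CTD", "CR"),
    inheritance = c("dual", "single"),
    structure = sse_structures(),
    stringsAsFactors = FALSE
  )
  specs <- pmap(grid, function(dependence, inheritance, structure) {
    sse_model_spec(dependence, inheritance, structure, d = d, f = f)
  })
  out <- as_tibble(grid)
  out$n_params <- vapply(specs, `[[`, 0L, "n_params")
  out$model <- paste(out$dependence, out$inheritance, out$structure, sep = "-")
  out$spec <- specs
  out[, c("model", "dependence", "inheritance", "structure", "n_params", "spec")]
}

# expand a named parameter list into combined-state rate objects.
# pars: list(lambda = length n_lambda, mu = 1, q_examined = struct params,
#            q_concealed = 1 when d > 1)
sse_rates <- function(spec, pars) {
  d <- spec$d
  k <- 3 * d
  exam <- rep(1:3, times = d) # combined index: examined fastest
  conc <- rep(seq_len(d), each = 3)
  lambda <- switch(spec$dependence,
    ETD = pars$lambda[exam],
    CTD = pars$lambda[conc],
    CR = rep(pars$lambda[1], k)
  )
  mu <- rep(pars$mu[1], k)
  M <- examined_template(spec$structure)
  qe <- matrix(0, 3, 3)
  qe[M > 0] <- pars$q_examined[M[M > 0]]
  Q <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      if (conc[a] == conc[b] && exam[a] != exam[b]) {
        Q[a, b] <- qe[exam[a], exam[b]]
      } else if (exam[a] == exam[b] && conc[a] != conc[b] && d > 1) {
        Q[a, b] <- pars$q_concealed[1]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  # cladogenesis tensor as an ordered-pair event list
  alts <- examined_alternatives(spec$structure)
  cs <- ci <- cj <- integer(0)
  crate <- numeric(0)
  for (s in seq_len(k)) {
    if (spec$inheritance == "dual") {
      cs <- c(cs, s); ci <- c(ci, s); cj <- c(cj, s)
      crate <- c(crate, lambda[s])
    } else {
      alt_e <- alts[[exam[s]]]
      if (!length(alt_e)) { # no permitted alternative: degenerate to dual
        cs <- c(cs, s); ci <- c(ci, s); cj <- c(cj, s)
        crate <- c(crate, lambda[s])
        next
      }
      r <- lambda[s] / (2 * length(alt_e))
      for (x in alt_e) {
        xs <- (conc[s] - 1L) * 3L + x # same concealed, examined x
        cs <- c(cs, s, s); ci <- c(ci, s, xs); cj <- c(cj, xs, s)
        crate <- c(crate, r, r)
      }
    }
  }
  list(
    k = k, exam = exam, conc = conc, lambda = lambda, mu = mu, Q = Q,
    clado = list(cs = cs, ci = ci, cj = cj, rate = crate)
  )
}

# tree geometry shared by likelihood calls
sse_tree_data <- function(tree) {
  tree <- validate_phylo(tree)
  ages <- node_ages(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")
  edge <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE] # postorder
  list(
    tree = tree, edge = edge,
    t_child = ages[edge[, 2]], t_parent = ages[edge[, 1]],
    n_tip = length(tree$tip.label)
  )
}

#' Hidden-state SSE log-likelihood
#'
#' Pruning likelihood over combined (examined x concealed) states with
#' anagenetic transitions via the combined rate matrix and cladogenetic
#' daughter-state inheritance via the ordered-pair event tensor. Tips enter
#' with `D = f` on the observed examined state for every concealed state
#' and `E = 1 - f`; the root combines daughters without a speciation-rate
#' factor, weights states by their conditional likelihoods (or uniformly),
#' and conditions on survival of both crown lineages.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param tip_states Tip habitat states (named vector or `taxon`/`habitat`
#'   tibble).
#' @param spec An [sse_model_spec()].
#' @param pars Named list: `lambda` (length per dependence), `mu` (1),
#'   `q_examined` (structure parameter count), `q_concealed` (1, when
#'   d > 1).
#' @param conditioning `"crown_survival"` or `"none"`.
#' @param root_weighting `"conditional"` (likelihood-weighted) or
#'   `"uniform"`.
#' @param engine `"cpp"` (default) or `"R"` (deSolve reference
#'   implementation).
#' @param node_mask Optional internal matrix (internal nodes x combined
#'   states) of 0/1 factors applied at node combination; used for
#'   state-clamped likelihoods.
#' @return Log-likelihood scalar (`-Inf` on numerical failure).
#' @export
sse_loglik <- function(tree, tip_states, spec, pars,
                       conditioning = c("crown_survival", "none"),
                       root_weighting = c("conditional", "uniform"),
                       engine = c("cpp", "R"), node_mask = NULL) {
  conditioning <- match.arg(conditioning)
  root_weighting <- match.arg(root_weighting)
  engine <- match.arg(engine)
  td <- sse_tree_data(tree)
  states <- as_tip_states(tip_states, td$tree)
  rt <- sse_rates(spec, pars)
  k <- rt$k
  fvec <- spec$f[rt$exam]
  tipD <- matrix(0, td$n_tip, k)
  for (i in seq_len(td$n_tip)) {
    sel <- rt$exam == states[i]
    tipD[i, sel] <- fvec[sel]
  }
  E0 <- 1 - fvec
  mask <- node_mask %||% matrix(1, td$n_tip - 1, k)
  res <- if (engine == "cpp") {
    sse_prune_cpp(
      td$edge, td$t_child, td$t_parent, td$n_tip,
      rt$lambda, rt$mu, rt$Q,
      rt$clado$cs - 1L, rt$clado$ci - 1L, rt$clado$cj - 1L, rt$clado$rate,
      tipD, E0, mask, 1e-8, 1e-10
    )
  } else {
    sse_prune_r(td, rt, tipD, E0, mask)
  }
  if (!isTRUE(res$ok)) {
    return(-Inf)
  }
  D <- res$D_root
  E <- res$E_root
  w <- if (root_weighting == "conditional") {
    if (sum(D) <= 0) return(-Inf)
    D / sum(D)
  } else {
    rep(1 / k, k)
  }
  L <- sum(w * D)
  ll <- log(L) + res$logscale
  if (conditioning == "crown_survival") {
    cond <- sum(w * (1 - E)^2)
    if (cond <= 0) return(-Inf)
    ll <- ll - log(cond)
  }
  if (!is.finite(ll)) -Inf else ll
}

# deSolve reference engine (same algorithm, independent integrator)
sse_prune_r <- function(td, rt, tipD, E0, mask) {
  k <- rt$k
  cl <- rt$clado
  rhs <- function(t, y, parms) {
    E <- y[seq_len(k)]
    D <- y[k + seq_len(k)]
    dE <- rt$mu - (rt$lambda + rt$mu) * E + as.vector(rt$Q %*% E)
    dD <- -(rt$lambda + rt$mu) * D + as.vector(rt$Q %*% D)
    for (e in seq_along(cl$rate)) {
      s <- cl$cs[e]; i <- cl$ci[e]; j <- cl$cj[e]; r <- cl$rate[e]
      dE[s] <- dE[s] + r * E[i] * E[j]
      dD[s] <- dD[s] + r * (E[i] * D[j] + D[i] * E[j])
    }
    list(c(dE, dD))
  }
  n_tip <- td$n_tip
  root <- n_tip + 1L
  storeE <- storeD <- vector("list", 2 * n_tip)
  arrived <- integer(2 * n_tip)
  logscale <- 0
  for (r in seq_len(nrow(td$edge))) {
    child <- td$edge[r, 2]
    parent <- td$edge[r, 1]
    y0 <- if (child <= n_tip) {
      c(E0, tipD[child, ])
    } else {
      c(storeE[[child]], storeD[[child]])
    }
    if (td$t_parent[r] > td$t_child[r]) {
      sol <- deSolve::lsoda(y0, c(td$t_child[r], td$t_parent[r]), rhs,
        parms = NULL, rtol = 1e-9, atol = 1e-12
      )
      y <- sol[nrow(sol), -1]
    } else {
      y <- y0
    }
    E <- pmin(pmax(y[seq_len(k)], 0), 1)
    D <- y[k + seq_len(k)]
    sc <- sum(D)
    if (!is.finite(sc) || sc <= 0) return(list(ok = FALSE))
    D <- D / sc
    logscale <- logscale + log(sc)
    if (arrived[parent] == 0) {
      storeE[[parent]] <- E
      storeD[[parent]] <- D
      arrived[parent] <- 1L
    } else {
      Dnew <- numeric(k)
      for (e in seq_along(cl$rate)) {
        s <- cl$cs[e]
        rate <- cl$rate[e]
        if (parent == root && rt$lambda[s] > 0) rate <- rate / rt$lambda[s]
        Dnew[s] <- Dnew[s] + rate * storeD[[parent]][cl$ci[e]] * D[cl$cj[e]]
      }
      Dnew <- Dnew * mask[parent - n_tip, ]
      sc <- sum(Dnew)
      if (!is.finite(sc) || sc <= 0) return(list(ok = FALSE))
      logscale <- logscale + log(sc)
      storeE[[parent]] <- 0.5 * (storeE[[parent]] + E)
      storeD[[parent]] <- Dnew / sc
      arrived[parent] <- 2L
    }
  }
  list(
    ok = TRUE, D_root = storeD[[root]], E_root = storeE[[root]],
    logscale = logscale
  )
}

#' Fit a hidden-state SSE model by multi-start maximum likelihood
#'
#' @inheritParams sse_loglik
#' @param n_starts Number of random starts (default 3, hedging against
#'   local optima).
#' @param seed Seed for start jitter.
#' @return An `sse_fit` list: `spec`, `pars` (ML estimates), `loglik`,
#'   `n_params`, `aic`, `aicc` (sample size = tip count), `converged`,
#'   `n_starts_used`.
#' @export
fit_sse <- function(tree, tip_states, spec, n_starts = 3, seed = 1,
                    conditioning = "crown_survival",
                    root_weighting = "conditional") {
  td <- sse_tree_data(tree)
  states <- as_tip_states(tip_states, td$tree)
  n <- td$n_tip
  crown <- max(td$t_parent)
  lam0 <- max(log(n / 2) / crown, 0.03)
  q0 <- max(3 / sum(td$tree$edge.length), 1e-4)
  layout <- sse_par_layout(spec)
  objfn <- function(par) {
    pars <- sse_unpack(spec, layout, par)
    ll <- sse_loglik(td$tree, states, spec, pars,
      conditioning = conditioning, root_weighting = root_weighting
    )
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  best <- NULL
  used <- 0
  for (s in seq_len(n_starts)) {
    st <- c(
      log(lam0) + runif(spec$n_lambda, -0.8, 0.8),
      log(lam0) + runif(1, -4, -1.5),
      log(q0) + runif(n_examined_params(spec$structure), -1, 1),
      if (spec$d > 1) log(q0) + runif(1, -1, 1)
    )
    fit <- tryCatch(
      {
        f1 <- optim(st, objfn,
          method = "Nelder-Mead",
          control = list(maxit = 800, reltol = 1e-9)
        )
        optim(f1$par, objfn,
          method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10)
        )
      },
      error = function(e) NULL
    )
    if (!is.null(fit)) used <- used + 1
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e9) {
    return(structure(
      list(
        spec = spec, pars = NULL, loglik = -Inf, n_params = spec$n_params,
        aic = Inf, aicc = Inf, converged = FALSE, n_starts_used = used,
        tree = td$tree, tip_states = states
      ),
      class = "sse_fit"
    ))
  }
  pars <- sse_unpack(spec, layout, best$par)
  ll <- -best$value
  structure(
    list(
      spec = spec, pars = pars, loglik = ll, n_params = spec$n_params,
      aic = aic(ll, spec$n_params),
      aicc = aicc(ll, spec$n_params, n),
      converged = TRUE, n_starts_used = used,
      root_weighting = root_weighting, conditioning = conditioning,
      tree = td$tree, tip_states = states
    ),
    class = "sse_fit"
  )
}

sse_par_layout <- function(spec) {
  list(
    n_lambda = spec$n_lambda,
    n_qe = n_examined_params(spec$structure),
    has_qc = spec$d > 1
  )
}

sse_unpack <- function(spec, layout, par) {
  par <- pmin(par, 6) # cap rates at e^6 to keep the ODEs sane
  i <- 0
  lambda <- exp(par[i + seq_len(layout$n_lambda)])
  i <- i + layout$n_lambda
  mu <- exp(par[i + 1])
  i <- i + 1
  qe <- exp(par[i + seq_len(layout$n_qe)])
  i <- i + layout$n_qe
  qc <- if (layout$has_qc) exp(par[i + 1]) else numeric(0)
  list(lambda = lambda, mu = mu, q_examined = qe, q_concealed = qc)
}

#' @export
print.sse_fit <- function(x, ...) {
  cat("<sse_fit> ", x$spec$dependence, "-", x$spec$inheritance, "-",
    x$spec$structure, ": logL = ", format(x$loglik, digits = 6),
    ", AICc = ", format(x$aicc, digits = 6), "\n",
    sep = ""
  )
  if (!is.null(x$pars)) {
    cat("  lambda:", paste(signif(x$pars$lambda, 4), collapse = " "), "\n")
    cat("  mu:", signif(x$pars$mu, 4), "\n")
  }
  invisible(x)
}

#' Fit every model in the 36-model SSE space
#'
#' @inheritParams fit_sse
#' @param d Concealed-state count.
#' @param f Sampling fraction.
#' @param models Optional subset (row filter of [enumerate_model_space()]
#'   by `model` name).
#' @return A tibble (one row per model) with loglik/AICc columns, delta and
#'   Akaike weights, plus a `fit` list-column.
#' @export
fit_sse_model_space <- function(tree, tip_states, d = 3, f = 0.92,
                                models = NULL, n_starts = 3, seed = 1) {
  space <- enumerate_model_space(d = d, f = f)
  if (!is.null(models)) space <- space[space$model %in% models, ]
  fits <- vector("list", nrow(space))
  for (i in seq_len(nrow(space))) {
    fits[[i]] <- fit_sse(tree, tip_states, space$spec[[i]],
      n_starts = n_starts, seed = seed + i
    )
  }
  out <- space[, c("model", "dependence", "inheritance", "structure", "n_params")]
  out$loglik <- vapply(fits, `[[`, 0, "loglik")
  out$aicc <- vapply(fits, `[[`, 0, "aicc")
  out$converged <- vapply(fits, `[[`, TRUE, "converged")
  ok <- is.finite(out$aicc)
  out$delta_aicc <- out$aicc - min(out$aicc[ok])
  w <- exp(-out$delta_aicc / 2)
  w[!ok] <- 0
  out$weight <- w / sum(w)
  out$fit <- fits
  out[order(out$aicc), ]
}

#' Per-node examined-state probabilities under a fitted SSE model
#'
#' For each internal node and each examined habitat state, the likelihood
#' is recomputed with that node clamped to the state (concealed states
#' marginalized); normalized across states this gives the probability that
#' the node produced its descendant data in that habitat state.
#'
#' @param fit An `sse_fit`.
#' @return A tibble with `node` (ape id) and one probability column per
#'   habitat state; rows sum to 1.
#' @export
node_state_probs <- function(fit) {
  stopifnot(inherits(fit, "sse_fit"), fit$converged)
  tree <- fit$tree
  spec <- fit$spec
  rt <- sse_rates(spec, fit$pars)
  n <- length(tree$tip.label)
  lv <- habitat_levels()
  out <- matrix(NA_real_, tree$Nnode, 3)
  for (v in seq_len(tree$Nnode)) {
    lls <- numeric(3)
    for (e in 1:3) {
      mask <- matrix(1, n - 1, rt$k)
      mask[v, rt$exam != e] <- 0
      lls[e] <- sse_loglik(tree, fit$tip_states, spec, fit$pars,
        conditioning = fit$conditioning,
        root_weighting = fit$root_weighting, node_mask = mask
      )
    }
    m <- max(lls)
    p <- exp(lls - m)
    out[v, ] <- p / sum(p)
  }
  colnames(out) <- lv
  res <- as_tibble(out)
  res$node <- n + seq_len(tree$Nnode)
  res[, c("node", lv)]
}

#' Simulate a tree and habitat states under a hidden-state SSE model
#'
#' Exact forward Gillespie simulation over combined states; cladogenesis
#' draws ordered daughter-state pairs from the model's event tensor.
#' Concealed states are simulated but only examined states are returned.
#'
#' @inheritParams sse_loglik
#' @param crown_age Crown age (Ma).
#' @param seed Integer seed.
#' @param n_tips_range Optional reconstructed tip-count range.
#' @param max_attempts Resimulation cap.
#' @param root_state Combined root state (integer), or `NULL` to draw
#'   uniformly.
#' @return A list with `tree`, `tip_states` (tibble `taxon`, `habitat`),
#'   `events` (speciation records with parent/daughter combined states) and
#'   `attempts`.
#' @export
simulate_sse_tree <- function(spec, pars, crown_age, seed, n_tips_range = NULL,
                              max_attempts = 1000, root_state = NULL) {
  rt <- sse_rates(spec, pars)
  sim_condition_loop(seed, max_attempts, n_tips_range, function() {
    sim_sse_once(crown_age, spec, rt, root_state)
  })
}

sim_sse_once <- function(T_total, spec, rt, root_state, max_lineages = 50000) {
  k <- rt$k
  qrates <- rt$Q
  diag(qrates) <- 0
  qtot <- rowSums(qrates)
  # per-state daughter-pair distribution
  clado_by_state <- split(
    data.frame(i = rt$clado$ci, j = rt$clado$cj, r = rt$clado$rate),
    factor(rt$clado$cs, levels = seq_len(k))
  )
  rec <- new_linrec()
  rs <- root_state %||% sample.int(k, 1)
  add_lineage(rec, 0L, 0, state = rs)
  add_lineage(rec, 0L, 0, state = rs)
  alive <- c(1L, 2L)
  t <- 0
  events <- list()
  repeat {
    n <- length(alive)
    if (n == 0 || length(rec$parent) > max_lineages) break
    st <- rec$state[alive]
    rate_lin <- rt$lambda[st] + rt$mu[st] + qtot[st]
    tot <- sum(rate_lin)
    if (tot <= 0) break
    dt <- rexp(1, tot)
    if (t + dt > T_total) break
    t <- t + dt
    pick <- sample.int(n, 1, prob = rate_lin)
    i <- alive[pick]
    s <- rec$state[i]
    u <- runif(1) * rate_lin[pick]
    if (u < rt$lambda[s]) {
      cb <- clado_by_state[[s]]
      ev <- sample.int(nrow(cb), 1, prob = cb$r)
      rec$end[i] <- t
      rec$status[i] <- "split"
      c1 <- add_lineage(rec, i, t, state = cb$i[ev])
      c2 <- add_lineage(rec, i, t, state = cb$j[ev])
      alive <- c(setdiff(alive, i), c1, c2)
      events[[length(events) + 1]] <- c(parent_state = s, d1 = cb$i[ev], d2 = cb$j[ev])
    } else if (u < rt$lambda[s] + rt$mu[s]) {
      rec$end[i] <- t
      rec$status[i] <- "extinct"
      alive <- setdiff(alive, i)
    } else {
      rec$state[i] <- sample.int(k, 1, prob = qrates[s, ])
    }
  }
  if (length(alive) < 2) return(NULL)
  fvec <- spec$f[rt$exam]
  sampled <- alive[runif(length(alive)) < fvec[rec$state[alive]]]
  if (length(sampled) < 2) return(NULL)
  roots <- vapply(sampled, function(i) crown_root_of(rec, i), integer(1))
  if (length(unique(roots)) < 2) return(NULL)
  tree <- prune_reconstructed(rec, T_total, sampled)
  if (is.null(tree)) return(NULL)
  tree <- validate_phylo(tree)
  lin_id <- as.integer(sub("^t", "", tree$tip.label))
  exam_state <- rt$exam[rec$state[lin_id]]
  tip_states <- tibble(
    taxon = tree$tip.label,
    habitat = habitat_levels()[exam_state]
  )
  list(
    tree = tree, tip_states = tip_states,
    events = if (length(events)) do.call(rbind, events) else NULL
  )
}

#' Simulate-and-refit validation of ETD vs CTD
#'
#' Simulates `n_sims` data sets under each fitted model (crown age adjusted
#' so simulated trees match the empirical tip count), refits both models to
#' every data set, and selects by log-likelihood comparison.
#'
#' @param etd_fit,ctd_fit Converged `sse_fit` objects for the ETD and CTD
#'   models.
#' @param n_sims Simulated data sets per generating model (default 30).
#' @param seed Integer seed.
#' @param n_starts Starts per refit.
#' @param size_tolerance Relative tip-count window around the empirical
#'   size.
#' @return A list with `confusion` (tibble: generating model, times ETD
#'   selected, times CTD selected) and `details` (per-replicate tibble).
#' @export
validate_by_simulation <- function(etd_fit, ctd_fit, n_sims = 30, seed = 1,
                                   n_starts = 1, size_tolerance = 0.35) {
  stopifnot(inherits(etd_fit, "sse_fit"), inherits(ctd_fit, "sse_fit"))
  if (!etd_fit$converged || !ctd_fit$converged) {
    abort("Both fits must have converged.")
  }
  n_emp <- length(etd_fit$tree$tip.label)
  range_n <- c(
    max(4, floor(n_emp * (1 - size_tolerance))),
    ceiling(n_emp * (1 + size_tolerance))
  )
  rows <- list()
  for (gen in c("ETD", "CTD")) {
    fit_gen <- if (gen == "ETD") etd_fit else ctd_fit
    # crown age tuned so expected reconstructed size matches the data
    lam_bar <- mean(sse_rates(fit_gen$spec, fit_gen$pars)$lambda)
    mu_bar <- fit_gen$pars$mu[1]
    r_bar <- max(lam_bar - mu_bar, 0.02)
    crown <- log(n_emp / (2 * mean(fit_gen$spec$f))) / r_bar
    for (rep in seq_len(n_sims)) {
      sim <- simulate_sse_tree(fit_gen$spec, fit_gen$pars,
        crown_age = crown,
        seed = seed + 1000 * match(gen, c("ETD", "CTD")) + rep,
        n_tips_range = range_n, max_attempts = 100
      )
      f_etd <- fit_sse(sim$tree, sim$tip_states, etd_fit$spec,
        n_starts = n_starts, seed = seed + rep
      )
      f_ctd <- fit_sse(sim$tree, sim$tip_states, ctd_fit$spec,
        n_starts = n_starts, seed = seed + rep
      )
      rows[[length(rows) + 1]] <- tibble(
        generating = gen,
        loglik_etd = f_etd$loglik,
        loglik_ctd = f_ctd$loglik,
        selected = ifelse(f_etd$loglik >= f_ctd$loglik, "ETD", "CTD")
      )
    }
  }
  details <- bind_rows(rows)
  confusion <- details |>
    group_by(.data$generating) |>
    summarise(
      etd_selected = sum(.data$selected == "ETD"),
      ctd_selected = sum(.data$selected == "CTD"),
      .groups = "drop"
    )
  list(confusion = confusion, details = details, seed = seed)
}
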