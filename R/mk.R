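## Mk (continuous-time Markov) models of habitat evolution on the tree:
## pruning likelihood, ER/SYM/ARD fits with LRT selection, marginal
## ancestral states, and stochastic character mapping by uniformization.

#' Habitat state codes
#'
#' The three habitat-preference states used throughout, encoded 1/2/3 in
#' this order.
#'
#' @return `c("forest", "intermediate", "open")`.
#' @export
habitat_levels <- function() c("forest", "intermediate", "open")

#' Build a 3x3 Mk transition-rate matrix
#'
#' @param structure `"ER"` (1 free rate), `"SYM"` (3: forest-intermediate,
#'   forest-open, intermediate-open), or `"ARD"` (6, row-wise:
#'   q12, q13, q21, q23, q31, q32 with states ordered as
#'   [habitat_levels()]).
#' @param rates Numeric vector of free rates (per Myr, >= 0).
#' @return A 3x3 rate matrix with rows summing to zero.
#' @export
mk_build_Q <- function(structure = c("ER", "SYM", "ARD"), rates) {
  structure <- match.arg(structure)
  need <- c(ER = 1, SYM = 3, ARD = 6)[[structure]]
  if (length(rates) != need) {
    abort(paste0(structure, " needs ", need, " rate(s), got ", length(rates), "."))
  }
  if (any(rates < 0)) abort("Transition rates must be >= 0.")
  Q <- matrix(0, 3, 3, dimnames = list(habitat_levels(), habitat_levels()))
  if (structure == "ER") {
    Q[row(Q) != col(Q)] <- rates
  } else if (structure == "SYM") {
    Q[1, 2] <- Q[2, 1] <- rates[1]
    Q[1, 3] <- Q[3, 1] <- rates[2]
    Q[2, 3] <- Q[3, 2] <- rates[3]
  } else {
    Q[1, 2] <- rates[1]
    Q[1, 3] <- rates[2]
    Q[2, 1] <- rates[3]
    Q[2, 3] <- rates[4]
    Q[3, 1] <- rates[5]
    Q[3, 2] <- rates[6]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(structure) c(ER = 1, SYM = 3, ARD = 6)[[structure]]

# coerce tip states to an integer vector named by taxon
as_tip_states <- function(tip_states, tree = NULL) {
  lv <- habitat_levels()
  if (is.data.frame(tip_states)) {
    stopifnot(all(c("taxon", "habitat") %in% names(tip_states)))
    x <- setNames(as.character(tip_states$habitat), tip_states$taxon)
  } else {
    x <- tip_states
  }
  if (is.character(x)) {
    bad <- setdiff(unique(x), lv)
    if (length(bad)) abort(paste0("Unknown habitat states: ", paste(bad, collapse = ", ")))
    x <- setNames(match(x, lv), names(x))
  }
  nm <- names(x)
  x <- as.integer(x)
  names(x) <- nm
  if (is.null(names(x)) || any(names(x) == "")) abort("Tip states must be named by taxon.")
  if (!is.null(tree)) {
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing)) {
      abort(paste0("Missing habitat state for tips: ", paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(x), tree$tip.label)
    if (length(extra)) {
      abort(paste0("Habitat table lists taxa absent from tree: ", paste(extra, collapse = ", ")))
    }
    x <- x[tree$tip.label]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a habitat trait TSV (columns `taxon`, `habitat`)
#'
#' Values must be `forest`, `intermediate` or `open`; when `tree` is given
#' the taxa must match its tip labels exactly (offenders are listed).
#'
#' @param path Path to a tab-separated file with a header.
#' @param tree Optional `phylo` to validate against.
#' @return A tibble with columns `taxon` and `habitat`.
#' @export
read_habitat_tsv <- function(path, tree = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "habitat") %in% names(df))) {
    abort("Habitat TSV must have columns 'taxon' and 'habitat'.")
  }
  out <- as_tibble(df[, c("taxon", "habitat")])
  as_tip_states(out, tree) # validation side effect
  out
}

# eigen-decomposition cache for P(t) = expm(Q t)
mk_expm_factory <- function(Q) {
  e <- eigen(Q)
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) NULL)
  if (is.null(Vi) || !all(is.finite(Mod(Vi)))) {
    # defective matrix: fall back to series expm per call
    return(function(t) expm_series(Q, t))
  }
  vals <- e$values
  function(t) {
    P <- Re(V %*% (exp(vals * t) * Vi))
    P[P < 0] <- 0
    P[P > 1] <- 1
    P
  }
}

# scaling-and-squaring Taylor expm for small matrices (fallback / oracle)
expm_series <- function(Q, t) {
  A <- Q * t
  s <- max(0, ceiling(log2(max(sum(abs(A)), 1e-12))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:18) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# postorder pruning; returns list(loglik, down = matrix of scaled partials,
# logscale per node, Pmats per edge)
mk_prune <- function(tree, states, Q, root_prior = "equal") {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  pf <- mk_expm_factory(Q)
  logsc <- numeric(nn)
  tree_ord <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree_ord$edge
  elen <- tree_ord$edge.length
  Pm <- vector("list", nrow(edge))
  partial <- matrix(1, nn, 3)
  partial[seq_len(n), ] <- 0
  partial[cbind(seq_len(n), states)] <- 1
  # cladewise edges traversed in reverse visit children before parents
  for (i in rev(seq_len(nrow(edge)))) {
    par <- edge[i, 1]
    ch <- edge[i, 2]
    P <- pf(elen[i])
    Pm[[i]] <- P
    contrib <- as.vector(P %*% partial[ch, ])
    partial[par, ] <- partial[par, ] * contrib
    sc <- sum(partial[par, ])
    if (sc <= 0 || !is.finite(sc)) {
      return(list(loglik = -Inf))
    }
    # rescale parents opportunistically (each parent visited twice; fine)
    logsc[par] <- logsc[par] + log(sc)
    partial[par, ] <- partial[par, ] / sc
  }
  root <- n + 1L
  pr <- mk_root_prior(root_prior, partial[root, ])
  lik <- sum(pr * partial[root, ])
  loglik <- log(lik) + sum(logsc)
  list(
    loglik = loglik, partial = partial, logscale = logsc,
    P = Pm, edge = edge, elen = elen, prior = pr, pf = pf
  )
}

mk_root_prior <- function(root_prior, root_partial) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 3)
    return(root_prior / sum(root_prior))
  }
  switch(root_prior,
    equal = rep(1 / 3, 3),
    fitzjohn = {
      s <- sum(root_partial)
      if (s <= 0) rep(1 / 3, 3) else root_partial / s
    },
    abort("root_prior must be 'equal', 'fitzjohn', or a length-3 vector.")
  )
}

#' Mk log-likelihood of tip habitat states
#'
#' Felsenstein pruning with a 3-state transition-rate matrix; per-branch
#' transition probabilities via the matrix exponential.
#'
#' @param tree A validated `phylo`.
#' @param tip_states Named vector or tibble (`taxon`, `habitat`); every tip
#'   must have a state.
#' @param Q A 3x3 rate matrix, e.g. from [mk_build_Q()].
#' @param root_prior `"equal"` (default), `"fitzjohn"`, or a length-3
#'   probability vector.
#' @return Log-likelihood scalar.
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "equal") {
  states <- as_tip_states(tip_states, tree)
  mk_prune(tree, states, Q, root_prior)$loglik
}

#' Fit ER, SYM and ARD Mk models and select by likelihood-ratio tests
#'
#' Maximum-likelihood fits of the three transition structures, with the
#' standard nested comparisons: SYM vs ER (df 2), ARD vs SYM (df 3), ARD vs
#' ER (df 5). The returned best structure is the most complex one still
#' supported at `alpha`, with ties broken toward fewer parameters.
#'
#' @param tree A validated `phylo` with at least 3 tips.
#' @param tip_states Tip habitat states.
#' @param root_prior Root prior (see [mk_loglik()]).
#' @param alpha LRT significance level.
#' @param n_starts Starts per structure.
#' @param seed Seed for start jitter.
#' @return A list with `best` (structure name), `Q` (fitted matrix of the
#'   best structure), `fits` (tibble: structure, n_params, loglik, aic,
#'   rates list-column) and `lrt` (tibble of the three comparisons).
#' @export
fit_mk <- function(tree, tip_states, root_prior = "equal", alpha = 0.05,
                   n_starts = 3, seed = 1) {
  tree <- validate_phylo(tree)
  states <- as_tip_states(tip_states, tree)
  if (length(unique(states)) == 1) {
    warn("Single observed state: returning ER with rate ~ 0.")
    Q <- mk_build_Q("ER", 1e-10)
    ll <- mk_loglik(tree, states, Q, root_prior)
    fits <- tibble(
      structure = "ER", n_params = 1, loglik = ll,
      aic = aic(ll, 1), rates = list(1e-10)
    )
    return(list(best = "ER", Q = Q, fits = fits, lrt = tibble()))
  }
  total_len <- sum(tree$edge.length)
  q0 <- max(3 / total_len, 1e-4)
  fit_structure <- function(structure) {
    np <- n_free_rates(structure)
    objfn <- function(par) {
      Q <- mk_build_Q(structure, exp(pmin(par, 8)))
      ll <- mk_prune(tree, states, Q, root_prior)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    set.seed(seed + np)
    best <- NULL
    for (s in seq_len(n_starts)) {
      st <- log(q0) + runif(np, -1.5, 1.5)
      if (np == 1) {
        fit <- optim(st, objfn,
          method = "Brent", lower = -22, upper = 8,
          control = list(reltol = 1e-12)
        )
      } else {
        fit <- optim(st, objfn,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)
        )
        fit <- optim(fit$par, objfn,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)
        )
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    list(rates = exp(best$par), loglik = -best$value, n_params = np)
  }
  fits <- lapply(c("ER", "SYM", "ARD"), fit_structure)
  names(fits) <- c("ER", "SYM", "ARD")
  tab <- tibble(
    structure = names(fits),
    n_params = vapply(fits, `[[`, 0, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    rates = lapply(fits, `[[`, "rates")
  )
  tab$aic <- aic(tab$loglik, tab$n_params)
  # guard tiny negative improvements from optimizer noise
  ll <- setNames(tab$loglik, tab$structure)
  ll["SYM"] <- max(ll["SYM"], ll["ER"])
  ll["ARD"] <- max(ll["ARD"], ll["SYM"], ll["ER"])
  lrt_tab <- bind_rows(
    mutate(lrt(ll["ER"], ll["SYM"], 2), comparison = "SYM vs ER"),
    mutate(lrt(ll["SYM"], ll["ARD"], 3), comparison = "ARD vs SYM"),
    mutate(lrt(ll["ER"], ll["ARD"], 5), comparison = "ARD vs ER")
  )
  sig <- setNames(lrt_tab$p_value < alpha, lrt_tab$comparison)
  best <- if (sig[["ARD vs SYM"]] && sig[["ARD vs ER"]]) {
    "ARD"
  } else if (sig[["SYM vs ER"]]) {
    "SYM"
  } else {
    "ER"
  }
  list(
    best = best,
    Q = mk_build_Q(best, fits[[best]]$rates),
    fits = tab,
    lrt = lrt_tab[, c("comparison", "statistic", "df", "p_value")]
  )
}

#' Marginal ancestral state probabilities
#'
#' Standard two-pass (inside/outside) marginal reconstruction: each internal
#' node's row is the probability distribution of its state given all tip
#' data, the rate matrix and the root prior.
#'
#' @inheritParams mk_loglik
#' @return A tibble with columns `node` (ape node id), plus one probability
#'   column per habitat state; rows sum to 1.
#' @export
ancestral_marginals <- function(tree, tip_states, Q, root_prior = "equal") {
  tree <- validate_phylo(tree)
  states <- as_tip_states(tip_states, tree)
  pr <- mk_prune(tree, states, Q, root_prior)
  if (!is.finite(pr$loglik)) abort("Likelihood is -Inf; cannot compute marginals.")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  edge <- pr$edge
  # outside (above) partials
  up <- matrix(NA_real_, nn, 3)
  up[n + 1L, ] <- pr$prior
  children <- vector("list", nn)
  for (i in seq_len(nrow(edge))) {
    children[[edge[i, 1]]] <- c(children[[edge[i, 1]]], i)
  }
  for (i in seq_len(nrow(edge))) { # cladewise: parents before children
    par <- edge[i, 1]
    ch <- edge[i, 2]
    sibs <- setdiff(children[[par]], i)
    above <- up[par, ]
    for (j in sibs) {
      sib_contrib <- as.vector(pr$P[[j]] %*% pr$partial[edge[j, 2], ])
      above <- above * sib_contrib
    }
    v <- as.vector(t(pr$P[[i]]) %*% above)
    s <- sum(v)
    up[ch, ] <- if (s > 0) v / s else rep(1 / 3, 3)
  }
  marg <- up * pr$partial
  marg <- marg / rowSums(marg)
  colnames(marg) <- habitat_levels()
  out <- as_tibble(marg)
  out$node <- seq_len(nn)
  out[, c("node", habitat_levels())]
}

#' Stochastic character maps
#'
#' Draws full habitat histories conditional on the tip states and a fixed
#' (empirical) rate matrix: node states are sampled from their joint
#' conditional distribution by a backward-filtering forward-sampling pass,
#' and each branch history conditional on its endpoint states is sampled by
#' uniformization.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps (>= 1).
#' @param seed Integer seed; identical seeds give identical map sets.
#' @param keep_paths Keep the full per-edge piecewise histories (lists of
#'   state/duration vectors). Defaults to `TRUE` for `n_maps <= 500`;
#'   otherwise only per-map transition counts, state occupancy times and
#'   node states are retained.
#' @return A `simmap_set`: list with `tree`, `node_states` (n_maps x nodes
#'   matrix), `counts` (n_maps x 9, ordered state pairs), `times`
#'   (n_maps x 3, time in state), and optionally `paths`.
#' @export
stochastic_map <- function(tree, tip_states, Q, n_maps = 100, seed = 1,
                           root_prior = "equal", keep_paths = n_maps <= 500) {
  stopifnot(n_maps >= 1)
  tree <- validate_phylo(tree)
  states <- as_tip_states(tip_states, tree)
  pr <- mk_prune(tree, states, Q, root_prior)
  if (!is.finite(pr$loglik)) abort("Likelihood is -Inf; cannot map.")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  edge <- pr$edge
  elen <- pr$elen
  set.seed(seed)
  Omega <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(3) + Q / Omega
  Rpow <- list(diag(3), R) # R^0, R^1, extended on demand
  getRpow <- function(k) {
    while (length(Rpow) < k + 1) {
      Rpow[[length(Rpow) + 1]] <<- Rpow[[length(Rpow)]] %*% R
    }
    Rpow[[k + 1]]
  }
  pair_names <- as.vector(outer(habitat_levels(), habitat_levels(),
    function(a, b) paste0(a, "->", b)
  ))
  node_states <- matrix(NA_integer_, n_maps, nn)
  counts <- matrix(0, n_maps, 9, dimnames = list(NULL, pair_names))
  times <- matrix(0, n_maps, 3, dimnames = list(NULL, habitat_levels()))
  paths <- if (keep_paths) vector("list", n_maps) else NULL
  root <- n + 1L
  root_p <- pr$prior * pr$partial[root, ]
  root_p <- root_p / sum(root_p)
  for (m in seq_len(n_maps)) {
    ns <- integer(nn)
    ns[root] <- sample.int(3, 1, prob = root_p)
    cnt <- matrix(0, 3, 3)
    tis <- numeric(3)
    mpaths <- if (keep_paths) vector("list", nrow(edge)) else NULL
    ok <- TRUE
    for (i in seq_len(nrow(edge))) { # preorder
      par <- edge[i, 1]
      ch <- edge[i, 2]
      p <- pr$P[[i]][ns[par], ] * pr$partial[ch, ]
      if (sum(p) <= 0) {
        ok <- FALSE
        break
      }
      ns[ch] <- sample.int(3, 1, prob = p)
      path <- sample_mk_path(ns[par], ns[ch], elen[i], pr$P[[i]], Omega, R, getRpow)
      if (is.null(path)) {
        ok <- FALSE
        break
      }
      st <- path$states
      du <- path$durations
      for (seg in seq_along(du)) tis[st[seg]] <- tis[st[seg]] + du[seg]
      if (length(st) > 1) {
        for (seg in 2:length(st)) cnt[st[seg - 1], st[seg]] <- cnt[st[seg - 1], st[seg]] + 1
      }
      if (keep_paths) mpaths[[i]] <- path
    }
    if (!ok) {
      abort("Stochastic map sampling failed (numerical underflow on a branch).")
    }
    node_states[m, ] <- ns
    counts[m, ] <- as.vector(cnt)
    times[m, ] <- tis
    if (keep_paths) paths[[m]] <- mpaths
  }
  structure(
    list(
      tree = tree, edge = edge, node_states = node_states,
      counts = counts, times = times, paths = paths, Q = Q, seed = seed
    ),
    class = "simmap_set"
  )
}

# branch history i -> j over duration t by uniformization
sample_mk_path <- function(i, j, t, P, Omega, R, getRpow) {
  pij <- P[i, j]
  if (pij <= 0) return(NULL)
  a <- Omega * t
  u <- runif(1) * pij
  wn <- exp(-a)
  cum <- wn * (i == j)
  njump <- 0L
  while (cum < u && njump < 10000L) {
    njump <- njump + 1L
    wn <- wn * a / njump
    cum <- cum + wn * getRpow(njump)[i, j]
  }
  if (njump == 0L) {
    return(list(states = i, durations = t))
  }
  # sample the uniformized chain conditional on endpoints
  s <- integer(njump + 1)
  s[1] <- i
  for (k in seq_len(njump)) {
    back <- getRpow(njump - k)[, j]
    p <- R[s[k], ] * back
    s[k + 1] <- sample.int(3, 1, prob = p)
  }
  jumps <- sort(runif(njump)) * t
  # collapse virtual (self) jumps
  keep <- which(diff(s) != 0)
  if (!length(keep)) {
    return(list(states = i, durations = t))
  }
  change_times <- jumps[keep]
  st <- c(i, s[keep + 1])
  du <- diff(c(0, change_times, t))
  list(states = st, durations = du)
}

#' Summarize a set of stochastic maps
#'
#' @param maps A `simmap_set` from [stochastic_map()].
#' @return A list with `transitions` (tibble: from, to, mean_count),
#'   `time_in_state` (tibble: habitat, proportion, summing to 1) and
#'   `n_maps`.
#' @export
summarize_maps <- function(maps) {
  stopifnot(inherits(maps, "simmap_set"))
  lv <- habitat_levels()
  mean_counts <- colMeans(maps$counts)
  trans <- tibble(
    from = rep(lv, times = 3),
    to = rep(lv, each = 3),
    mean_count = as.vector(matrix(mean_counts, 3, 3))
  )
  trans <- trans[trans$from != trans$to, ]
  tprop <- colMeans(maps$times)
  tprop <- tprop / sum(tprop)
  list(
    transitions = trans,
    time_in_state = tibble(habitat = lv, proportion = as.vector(tprop)),
    n_maps = nrow(maps$counts)
  )
}

# forward-simulate Mk states down the tree; returns named vector tip -> state
simulate_mk_states <- function(tree, Q, root_state = NULL, seed = 1) {
  set.seed(seed)
  tree_ord <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  pf <- mk_expm_factory(Q)
  st <- integer(nn)
  st[n + 1L] <- root_state %||% sample.int(3, 1)
  for (i in seq_len(nrow(tree_ord$edge))) {
    par <- tree_ord$edge[i, 1]
    ch <- tree_ord$edge[i, 2]
    P <- pf(tree_ord$edge.length[i])
    st[ch] <- sample.int(3, 1, prob = P[st[par], ])
  }
  setNames(st[seq_len(n)], tree$tip.label)
}
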