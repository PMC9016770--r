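## Forward (Gillespie) simulators for every model class, pruned to the
## reconstructed tree. All simulators are exact for their model class:
## events are drawn lineage-by-lineage on the complete tree, extinct
## lineages and unsampled extant tips are then dropped, which preserves
## ultrametricity. Time-inhomogeneous rates use thinning with a windowed
## rate bound. Every simulator is reproducible bit-for-bit from its seed.

# internal record growth helper ------------------------------------------------

new_linrec <- function() {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)
  env$birth <- numeric(0)
  env$end <- numeric(0)
  env$status <- character(0) # "alive", "extinct", "split"
  env$state <- integer(0)
  env
}

add_lineage <- function(rec, parent, birth, state = NA_integer_) {
  id <- length(rec$parent) + 1L
  rec$parent[id] <- parent
  rec$birth[id] <- birth
  rec$end[id] <- NA_real_
  rec$status[id] <- "alive"
  rec$state[id] <- state
  id
}

# build a phylo from lineage records (complete tree, tips at their end times)
records_to_phylo <- function(rec, T_total) {
  n_lin <- length(rec$parent)
  alive <- rec$status == "alive"
  rec$end[alive] <- T_total
  children <- split(seq_len(n_lin), factor(rec$parent, levels = seq_len(n_lin)))
  str <- character(n_lin)
  label <- character(n_lin)
  tip_i <- 0L
  # children are always born after parents, so reverse id order works
  for (i in rev(seq_len(n_lin))) {
    len <- rec$end[i] - rec$birth[i]
    kids <- children[[i]]
    if (rec$status[i] == "split") {
      str[i] <- paste0("(", str[kids[1]], ",", str[kids[2]], "):", format(len, digits = 12))
    } else {
      tip_i <- tip_i + 1L
      label[i] <- paste0("t", i)
      str[i] <- paste0(label[i], ":", format(len, digits = 12))
    }
  }
  roots <- which(rec$parent == 0L)
  txt <- paste0("(", str[roots[1]], ",", str[roots[2]], ");")
  tree <- ape::read.tree(text = txt)
  tree
}

# prune a complete simulated tree to the reconstructed, sampled tree.
# sampled_of: function(lineage ids of alive tips) -> logical keep
prune_reconstructed <- function(rec, T_total, keep_ids) {
  tree <- records_to_phylo(rec, T_total)
  keep <- paste0("t", keep_ids)
  keep <- intersect(keep, tree$tip.label)
  if (length(keep) < 2) return(NULL)
  sub <- ape::keep.tip(tree, keep)
  sub
}

# crown-survival check: at least one kept tip descends from each of the two
# crown lineages (ids 1 and 2)
crown_root_of <- function(rec, id) {
  while (rec$parent[id] != 0L) id <- rec$parent[id]
  id
}

# generic acceptance loop
sim_condition_loop <- function(seed, max_attempts, n_tips_range, one_sim) {
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    out <- one_sim()
    if (is.null(out)) next
    n <- length(out$tree$tip.label)
    if (!is.null(n_tips_range) &&
      (n < n_tips_range[1] || n > n_tips_range[2])) {
      next
    }
    out$attempts <- attempt
    return(out)
  }
  abort(paste0(
    "Simulation failed to meet conditioning in ", max_attempts,
    " attempts (crown survival and/or tip-count range too improbable)."
  ))
}

# core forward simulation with tree-wide time-dependent rates.
# lam_fn/mu_fn take forward time (0 = crown start) and return rates.
# boundaries: forward times at which rates may jump (thinning windows align).
sim_bdtime_once <- function(T_total, lam_fn, mu_fn, f, boundaries = numeric(0),
                            max_lineages = 100000) {
  rec <- new_linrec()
  add_lineage(rec, 0L, 0)
  add_lineage(rec, 0L, 0)
  alive <- c(1L, 2L)
  t <- 0
  knots <- sort(unique(c(boundaries, seq(0, T_total, length.out = 65), T_total)))
  while (t < T_total && length(alive) > 0) {
    if (length(rec$parent) > max_lineages) return(NULL)
    t_win <- min(knots[knots > t + 1e-12], T_total)
    # rate bound over (t, t_win]
    ss <- seq(t, t_win, length.out = 8)
    lmax <- max(lam_fn(ss)) * 1.2 + 1e-10
    mmax <- max(mu_fn(ss)) * 1.2 + 1e-10
    B <- length(alive) * (lmax + mmax)
    dt <- rexp(1, B)
    if (t + dt > t_win) {
      t <- t_win
      next
    }
    t <- t + dt
    lam <- lam_fn(t)
    mu <- mu_fn(t)
    u <- runif(1) * (lmax + mmax)
    if (u < lam) {
      i <- alive[sample.int(length(alive), 1)]
      rec$end[i] <- t
      rec$status[i] <- "split"
      c1 <- add_lineage(rec, i, t)
      c2 <- add_lineage(rec, i, t)
      alive <- c(setdiff(alive, i), c1, c2)
    } else if (u < lam + mu) {
      i <- alive[sample.int(length(alive), 1)]
      rec$end[i] <- t
      rec$status[i] <- "extinct"
      alive <- setdiff(alive, i)
    }
    # else thinning rejection: no event
  }
  if (length(alive) < 2) return(NULL)
  sampled <- alive[runif(length(alive)) < f]
  if (length(sampled) < 2) return(NULL)
  roots <- vapply(sampled, function(i) crown_root_of(rec, i), integer(1))
  if (length(unique(roots)) < 2) return(NULL) # crown survival
  tree <- prune_reconstructed(rec, T_total, sampled)
  if (is.null(tree)) return(NULL)
  list(tree = validate_phylo(tree), rec = rec, sampled = sampled)
}

#' Simulate a reconstructed tree under a (possibly time/env-dependent)
#' birth-death model
#'
#' Forward Gillespie simulation of the complete tree starting from the two
#' crown lineages, followed by pruning of extinct lineages and
#' Bernoulli(`f`) subsampling of extant tips. Conditioning is on both crown
#' lineages leaving sampled descendants, plus an optional tip-count range
#' (by resimulation).
#'
#' @param spec A [bd_model_spec()] (its `f` is used for tip sampling).
#' @param crown_age Crown age (Ma).
#' @param seed Integer seed (mandatory).
#' @param n_tips_range Optional `c(min, max)` for the reconstructed tip
#'   count.
#' @param max_attempts Resimulation cap.
#' @return A list with `tree` (a `phylo`) and `attempts`.
#' @export
simulate_bd_tree <- function(spec, crown_age, seed, n_tips_range = NULL,
                             max_attempts = 1000) {
  stopifnot(inherits(spec, "bd_model_spec"))
  lamA <- spec$lambda_fn
  muA <- if (is.null(spec$mu_fn)) rate_constant(0) else spec$mu_fn
  # rate functions are indexed by age; convert to forward time
  lam_fn <- function(tf) eval_rate(lamA, crown_age - tf)
  mu_fn <- function(tf) eval_rate(muA, crown_age - tf)
  sim_condition_loop(seed, max_attempts, n_tips_range, function() {
    sim_bdtime_once(crown_age, lam_fn, mu_fn, spec$f)
  })
}

#' Simulate a reconstructed tree under an episodic birth-death model
#'
#' @param model An [episodic_model()].
#' @inheritParams simulate_bd_tree
#' @return A list with `tree` and `attempts`.
#' @export
simulate_episodic_tree <- function(model, crown_age, seed, n_tips_range = NULL,
                                   max_attempts = 1000) {
  stopifnot(inherits(model, "episodic_model"))
  idx_of <- function(age) findInterval(age, model$shift_times) + 1L
  lam_fn <- function(tf) model$lambda[idx_of(pmax(crown_age - tf, 0))]
  mu_fn <- function(tf) model$mu[idx_of(pmax(crown_age - tf, 0))]
  boundaries <- crown_age - model$shift_times
  sim_condition_loop(seed, max_attempts, n_tips_range, function() {
    sim_bdtime_once(crown_age, lam_fn, mu_fn, model$f, boundaries = boundaries)
  })
}

#' Simulate a reconstructed tree under a diversity-dependent model
#'
#' Exact Gillespie simulation with rates re-evaluated at every change of the
#' standing species number.
#'
#' @param model A [dd_model()].
#' @inheritParams simulate_bd_tree
#' @return A list with `tree` and `attempts`.
#' @export
simulate_dd_tree <- function(model, crown_age, seed, n_tips_range = NULL,
                             max_attempts = 1000) {
  stopifnot(inherits(model, "dd_model"))
  sim_condition_loop(seed, max_attempts, n_tips_range, function() {
    sim_dd_once(crown_age, model)
  })
}

sim_dd_once <- function(T_total, model, max_lineages = 100000) {
  rec <- new_linrec()
  add_lineage(rec, 0L, 0)
  add_lineage(rec, 0L, 0)
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    n <- length(alive)
    if (n == 0 || length(rec$parent) > max_lineages) break
    lam <- dd_lambda_n(model, n)
    mu <- dd_mu_n(model, n)
    tot <- n * (lam + mu)
    if (tot <= 0) {
      t <- T_total
      break
    }
    dt <- rexp(1, tot)
    if (t + dt > T_total) break
    t <- t + dt
    i <- alive[sample.int(n, 1)]
    if (runif(1) < lam / (lam + mu)) {
      rec$end[i] <- t
      rec$status[i] <- "split"
      c1 <- add_lineage(rec, i, t)
      c2 <- add_lineage(rec, i, t)
      alive <- c(setdiff(alive, i), c1, c2)
    } else {
      rec$end[i] <- t
      rec$status[i] <- "extinct"
      alive <- setdiff(alive, i)
    }
  }
  if (length(alive) < 2) return(NULL)
  sampled <- alive[runif(length(alive)) < model$f]
  if (length(sampled) < 2) return(NULL)
  roots <- vapply(sampled, function(i) crown_root_of(rec, i), integer(1))
  if (length(unique(roots)) < 2) return(NULL)
  tree <- prune_reconstructed(rec, T_total, sampled)
  if (is.null(tree)) return(NULL)
  list(tree = validate_phylo(tree), n_extant = length(alive))
}

#' Jitter the node ages of an ultrametric tree
#'
#' Multiplies each internal node age by an independent log-normal factor,
#' then restores parent-older-than-child ordering, keeping the tree
#' ultrametric. Emulates posterior divergence-time uncertainty around a
#' consensus tree.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param sd Standard deviation of the log-normal age factors.
#' @param seed Integer seed.
#' @return A jittered ultrametric `phylo` with the same topology.
#' @export
jitter_node_ages <- function(tree, sd = 0.05, seed = 1) {
  tree <- validate_phylo(tree)
  set.seed(seed)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  ages[(n + 1):length(ages)] <- ages[(n + 1):length(ages)] *
    exp(stats::rnorm(tree$Nnode, 0, sd))
  # enforce parent strictly older than child (preorder)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]
    ch <- ord$edge[i, 2]
    if (ch > n && ages[ch] >= ages[par]) {
      ages[ch] <- ages[par] * 0.99
    }
  }
  out <- tree
  out$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  validate_phylo(out)
}

#' Synthetic paleoenvironment curves
#'
#' Smooth deterministic proxy curves spanning an age range, emulating the
#' shapes of Cenozoic proxy series: a cooling trend (values increase
#' monotonically with age, like a temperature proxy), an oscillation with a
#' fixed period, or a constant.
#'
#' @param kind `"cooling_trend"`, `"oscillation"` or `"constant"`.
#' @param seed Integer seed (perturbs phase/amplitude slightly).
#' @param age_range Age span in Ma (default 0 to 25).
#' @param n_samples Number of samples.
#' @param period Oscillation period in Myr (oscillation kind only).
#' @return An [env_curve()].
#' @export
synthetic_env_curve <- function(kind = c("cooling_trend", "oscillation", "constant"),
                                seed = 1, age_range = c(0, 25), n_samples = 251,
                                period = 2.5) {
  kind <- match.arg(kind)
  set.seed(seed)
  age <- seq(age_range[1], age_range[2], length.out = n_samples)
  value <- switch(kind,
    cooling_trend = {
      phase <- runif(1, 0, 2 * pi)
      # strictly increasing with age: derivative 0.45 - 0.3 >= 0.15
      12 + 0.45 * age + 0.3 * sin(age + phase)
    },
    oscillation = {
      phase <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.8, 1.2)
      15 + amp * sin(2 * pi * age / period + phase)
    },
    constant = rep(15, length(age))
  )
  env_curve(tibble(age_Ma = age, value = value), smooth_df = n_samples)
}

#' Study-shaped synthetic fixture bundle
#'
#' Generates the package's stand-in for an empirical data deposit: an
#' ultrametric tree of roughly 94 tips with crown age 20 Ma and sampling
#' fraction 0.92, made of two nested focal clades ("clade_I", around 40
#' tips, crown about 19.2 Ma, simulated under an episodic birth-death
#' process with two downshifts; "clade_II", around 54 tips, crown about
#' 17.5 Ma, simulated under linear diversity-dependent speciation with
#' lambda0 = 0.3 and K = 70), three-state habitat labels simulated under an
#' all-rates-different Mk process, and a smooth temperature-like proxy curve
#' spanning 0 to 25 Ma.
#'
#' @param seed Integer seed.
#' @return A list with `tree`, `clades` (named list of tip-label vectors),
#'   `habitats` (tibble `taxon`, `habitat`), `env` (named list of
#'   `env_curve`s), `f`, and `params` (generator settings).
#' @export
make_fixture_study <- function(seed = 1) {
  f <- 0.92
  # clade I: episodic, two downshifts (old fast phase, then slowdowns)
  epi <- episodic_model(
    shift_times = c(2, 17),
    rates = c(0.013, 0.10, 0.548),
    turnovers = c(0.163, 0.5, 0.503),
    f = f
  )
  simI <- simulate_episodic_tree(epi, crown_age = 19.2, seed = seed,
    n_tips_range = c(28, 52), max_attempts = 4000
  )
  ddm <- dd_model("DDL", lambda0 = 0.3, K = 70, f = f)
  simII <- simulate_dd_tree(ddm, crown_age = 17.5, seed = seed + 1,
    n_tips_range = c(44, 64), max_attempts = 4000
  )
  treeI <- simI$tree
  treeII <- simII$tree
  nI <- length(treeI$tip.label)
  nII <- length(treeII$tip.label)
  treeI$tip.label <- sprintf("sp%03d", seq_len(nI))
  treeII$tip.label <- sprintf("sp%03d", nI + seq_len(nII))
  crown <- 20
  nwkI <- sub(";$", "", write_newick(treeI))
  nwkII <- sub(";$", "", write_newick(treeII))
  tree <- parse_newick(paste0(
    "(", nwkI, ":", crown - 19.2, ",", nwkII, ":", crown - 17.5, ");"
  ))
  # habitat states: ARD-like Mk simulation, rerun until all 3 states present
  Q <- mk_build_Q("ARD", c(0.020, 0.030, 0.045, 0.025, 0.008, 0.035))
  for (k in 1:50) {
    states <- simulate_mk_states(tree, Q, root_state = 1L, seed = seed + 100 + k)
    if (length(unique(states)) == 3) break
  }
  habitats <- tibble(
    taxon = tree$tip.label,
    habitat = habitat_levels()[states[tree$tip.label]]
  )
  env <- list(
    temperature = synthetic_env_curve("cooling_trend", seed = seed),
    co2 = synthetic_env_curve("oscillation", seed = seed + 1)
  )
  list(
    tree = tree,
    clades = list(clade_I = treeI$tip.label, clade_II = treeII$tip.label),
    habitats = habitats,
    env = env,
    f = f,
    params = list(
      seed = seed, crown_age = crown, episodic = epi[c("shift_times", "rates", "turnovers")],
      dd = ddm[c("variant", "lambda0", "K")],
      mk_Q = Q
    )
  )
}

#' Write a fixture bundle to a directory
#'
#' Writes `tree.nwk`, `habitats.tsv`, `env_<name>.csv`, `clades.json` and
#' `manifest.json` (seed and generator parameters) in plain-text formats.
#'
#' @param fixture Output of [make_fixture_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_study <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(write_newick(fixture$tree), file.path(dir, "tree.nwk"))
  utils::write.table(fixture$habitats, file.path(dir, "habitats.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (nm in names(fixture$env)) {
    write.csv(fixture$env[[nm]]$samples, file.path(dir, paste0("env_", nm, ".csv")),
      row.names = FALSE
    )
  }
  jsonlite::write_json(fixture$clades, file.path(dir, "clades.json"))
  manifest <- fixture$params
  manifest$f <- fixture$f
  manifest$mk_Q <- as.vector(manifest$mk_Q)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
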