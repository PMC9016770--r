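test_that("ER transition probability matches the closed form on one branch", {
  Q <- mk_build_Q("ER", 0.1)
  P <- paleodiv:::mk_expm_factory(Q)(1)
  expect_equal(P[1, 1], 1 / 3 + 2 / 3 * exp(-0.3), tolerance = 1e-10)
  expect_equal(P[1, 2], 1 / 3 - 1 / 3 * exp(-0.3), tolerance = 1e-10)
})

test_that("Q builders respect structure constraints", {
  expect_equal(sum(mk_build_Q("ER", 0.2)), 0)
  Qs <- mk_build_Q("SYM", c(0.1, 0.2, 0.3))
  expect_equal(Qs[1, 2], Qs[2, 1])
  expect_equal(rowSums(Qs), c(forest = 0, intermediate = 0, open = 0))
  Qa <- mk_build_Q("ARD", 1:6 / 10)
  expect_equal(rowSums(Qa), c(forest = 0, intermediate = 0, open = 0))
  expect_error(mk_build_Q("SYM", c(0.1, 0.2)), "3 rate")
  expect_error(mk_build_Q("ER", -1), ">= 0")
})

test_that("pruning likelihood and marginals match exhaustive enumeration", {
  tree <- tree_5tip()
  st <- c(A = "forest", B = "intermediate", C = "forest", D = "open", E = "open")
  Q <- mk_build_Q("ARD", c(0.12, 0.05, 0.3, 0.14, 0.08, 0.2))
  en <- oracle_mk_enum(tree, st, Q)
  expect_equal(mk_loglik(tree, st, Q), en$loglik, tolerance = 1e-10)
  marg <- ancestral_marginals(tree, st, Q)
  expect_equal(
    unname(as.matrix(marg[, habitat_levels()])),
    unname(en$marginals),
    tolerance = 1e-10
  )
  expect_equal(rowSums(as.matrix(marg[, habitat_levels()])), rep(1, nrow(marg)))
})

test_that("likelihood limits behave: q -> 0 and star-tree factorization", {
  tree <- tree_4tip()
  mono <- c(A = "forest", B = "forest", C = "forest", D = "forest")
  Q0 <- mk_build_Q("ER", 1e-12)
  # monomorphic data, no change: loglik -> log(prior of that state)
  expect_equal(mk_loglik(tree, mono, Q0), log(1 / 3), tolerance = 1e-6)
  marg <- ancestral_marginals(tree, mono, Q0)
  expect_true(all(marg$forest > 1 - 1e-8))
  # star-like factorization: per-tip branch likelihoods multiply
  Q <- mk_build_Q("ER", 0.15)
  P <- paleodiv:::mk_expm_factory(Q)(2)
  st <- c(A = 1, B = 2, C = 3, D = 1)
  by_hand <- log(sum(sapply(1:3, function(r) {
    (1 / 3) * prod(P[r, st])
  })))
  # binary comb with zero-length internal branches is equivalent to a star
  comb <- parse_newick("(((A:2,B:2):0,C:2):0,D:2);")
  expect_equal(mk_loglik(comb, habitat_levels()[st] |> setNames(names(st)), Q),
    by_hand,
    tolerance = 1e-9
  )
})

test_that("fit_mk matches ape::ace likelihoods and selects by LRT", {
  tree <- tree_5tip()
  st <- c(A = "forest", B = "intermediate", C = "forest", D = "open", E = "open")
  fit <- fit_mk(tree, st, n_starts = 2, seed = 1)
  expect_true(fit$best %in% c("ER", "SYM", "ARD"))
  expect_true(all(fit$lrt$statistic >= 0))
  # ape::ace sums (not averages) over root states: offset log(3)
  a_er <- suppressWarnings(
    ape::ace(factor(st[tree$tip.label]), tree, type = "discrete", model = "ER")
  )
  er_ll <- unname(fit$fits$loglik[fit$fits$structure == "ER"])
  expect_equal(er_ll, unname(a_er$loglik) - log(3), tolerance = 1e-4)
  # degenerate data: single state
  mono <- c(A = "open", B = "open", C = "open", D = "open", E = "open")
  expect_warning(fm <- fit_mk(tree, mono), "Single observed state")
  expect_equal(fm$best, "ER")
})

test_that("ER data does not spuriously prefer ARD (type-I control)", {
  tree <- simulate_bd_tree(bd_model_spec(rate_constant(0.25), NULL, f = 1),
    crown_age = 14, seed = 8, n_tips_range = c(50, 120)
  )$tree
  Q <- mk_build_Q("ER", 0.06)
  hits <- 0
  n_rep <- 10
  for (i in seq_len(n_rep)) {
    st <- paleodiv:::simulate_mk_states(tree, Q, seed = 900 + i)
    st <- setNames(habitat_levels()[st], names(st))
    if (length(unique(st)) < 2) next
    fit <- suppressWarnings(fit_mk(tree, st, n_starts = 1, seed = i))
    if (fit$best != "ARD") hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.7)
})

test_that("missing or mismatched tip states raise informative errors", {
  tree <- tree_4tip()
  expect_error(
    mk_loglik(tree, c(A = "forest", B = "open"), mk_build_Q("ER", 0.1)),
    "Missing habitat state.*C"
  )
  expect_error(
    mk_loglik(tree, c(A = "forest", B = "open", C = "forest", D = "open", Z = "open"),
      mk_build_Q("ER", 0.1)
    ),
    "absent from tree.*Z"
  )
  expect_error(
    paleodiv:::as_tip_states(c(A = "woodland")),
    "Unknown habitat"
  )
})

test_that("stochastic maps are seed-deterministic and tip-consistent", {
  tree <- tree_5tip()
  st <- c(A = "forest", B = "intermediate", C = "forest", D = "open", E = "open")
  Q <- mk_build_Q("SYM", c(0.1, 0.05, 0.12))
  m1 <- stochastic_map(tree, st, Q, n_maps = 30, seed = 11)
  m2 <- stochastic_map(tree, st, Q, n_maps = 30, seed = 11)
  expect_identical(m1$node_states, m2$node_states)
  expect_identical(m1$counts, m2$counts)
  # tip rows of node_states agree with the data
  si <- paleodiv:::as_tip_states(st, tree)
  for (i in seq_along(si)) expect_true(all(m1$node_states[, i] == si[i]))
  # monomorphic, vanishing rates: every map has zero transitions
  mono <- c(A = "open", B = "open", C = "open", D = "open", E = "open")
  mm <- stochastic_map(tree, mono, mk_build_Q("ER", 1e-12), n_maps = 10, seed = 1)
  expect_equal(sum(mm$counts), 0)
  summ <- summarize_maps(mm)
  expect_equal(summ$time_in_state$proportion[3], 1)
})

test_that("map summaries match a hand-built two-segment history", {
  # single branch of length 2, forced i -> j endpoints via a 2-tip tree
  tree <- parse_newick("(A:2,B:2);")
  st <- c(A = "forest", B = "open")
  Q <- mk_build_Q("ER", 0.3)
  maps <- stochastic_map(tree, st, Q, n_maps = 200, seed = 5)
  summ <- summarize_maps(maps)
  expect_equal(sum(summ$time_in_state$proportion), 1, tolerance = 1e-9)
  expect_true(all(summ$transitions$mean_count >= 0))
  # the two tips differ, so every map needs at least one transition
  expect_true(all(rowSums(maps$counts) >= 1))
})

test_that("simmap node-state frequencies converge to the marginals", {
  tree <- tree_5tip()
  st <- c(A = "forest", B = "intermediate", C = "forest", D = "open", E = "open")
  Q <- mk_build_Q("ARD", c(0.12, 0.05, 0.3, 0.14, 0.08, 0.2))
  marg <- ancestral_marginals(tree, st, Q)
  maps <- stochastic_map(tree, st, Q, n_maps = 4000, seed = 3, keep_paths = FALSE)
  nodes <- 6:9
  freq <- t(sapply(nodes, function(nd) tabulate(maps$node_states[, nd], 3) / 4000))
  expect_lt(max(abs(freq - as.matrix(marg[marg$node %in% nodes, habitat_levels()]))), 0.03)
})

test_that("simmap summaries agree with an independent implementation", {
  # same data, same empirical Q: phytools::make.simmap is the oracle for
  # both the time-in-state proportions and the mean transition count
  tree <- simulate_bd_tree(bd_model_spec(rate_constant(0.4), NULL, f = 1),
    crown_age = 8, seed = 12, n_tips_range = c(15, 40)
  )$tree
  Q <- mk_build_Q("ER", 0.08)
  for (s in 21:40) { # need all three states observed for the oracle call
    st <- paleodiv:::simulate_mk_states(tree, Q, seed = s)
    if (length(unique(st)) == 3) break
  }
  st <- setNames(habitat_levels()[st], names(st))
  maps <- stochastic_map(tree, st, Q, n_maps = 600, seed = 2, keep_paths = FALSE)
  summ <- summarize_maps(maps)
  st_f <- setNames(factor(st[tree$tip.label], levels = habitat_levels()), tree$tip.label)
  pm <- phytools::make.simmap(tree, st_f, Q = Q, nsim = 300,
    pi = rep(1 / 3, 3), message = FALSE
  )
  ds <- phytools::describe.simmap(pm)
  ref_prop <- colMeans(ds$times[, habitat_levels()] / rowSums(ds$times[, habitat_levels()]))
  expect_equal(
    setNames(summ$time_in_state$proportion, summ$time_in_state$habitat),
    ref_prop,
    tolerance = 0.12
  )
  expect_equal(
    sum(summ$transitions$mean_count),
    mean(ds$count[, "N"]),
    tolerance = 0.15
  )
})
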