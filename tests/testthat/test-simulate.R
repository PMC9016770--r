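test_that("simulators are bit-for-bit reproducible from their seed", {
  spec <- bd_model_spec(rate_constant(0.3), rate_constant(0.1), f = 0.9)
  s1 <- simulate_bd_tree(spec, 10, seed = 5)
  s2 <- simulate_bd_tree(spec, 10, seed = 5)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  em <- episodic_model(4, rates = c(0.1, 0.3), turnovers = c(0.1, 0.2), f = 1)
  e1 <- simulate_episodic_tree(em, 10, seed = 3)
  e2 <- simulate_episodic_tree(em, 10, seed = 3)
  expect_identical(write_newick(e1$tree), write_newick(e2$tree))
  dm <- dd_model("DDL", lambda0 = 0.3, K = 40, f = 1)
  d1 <- simulate_dd_tree(dm, 12, seed = 2)
  d2 <- simulate_dd_tree(dm, 12, seed = 2)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
})

test_that("crown-conditioned pure birth matches the analytic mean tip count", {
  lam <- 0.2
  Tc <- 10
  tips <- sapply(1:60, function(i) {
    sim <- simulate_bd_tree(bd_model_spec(rate_constant(lam), NULL, f = 1),
      crown_age = Tc, seed = 1000 + i
    )
    length(sim$tree$tip.label)
  })
  expect_equal(mean(tips), 2 * exp(lam * Tc), tolerance = 0.15)
})

test_that("pure birth with full sampling yields an unpruned ultrametric tree", {
  sim <- simulate_bd_tree(bd_model_spec(rate_constant(0.3), NULL, f = 1),
    crown_age = 10, seed = 77
  )
  # every simulated lineage is a sampled tip: n = branching events + 1
  expect_equal(length(sim$tree$tip.label), sim$tree$Nnode + 1)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-6))
  # pruning preserves ultrametricity under extinction + subsampling too
  sim2 <- simulate_bd_tree(bd_model_spec(rate_constant(0.4), rate_constant(0.15), f = 0.7),
    crown_age = 12, seed = 21, n_tips_range = c(10, 300)
  )
  expect_true(ape::is.ultrametric(sim2$tree, tol = 1e-6))
})

test_that("DD simulation equilibrates near the carrying capacity", {
  dm <- dd_model("DDL", lambda0 = 0.3, K = 70, f = 1)
  sizes <- sapply(1:12, function(i) {
    simulate_dd_tree(dm, crown_age = 40, seed = 300 + i)$n_extant
  })
  expect_equal(mean(sizes), 70, tolerance = 0.12)
})

test_that("episodic simulator honors its epochs", {
  # zero-rate second (older) epoch: no branchings older than the shift
  em <- episodic_model(5,
    rates = c(0.5, 1e-8), turnovers = c(0, 0), f = 1
  )
  sim <- simulate_episodic_tree(em, crown_age = 10, seed = 2,
    n_tips_range = c(5, 1000)
  )
  bt <- branching_times(sim$tree)
  expect_true(all(bt[-1] <= 5 + 1e-9))
  # degenerate shift: tip-count distribution matches the constant simulator
  em_eq <- episodic_model(5, rates = c(0.25, 0.25), turnovers = c(0.2, 0.2), f = 1)
  n_eq <- sapply(1:40, function(i) {
    length(simulate_episodic_tree(em_eq, 8, seed = 400 + i)$tree$tip.label)
  })
  cst <- bd_model_spec(
    rate_constant(0.25 / 0.8), rate_constant(0.25 / 0.8 * 0.2),
    f = 1
  )
  n_c <- sapply(1:40, function(i) {
    length(simulate_bd_tree(cst, 8, seed = 400 + i)$tree$tip.label)
  })
  expect_gt(suppressWarnings(ks.test(n_eq, n_c))$p.value, 0.01)
})

test_that("SSE state frequencies approach the transition stationary distribution", {
  # long tree, ER-like Q, rates equal across states: tip frequencies mix
  spec <- sse_model_spec("CR", "dual", "Unconstrained1", d = 1, f = 1)
  pars <- list(lambda = 0.15, mu = 0, q_examined = 0.5, q_concealed = numeric(0))
  freqs <- matrix(0, 4, 3)
  for (i in 1:4) {
    sim <- simulate_sse_tree(spec, pars, crown_age = 30, seed = 70 + i,
      n_tips_range = c(60, 600), root_state = 1
    )
    tab <- table(factor(sim$tip_states$habitat, levels = habitat_levels()))
    freqs[i, ] <- tab / sum(tab)
  }
  expect_equal(colMeans(freqs), rep(1 / 3, 3), tolerance = 0.25)
})

test_that("age jitter preserves ultrametricity and topology", {
  tc <- make_two_cluster_tree(seed = 4, n1 = 10, n2 = 10)
  jt <- jitter_node_ages(tc, 0.08, seed = 2)
  expect_true(ape::is.ultrametric(jt, tol = 1e-6))
  expect_equal(sort(jt$tip.label), sort(tc$tip.label))
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(jt, tc))), 0)
})

test_that("the study-shaped fixture has its declared shape", {
  fx <- make_fixture_study(seed = 42)
  n <- length(fx$tree$tip.label)
  expect_gte(n, 80)
  expect_lte(n, 116)
  expect_equal(max(branching_times(fx$tree)), 20, tolerance = 1e-6)
  # clades disjoint and jointly exhaustive
  expect_length(intersect(fx$clades$clade_I, fx$clades$clade_II), 0)
  expect_setequal(c(fx$clades$clade_I, fx$clades$clade_II), fx$tree$tip.label)
  # both clades monophyletic with the declared crown ages
  cI <- extract_clade(fx$tree, fx$clades$clade_I)
  cII <- extract_clade(fx$tree, fx$clades$clade_II)
  expect_equal(max(branching_times(cI)), 19.2, tolerance = 1e-6)
  expect_equal(max(branching_times(cII)), 17.5, tolerance = 1e-6)
  # all three habitat states present; taxa match tips exactly
  expect_setequal(unique(fx$habitats$habitat), habitat_levels())
  expect_setequal(fx$habitats$taxon, fx$tree$tip.label)
  expect_equal(fx$f, 0.92)
  # env curves span the required range
  expect_lte(fx$env$temperature$range[1], 0)
  expect_gte(fx$env$temperature$range[2], 20)
  # identical seed, identical bundle
  fx2 <- make_fixture_study(seed = 42)
  expect_identical(write_newick(fx$tree), write_newick(fx2$tree))
  expect_identical(fx$habitats, fx2$habitats)
})

test_that("fixture bundles write to plain-text files and read back", {
  fx <- make_fixture_study(seed = 7)
  dir <- withr::local_tempdir()
  write_fixture_study(fx, dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "habitats.tsv", "env_temperature.csv", "clades.json", "manifest.json")
  ))))
  tree <- parse_newick(readLines(file.path(dir, "tree.nwk")))
  expect_equal(sort(tree$tip.label), sort(fx$tree$tip.label))
  hab <- read_habitat_tsv(file.path(dir, "habitats.tsv"), tree)
  expect_equal(nrow(hab), length(tree$tip.label))
  env <- read_env_csv(file.path(dir, "env_temperature.csv"))
  expect_s3_class(env, "env_curve")
})
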