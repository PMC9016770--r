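test_that("zero-shift episodic equals the constant-rate likelihood on random trees", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:40, 1)
    bt <- sort(runif(n - 1, 0.1, 15), decreasing = TRUE)
    lam <- runif(1, 0.05, 0.6)
    eps <- runif(1, 0, 0.8)
    em <- episodic_model(numeric(0), rates = lam * (1 - eps), turnovers = eps, f = 0.92)
    spec <- bd_model_spec(rate_constant(lam), rate_constant(lam * eps), f = 0.92)
    expect_equal(episodic_loglik(bt, em), bd_loglik(bt, spec), tolerance = 1e-10)
  }
})

test_that("a degenerate shift with identical rates changes nothing", {
  bt <- c(8, 5, 2)
  em0 <- episodic_model(numeric(0), rates = 0.2, turnovers = 0.3, f = 0.9)
  em1 <- episodic_model(3.3, rates = c(0.2, 0.2), turnovers = c(0.3, 0.3), f = 0.9)
  expect_equal(episodic_loglik(bt, em1), episodic_loglik(bt, em0), tolerance = 1e-12)
})

test_that("single-shift likelihood matches the fine-grid oracle", {
  bt <- c(8, 5, 2)
  em <- episodic_model(1.0, rates = c(0.1, 0.4), turnovers = c(0.2, 0.5), f = 0.9)
  lam_pw <- function(t) ifelse(t < 1, em$lambda[1], em$lambda[2])
  mu_pw <- function(t) ifelse(t < 1, em$mu[1], em$mu[2])
  expect_equal(
    episodic_loglik(bt, em),
    oracle_bd_loglik(bt, lam_pw, mu_pw, 0.9),
    tolerance = 1e-4
  )
  # shift exactly at a branching time stays finite and oracle-consistent
  em2 <- episodic_model(5, rates = c(0.15, 0.3), turnovers = c(0.1, 0.4), f = 1)
  lam2 <- function(t) ifelse(t < 5, em2$lambda[1], em2$lambda[2])
  mu2 <- function(t) ifelse(t < 5, em2$mu[1], em2$mu[2])
  expect_equal(
    episodic_loglik(bt, em2),
    oracle_bd_loglik(bt, lam2, mu2, 1),
    tolerance = 1e-3
  )
})

test_that("model validation rejects malformed episodic models", {
  expect_error(episodic_model(5, rates = 0.2, turnovers = 0.1), "length")
  expect_error(episodic_model(numeric(0), rates = -0.1, turnovers = 0.1), "> 0")
  expect_error(episodic_model(numeric(0), rates = 0.1, turnovers = 1), "\\[0, 1\\)")
  em <- episodic_model(20, rates = c(0.1, 0.2), turnovers = c(0, 0), f = 1)
  expect_error(episodic_loglik(c(8, 5, 2), em), "inside")
})

test_that("fit_shifts yields non-decreasing likelihood and valid rates", {
  sim <- simulate_bd_tree(bd_model_spec(rate_constant(0.3), rate_constant(0.1), f = 1),
    crown_age = 10, seed = 21, n_tips_range = c(40, 120)
  )
  fs <- fit_shifts(branching_times(sim$tree),
    max_shifts = 2, grid_step = 0.5,
    f = 1, n_starts = 2, seed = 2
  )
  ll <- fs$loglik[order(fs$n_shifts)]
  expect_true(all(diff(ll) >= -1e-6))
  for (i in seq_len(nrow(fs))) {
    lam <- fs$rates[[i]] / (1 - fs$turnovers[[i]])
    expect_true(all(lam > 0))
    expect_true(all(fs$turnovers[[i]] >= 0 & fs$turnovers[[i]] < 1))
  }
  expect_equal(fs$aic, 2 * fs$n_params - 2 * fs$loglik, tolerance = 1e-9)
})

test_that("select_num_shifts follows the sequential LRT rule", {
  base <- tibble::tibble(
    n_shifts = 0:2, n_params = c(2, 5, 8),
    loglik = c(-100, -100, -100), aic = NA_real_,
    model = c("BD-constant", "BD-1 shift", "BD-2 shifts")
  )
  base$aic <- 2 * base$n_params - 2 * base$loglik
  expect_equal(select_num_shifts(base)$n_shifts, 0)
  # gain of 10 loglik units for one added shift: rejected null, continue
  gain <- base
  gain$loglik <- c(-100, -90, -89.9)
  gain$aic <- 2 * gain$n_params - 2 * gain$loglik
  expect_equal(select_num_shifts(gain)$n_shifts, 1)
  # trivial gains below 0.5 at every step keep the constant model
  tiny <- base
  tiny$loglik <- c(-100, -99.8, -99.6)
  tiny$aic <- 2 * tiny$n_params - 2 * tiny$loglik
  expect_equal(select_num_shifts(tiny)$n_shifts, 0)
})

test_that("type-I error of the shift LRT is controlled on Yule trees", {
  # constant-rate truth: a shift should rarely be selected
  hits <- 0
  n_rep <- 12
  for (i in seq_len(n_rep)) {
    sim <- simulate_bd_tree(bd_model_spec(rate_constant(0.25), NULL, f = 1),
      crown_age = 12, seed = 700 + i, n_tips_range = c(30, 200)
    )
    fs <- fit_shifts(branching_times(sim$tree),
      max_shifts = 1, grid_step = 0.5,
      f = 1, n_starts = 1, seed = i
    )
    if (select_num_shifts(fs)$n_shifts == 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.75)
})
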