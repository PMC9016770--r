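test_that("pure-birth 2-tip likelihood matches the analytic value", {
  spec <- bd_model_spec(rate_constant(0.1), NULL, f = 1, conditioning = "none")
  expect_equal(bd_loglik(10, spec), -2.0, tolerance = 1e-12)
})

test_that("constant-rate likelihood matches the fine-grid oracle", {
  bt <- c(8, 5, 2)
  spec <- bd_model_spec(rate_constant(0.3), rate_constant(0.1), f = 0.9)
  expect_equal(
    bd_loglik(bt, spec),
    oracle_bd_loglik(bt, function(t) rep(0.3, length(t)),
      function(t) rep(0.1, length(t)), 0.9
    ),
    tolerance = 1e-4
  )
  # critical case lambda == mu
  spec_cr <- bd_model_spec(rate_constant(0.2), rate_constant(0.2), f = 1)
  expect_equal(
    bd_loglik(bt, spec_cr),
    oracle_bd_loglik(bt, function(t) rep(0.2, length(t)),
      function(t) rep(0.2, length(t)), 1
    ),
    tolerance = 1e-4
  )
})

test_that("time-exponential likelihood matches the fine-grid oracle", {
  bt <- c(8, 5, 2)
  spec <- bd_model_spec(rate_exp_time(0.25, 0.08), rate_constant(0.05), f = 0.95)
  expect_equal(
    bd_loglik(bt, spec),
    oracle_bd_loglik(bt, function(t) 0.25 * exp(0.08 * t),
      function(t) rep(0.05, length(t)), 0.95
    ),
    tolerance = 1e-4
  )
})

test_that("env dependence with alpha = 0 equals the constant-rate model", {
  env <- synthetic_env_curve("cooling_trend", seed = 2)
  for (bt in list(c(8, 5, 2), c(15, 11, 8.2, 4, 1.5))) {
    s_env <- bd_model_spec(rate_exp_env(0.3, 0, env), rate_constant(0.1), f = 0.9)
    s_cst <- bd_model_spec(rate_constant(0.3), rate_constant(0.1), f = 0.9)
    expect_equal(bd_loglik(bt, s_env), bd_loglik(bt, s_cst), tolerance = 1e-7)
  }
})

test_that("pure-birth full-sampling likelihood equals the Yule closed form", {
  for (seed in 1:5) {
    sim <- simulate_bd_tree(bd_model_spec(rate_constant(0.3), NULL, f = 1),
      crown_age = 8, seed = seed, n_tips_range = c(5, 60)
    )
    bt <- branching_times(sim$tree)
    n <- length(bt) + 1
    tot <- sum(seq(n, 2) * diff(c(0, sort(bt))))
    lam <- 0.22
    closed <- (n - 2) * log(lam) - lam * tot
    spec <- bd_model_spec(rate_constant(lam), NULL, f = 1, conditioning = "none")
    expect_equal(bd_loglik(bt, spec), closed, tolerance = 1e-8)
  }
})

test_that("log-likelihood is continuous in lambda0 and alpha", {
  bt <- c(12, 9, 6.5, 4, 2, 0.8)
  env <- synthetic_env_curve("oscillation", seed = 1)
  base <- c(lambda0 = 0.2, alpha = 0.12)
  ll <- function(l0, a) {
    bd_loglik(bt, bd_model_spec(rate_exp_env(l0, a, env), rate_constant(0.05), f = 0.92))
  }
  l0 <- ll(base[1], base[2])
  expect_lt(abs(ll(base[1] + 1e-6, base[2]) - l0), 1e-3)
  expect_lt(abs(ll(base[1], base[2] + 1e-6) - l0), 1e-3)
})

test_that("fit_bd_family recovers Yule generation and keeps AIC consistent", {
  # modest replicate count: median lambda-hat near truth, Yule wins overall
  lam_true <- 0.2
  res <- lapply(1:8, function(i) {
    sim <- simulate_bd_tree(bd_model_spec(rate_constant(lam_true), NULL, f = 1),
      crown_age = 18, seed = 500 + i, n_tips_range = c(40, 260)
    )
    fit_bd_family(branching_times(sim$tree), "time", f = 1, n_starts = 2, seed = i)
  })
  # AIC field consistency on every row of every fit
  for (ft in res) expect_equal(ft$aic, 2 * ft$n_params - 2 * ft$loglik, tolerance = 1e-9)
  lam_hat <- sapply(res, function(ft) ft$lambda0[ft$model == "yule"])
  expect_equal(median(lam_hat), lam_true, tolerance = 0.2)
  best_aic <- sapply(res, function(ft) {
    yule_delta <- ft$delta[ft$model == "yule"]
    yule_delta
  })
  # Yule is within 2 AIC units of the best model in most replicates
  expect_gte(mean(best_aic < 2), 0.5)
})

test_that("constant env curve collapses the env family onto constant fits", {
  sim <- simulate_bd_tree(bd_model_spec(rate_constant(0.25), NULL, f = 1),
    crown_age = 12, seed = 33, n_tips_range = c(30, 120)
  )
  bt <- branching_times(sim$tree)
  flat <- synthetic_env_curve("constant", seed = 1)
  fe <- suppressWarnings(
    fit_bd_family(bt, "env", env = flat, f = 1, n_starts = 2, seed = 3)
  )
  ft <- suppressWarnings(
    fit_bd_family(bt, "time", f = 1, n_starts = 2, seed = 3)
  )
  # alpha is unidentifiable; logliks match the constant-rate models
  expect_equal(
    fe$loglik[fe$model == "benv"],
    ft$loglik[ft$model == "yule"],
    tolerance = 1e-4
  )
  expect_equal(
    fe$loglik[fe$model == "benv_dcst"],
    ft$loglik[ft$model == "bcst_dcst"],
    tolerance = 1e-3
  )
})
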