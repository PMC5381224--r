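test_that("the standard mixture recovers well-separated generative parameters", {
  set.seed(81)
  n <- 10000
  gen <- list(p_target = 0.7, p_sub = 0.3, sd = 15)
  kap <- circ_sd_to_kappa(gen$sd)
  is_sub <- runif(n) < gen$p_sub
  e <- wrap_deg(rvonmises_deg(n, 0, kap) + ifelse(is_sub, 90, 0))
  fit <- fit_mixture(e, rep(90, n), seed = 82)
  expect_lt(abs(fit$estimates[["p_target"]] - 0.7), 0.01)
  expect_lt(abs(fit$estimates[["p_substitution"]] - 0.3), 0.01)
  expect_lt(abs(fit$estimates[["p_guess"]] - 0), 0.01)
  expect_lt(abs(fit$estimates[["kappa"]] - kap) / kap, 0.05)
  expect_true(fit$converged)
  # simplex and diagnostics contracts
  expect_equal(sum(fit$estimates[c("p_target", "p_substitution",
                                   "p_guess")]), 1, tolerance = 1e-6)
  # MLE dominance: fitted log-likelihood beats the generating parameters
  ll_gen <- sum(log(0.7 * dvonmises_deg(e, kap) +
                      0.3 * dvonmises_deg(e - 90, kap)))
  expect_gte(fit$log_likelihood, ll_gen)
})

test_that("pure uniform reports drive the guess rate to 1", {
  set.seed(83)
  e <- runif(2000, -180, 180)
  fit <- fit_mixture(e, rep(90, 2000), n_restarts = 10, seed = 84)
  expect_gt(fit$estimates[["p_guess"]], 0.95)
})

test_that("mixture fits are deterministic given a seed", {
  sim <- simulate_validation_dataset(0.6, 0.4, 12, n_trials = 150,
                                     seed = 85)
  f1 <- fit_mixture(sim$error_deg, sim$delta1_deg, seed = 86)
  f2 <- fit_mixture(sim$error_deg, sim$delta1_deg, seed = 86)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  fa1 <- fit_mixture(sim$error_deg, sim$delta1_deg, model = "averaging",
                     n_restarts = 10, seed = 87)
  fa2 <- fit_mixture(sim$error_deg, sim$delta1_deg, model = "averaging",
                     n_restarts = 10, seed = 87)
  expect_identical(fa1$estimates, fa2$estimates)
})

test_that("the averaging mixture nails degenerate averaging data", {
  set.seed(88)
  d <- runif(400, 30, 120)
  e <- 0.5 * d + rnorm(400, 0, 0.5)   # essentially noise-free midpoints
  fit <- fit_mixture(e, d, model = "averaging", n_restarts = 20,
                     seed = 89)
  expect_gt(fit$estimates[["p_average"]], 0.9)
  expect_lt(abs(fit$estimates[["average_weight"]] - 0.5), 0.02)
  ps <- fit$estimates[c("p_target", "p_substitution", "p_average",
                        "p_guess")]
  expect_equal(sum(ps), 1, tolerance = 1e-6)
})

test_that("the averaging mixture is flagged unstable on two-component 100-trial data", {
  flags <- vapply(1:5, function(i) {
    sim <- simulate_validation_dataset(0.5, 0.5, 10, n_trials = 100,
                                       seed = 900 + i)
    fit <- fit_mixture(sim$error_deg, sim$delta1_deg,
                       model = "averaging", seed = 910 + i)
    fit$unstable
  }, logical(1))
  expect_gte(mean(flags), 0.6)
})

test_that("mixture fit objects behave like fitted models", {
  sim <- simulate_validation_dataset(0.7, 0.3, 15, n_trials = 300,
                                     seed = 91)
  fit <- fit_mixture(sim$error_deg, sim$delta1_deg, n_restarts = 10,
                     seed = 92)
  expect_named(coef(fit), c("p_target", "p_substitution", "p_guess",
                            "kappa"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 3)
  expect_equal(attr(ll, "nobs"), 300)
  s <- summary(fit)
  expect_s3_class(s, "summary.crowd_mixfit")
  expect_output(print(s), "Circular mixture")
  sims <- simulate(fit, nsim = 3, seed = 93)
  expect_equal(dim(sims), c(300, 3))
  expect_true(all(as.matrix(sims) > -180 & as.matrix(sims) <= 180))
  # simulated data re-fit to roughly the same proportions
  refit <- fit_mixture(unlist(sims), rep(fit$deltas, 3),
                       n_restarts = 10, seed = 94)
  expect_lt(abs(refit$estimates[["p_target"]] -
                  fit$estimates[["p_target"]]), 0.1)
  js <- mixfit_to_json(fit)
  expect_true(jsonlite::validate(js))
})

test_that("the grid-search simulation estimator finds generative proportions", {
  v0 <- simulate_validation_dataset(1, 0, 10, n_trials = 500,
                                    fixed_delta_deg = 90, seed = 95)
  mc0 <- monte_carlo_proportions(v0$error_deg, v0$delta1_deg, 10,
                                 seed = 96)
  expect_equal(mc0$p_target, 1)
  expect_equal(mc0$p_substitution, 0)

  v <- simulate_validation_dataset(0.5, 0.5, 10, n_trials = 1000,
                                   fixed_delta_deg = 90, seed = 97)
  mc <- monte_carlo_proportions(v$error_deg, v$delta1_deg, 10, seed = 98)
  expect_lte(abs(mc$p_target - 0.5), mc$grid_step)
  expect_equal(nrow(mc$surface), 21)
  expect_equal(mc$p_target + mc$p_substitution, 1)
})

test_that("linear slope fits read 0 for target, 1 for substitution data", {
  d <- rnorm(200, 0, 22.5)
  f0 <- linear_slope(rep(0, 200), d)
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  f1 <- suppressWarnings(linear_slope(d, d))  # lm warns on a perfect fit
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_slope(c(1, 2, 3), rep(5, 3)), "zero variance")
  expect_error(linear_slope(1, 1), "at least 3")
  expect_warning(linear_slope(rnorm(10), seq(-100, 100, length.out = 10)),
                 "90")
})

test_that("a 50/50 target+substitution mixture yields a spurious 0.5 slope", {
  set.seed(99)
  n <- 10000
  d <- rnorm(n, 0, 22.5)
  is_sub <- runif(n) < 0.5
  e <- wrap_deg(ifelse(is_sub, d, 0) + rnorm(n, 0, 10))
  # a few offsets exceed 90 deg; the wrap warning is expected here
  sf <- suppressWarnings(linear_slope(e, d))
  expect_lt(abs(sf$slope - 0.5), 0.05)
})
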