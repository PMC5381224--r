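test_that("observer model validates its mixture", {
  expect_error(observer_model(p_target = 0.5, p_guess = 0.4), "sum to 1")
  expect_error(observer_model(p_target = 1.2, p_guess = -0.2), "\\[0, 1\\]")
  expect_error(observer_model(average_weight = 1.5), "average_weight")
  m <- observer_model(p_target = 0.25, p_average = 0.25,
                      p_sub_near = 0.25, p_sub_far = 0.25)
  expect_s3_class(m, "observer_model")
})

test_that("flanker-gap sampling matches the stimulus constraints", {
  d <- crowding_design()
  g1 <- sample_flanker_gaps(rep(0, 10000), "one_gap", d, seed = 21)
  off <- wrap_deg(g1$gap1_deg)
  expect_equal(sd(off), d$flanker_offset_sd_deg, tolerance = 0.02)
  expect_equal(mean(off), 0, tolerance = 1)
  expect_true(all(is.na(g1$gap2_deg)))

  g2 <- sample_flanker_gaps(runif(10000, 0, 360), "two_gap", d, seed = 22)
  between <- wrap_deg(g2$gap2_deg - g2$gap1_deg)
  expect_equal(circular_mean(between) %% 360, 180, tolerance = 0.7)
  expect_equal(circular_sd(between), d$flanker_offset_sd_deg,
               tolerance = 0.5)

  g0 <- sample_flanker_gaps(c(10, 20), c("no_gap", "unflanked"), d)
  expect_true(all(is.na(g0)))

  # degenerate SD pins the gap to the target
  d0 <- crowding_design(flanker_offset_sd_deg = 1e-12)
  gd <- sample_flanker_gaps(c(45, 300), "one_gap", d0)
  expect_equal(gd$gap1_deg, c(45, 300), tolerance = 1e-6)
})

test_that("report simulation places each component at its model mean", {
  base <- data.frame(flanker_type = "one_gap", target_deg = 100,
                     gap1_deg = 140, gap2_deg = NA_real_)
  pure <- function(model) {
    compute_errors(simulate_report(base, model, seed = 1))
  }
  expect_equal(pure(observer_model(p_target = 1, noise_sd_deg = 1e-9))$error_deg,
               0, tolerance = 1e-6)
  expect_equal(pure(observer_model(p_sub_near = 1, p_target = 0,
                                   noise_sd_deg = 1e-9))$report_deg,
               140, tolerance = 1e-6)
  # averaging midpoint: delta 40, w 0.5 -> error 20
  expect_equal(pure(observer_model(p_average = 1, p_target = 0,
                                   average_weight = 0.5,
                                   noise_sd_deg = 1e-9))$error_deg,
               20, tolerance = 1e-6)
  # all mass on an absent component is a configuration error
  expect_error(simulate_report(base, observer_model(p_sub_far = 1,
                                                    p_target = 0)),
               "absent")
})

test_that("component frequencies follow the renormalised mixture", {
  d <- crowding_design()
  m <- observer_model(p_target = 0.4, p_average = 0.2, p_sub_near = 0.2,
                      p_sub_far = 0.1, p_guess = 0.1, noise_sd_deg = 15)
  n <- 10000
  tg <- runif(n, 0, 360)
  gaps <- sample_flanker_gaps(tg, "two_gap", d, seed = 31)
  trials <- data.frame(flanker_type = "two_gap", target_deg = tg,
                       gap1_deg = gaps$gap1_deg, gap2_deg = gaps$gap2_deg)
  sim <- simulate_report(trials, m, seed = 32)
  obs <- table(factor(sim$truth_label,
                      levels = c("target", "average", "sub_near",
                                 "sub_far", "guess")))
  gof <- chisq.test(obs, p = c(0.4, 0.2, 0.2, 0.1, 0.1))
  expect_gt(gof$p.value, 0.01)

  # on one-gap trials the far-substitution mass renormalises away
  gaps1 <- sample_flanker_gaps(tg, "one_gap", d, seed = 33)
  trials1 <- data.frame(flanker_type = "one_gap", target_deg = tg,
                        gap1_deg = gaps1$gap1_deg, gap2_deg = NA_real_)
  sim1 <- simulate_report(trials1, m, seed = 34)
  expect_false(any(sim1$truth_label == "sub_far"))
  p1 <- c(0.4, 0.2, 0.2, 0.1) / 0.9
  obs1 <- table(factor(sim1$truth_label,
                       levels = c("target", "average", "sub_near",
                                  "guess")))
  expect_gt(chisq.test(obs1, p = p1)$p.value, 0.01)
})

test_that("a pure-guess observer is circularly uniform", {
  d <- crowding_design()
  m <- observer_model(p_target = 0, p_guess = 1)
  trials <- data.frame(flanker_type = "unflanked",
                       target_deg = runif(10000, 0, 360),
                       gap1_deg = NA_real_, gap2_deg = NA_real_)
  sim <- compute_errors(simulate_report(trials, m, seed = 41))
  expect_gt(rayleigh_test(sim$error_deg)$p_value, 0.01)
})

test_that("a simulated experiment has the session/condition structure", {
  tr <- simulate_experiment(seed = 51,
                            model = observer_model(p_target = 0.7,
                                                   p_sub_near = 0.3,
                                                   noise_sd_deg = 15))
  expect_equal(nrow(tr), 1600)
  expect_equal(as.vector(table(tr$session)), rep(320, 5))
  counts <- table(tr$flanker_type, addNA(tr$edge_separation_deg))
  expect_true(all(counts[counts > 0] == 100))
  expect_equal(sum(counts > 0), 16)
  # ranges and derived columns
  expect_true(all(tr$target_deg >= 0 & tr$target_deg < 360))
  expect_true(all(tr$report_deg >= 0 & tr$report_deg < 360))
  expect_true(all(tr$error_deg > -180 & tr$error_deg <= 180))
  expect_equal(tr$error_deg, wrap_deg(tr$report_deg - tr$target_deg))
  # gap presence matches the flanker type
  expect_true(all(is.na(tr$gap1_deg[tr$flanker_type %in%
                                      c("unflanked", "no_gap")])))
  expect_true(all(!is.na(tr$gap1_deg[tr$flanker_type == "one_gap"])))
  expect_true(all(!is.na(tr$gap2_deg[tr$flanker_type == "two_gap"])))
  # determinism
  tr2 <- simulate_experiment(seed = 51,
                             model = observer_model(p_target = 0.7,
                                                    p_sub_near = 0.3,
                                                    noise_sd_deg = 15))
  expect_identical(tr, tr2)
})

test_that("the validation generator exposes ground truth at the right rate", {
  expect_error(simulate_validation_dataset(0.6, 0.5, 10), "equal 1")
  v0 <- simulate_validation_dataset(1, 0, noise_sd_deg = 1e-9,
                                    n_trials = 100, seed = 61)
  expect_equal(v0$error_deg, rep(0, 100), tolerance = 1e-6)
  v <- simulate_validation_dataset(0.5, 0.5, noise_sd_deg = 10,
                                   n_trials = 10000, seed = 62)
  expect_true(all(v$truth_label %in% c("target", "sub_near")))
  # binomial oracle: sd of the fraction is 0.005 at n = 10,000
  expect_equal(mean(v$truth_label == "target"), 0.5, tolerance = 0.015)
  # fixed offsets when requested
  vf <- simulate_validation_dataset(0.5, 0.5, 10, n_trials = 50,
                                    fixed_delta_deg = 90, seed = 63)
  expect_equal(vf$delta1_deg, rep(90, 50))
})
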