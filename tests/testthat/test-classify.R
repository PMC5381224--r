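test_that("error derivation wraps differences with the clockwise-positive sign", {
  tr <- data.frame(target_deg = c(350, 10, 123), report_deg = c(10, 350, 123),
                   gap1_deg = c(0, NA, 150), gap2_deg = NA_real_)
  out <- compute_errors(tr)
  expect_equal(out$error_deg, c(20, -20, 0))
  expect_equal(out$delta1_deg, c(10, NA, 27))
  # missing reports are dropped with a warning
  tr$report_deg[2] <- NA
  expect_warning(out2 <- compute_errors(tr), "missing report")
  expect_equal(nrow(out2), 2)
})

test_that("far-gap splitting uses a strict 90-degree cut and partitions exactly", {
  tr <- data.frame(observer_id = "S1", flanker_type = "two_gap",
                   edge_separation_deg = 0.4,
                   target_deg = 0, report_deg = 0,
                   gap1_deg = 0, gap2_deg = 180,
                   error_deg = c(0, 50, -120, 170, 90, -90))
  sp <- split_far_gap(tr, seed = 1, n_boot = 50)
  expect_equal(nrow(sp$far), 2)
  expect_equal(nrow(sp$near), 4)
  expect_equal(nrow(sp$far) + nrow(sp$near), nrow(tr))
  expect_equal(sp$summary$proportion_far, 2 / 6)
  # boundary +/-90 counts as near (strict inequality)
  expect_true(all(abs(sp$far$error_deg) > 90))
  # all-zero errors give proportion 0
  tr0 <- tr; tr0$error_deg <- 0
  expect_equal(split_far_gap(tr0, n_boot = 50)$summary$proportion_far, 0)
  # refuses non-two-gap input
  tr$flanker_type <- "one_gap"
  expect_error(split_far_gap(tr), "two-gap")
})

test_that("re-centering subtracts 180 from error and far-gap offset with wrapping", {
  far <- data.frame(error_deg = c(170, -170, 180),
                    delta2_deg = c(160, 170, 180))
  rc <- recenter_far(far)
  expect_equal(rc$error_deg, c(-10, 10, 0))
  expect_equal(rc$delta2_deg, c(-20, -10, 0))
  expect_error(recenter_far(data.frame(error_deg = 1,
                                       delta2_deg = NA_real_)),
               "delta2")
})

test_that("nearest-model labelling matches its examples and tie priority", {
  expect_equal(as.character(nearest_model_label(0, 40)), "target")
  expect_equal(as.character(nearest_model_label(22, 40)), "average")
  expect_equal(as.character(nearest_model_label(39, 40)), "substitution")
  # tie at 10 vs 10 resolved target > average
  expect_equal(as.character(nearest_model_label(10, 40)), "target")
  # tie between average and substitution resolved to average
  expect_equal(as.character(nearest_model_label(30, 40)), "average")
})

test_that("labelling agrees with a brute-force circular-distance oracle", {
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  oracle <- function(e, dl) {
    ds <- c(target = circ_dist(e, 0),
            average = circ_dist(e, dl / 2),
            substitution = circ_dist(e, dl))
    # first index attaining the minimum encodes the tie priority
    names(ds)[which(ds <= min(ds) + 0)][1]
  }
  set.seed(71)
  e <- runif(10000, -180, 180)
  dl <- runif(10000, -180, 180)
  got <- as.character(nearest_model_label(e, dl))
  want <- mapply(oracle, e, dl)
  expect_identical(got, unname(want))
})

test_that("label proportions sum to 1 per group and recover a separated mixture", {
  labs <- data.frame(observer_id = "S1", flanker_type = "one_gap",
                     edge_separation_deg = 0.4,
                     error_deg = c(0, 1, 21, 39), delta1_deg = 40)
  lp <- label_proportions(labs)
  expect_equal(sum(lp$proportion), 1)
  expect_equal(lp$proportion[lp$label == "target"], 0.5)
  expect_equal(lp$proportion[lp$label == "average"], 0.25)
  expect_equal(lp$proportion[lp$label == "substitution"], 0.25)

  # generative oracle: well-separated components at delta 90, SD 5
  set.seed(72)
  n <- 10000
  comp <- sample(c("target", "average", "substitution"), n, TRUE,
                 prob = c(0.4, 0.3, 0.3))
  mu <- c(target = 0, average = 45, substitution = 90)[comp]
  tr <- data.frame(observer_id = "S1", flanker_type = "one_gap",
                   edge_separation_deg = 0.4,
                   error_deg = wrap_deg(rnorm(n, mu, 5)),
                   delta1_deg = 90)
  lp2 <- label_proportions(tr)
  expect_lt(abs(lp2$proportion[lp2$label == "target"] - 0.4), 0.02)
  expect_lt(abs(lp2$proportion[lp2$label == "average"] - 0.3), 0.02)
  expect_lt(abs(lp2$proportion[lp2$label == "substitution"] - 0.3), 0.02)
})

test_that("labelled target proportion underestimates a pure-target observer", {
  # with offsets near zero, noise alone pushes reports past the average
  # and substitution boundaries, so labelling must undercount targets
  set.seed(73)
  sim <- simulate_validation_dataset(1, 0, noise_sd_deg = 15,
                                     n_trials = 10000, seed = 73)
  lab <- nearest_model_label(sim$error_deg, sim$delta1_deg)
  expect_lt(mean(lab == "target"), 1)
  expect_gt(mean(lab == "target"), 0.3)
})
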