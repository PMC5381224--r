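#' Analysis configuration
#'
#' Collects every tunable of the full analysis in one object so a run is
#' reproducible from its configuration snapshot: the far-gap threshold,
#' bootstrap settings, mixture-fit settings and grouping/pooling choices.
#' Round-trips through YAML via [write_config()]/[read_config()].
#'
#' @param far_threshold_deg absolute-error cut (degrees) separating
#'   near- from far-gap reports in the two-gap condition.
#' @param n_boot,boot_level bootstrap resamples and confidence level.
#' @param mixture_restarts random restarts for the standard mixture fits.
#' @param kappa_bounds concentration bounds for mixture fits.
#' @param pool_far_observers pool observers in the far-gap analyses
#'   (the far subsets are small; per-observer cells can hold 1--2 trials).
#' @param seed master seed for all stochastic analysis steps.
#' @return object of class `"analysis_config"`.
#' @export
analysis_config <- function(far_threshold_deg = 90, n_boot = 1000,
                            boot_level = 0.95, mixture_restarts = 20,
                            kappa_bounds = c(0.01, 500),
                            pool_far_observers = TRUE, seed = 1L) {
  stopifnot(far_threshold_deg > 0, far_threshold_deg <= 180,
            n_boot >= 1, boot_level > 0, boot_level < 1,
            mixture_restarts >= 1, length(kappa_bounds) == 2)
  structure(list(far_threshold_deg = far_threshold_deg,
                 n_boot = n_boot, boot_level = boot_level,
                 mixture_restarts = mixture_restarts,
                 kappa_bounds = kappa_bounds,
                 pool_far_observers = pool_far_observers,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Run the full crowding analysis on a trial table
#'
#' Routes each flanker condition to its analyses:
#' \itemize{
#'   \item unflanked and no-gap trials: per-condition perceptual error
#'     (circular SD of report errors) with percentile-bootstrap CIs —
#'     the positional-uncertainty summary;
#'   \item one-gap trials: trial-wise nearest-model labelling into
#'     target/average/substitution proportions per condition, a standard
#'     mixture fit per condition, and a linear slope fit per condition;
#'   \item two-gap trials: far-gap split at the configured threshold with
#'     per-condition far proportions, the one-gap analyses repeated on
#'     the near subset (near-gap offset as the model axis), and
#'     nearest-model labelling of the re-centred far subset (far-gap
#'     offset as the model axis), pooled across observers by default.
#' }
#' Every stochastic step is seeded from `config$seed`, so the same input
#' and configuration give identical output tables.
#'
#' @param trials trial data.frame (from [read_trials()] or
#'   [simulate_experiment()]).
#' @param config an [analysis_config()].
#' @return object of class `"crowd_analysis"`: a list of tidy
#'   data.frames (`perceptual_error`, `one_gap_labels`,
#'   `one_gap_mixture`, `one_gap_slopes`, `far_gap`, `two_gap_near_labels`,
#'   `two_gap_far_labels`) plus the `config` used.
#' @export
run_analysis <- function(trials, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  trials <- compute_errors(trials)
  ft <- as.character(trials$flanker_type)
  out <- list(config = config)

  # --- perceptual error (unflanked + no-gap) ---
  pe_rows <- trials[ft %in% c("unflanked", "no_gap"), , drop = FALSE]
  out$perceptual_error <- if (nrow(pe_rows)) {
    set.seed(config$seed)
    key <- group_key(pe_rows, c("observer_id", "flanker_type",
                                "edge_separation_deg"))
    res <- do.call(rbind, lapply(split(seq_len(nrow(pe_rows)), key),
                                 function(idx) {
      ci <- bootstrap_ci(pe_rows$error_deg[idx], circular_sd,
                         n_boot = config$n_boot,
                         level = config$boot_level)
      cbind(pe_rows[idx[1], c("observer_id", "flanker_type",
                              "edge_separation_deg")],
            data.frame(n = length(idx), circ_sd_deg = ci$point,
                       ci_lower = ci$lower, ci_upper = ci$upper))
    }))
    rownames(res) <- NULL
    res
  } else NULL

  # --- one-gap condition ---
  one <- trials[ft == "one_gap", , drop = FALSE]
  if (nrow(one)) {
    out$one_gap_labels <- label_proportions(one, seed = config$seed)
    out$one_gap_mixture <- per_condition_mixtures(one, config)
    out$one_gap_slopes <- per_condition_slopes(one)
  }

  # --- two-gap condition ---
  two <- trials[ft == "two_gap", , drop = FALSE]
  if (nrow(two)) {
    sp <- split_far_gap(two, threshold_deg = config$far_threshold_deg,
                        n_boot = config$n_boot,
                        level = config$boot_level, seed = config$seed)
    out$far_gap <- sp$summary
    if (nrow(sp$near)) {
      out$two_gap_near_labels <- label_proportions(sp$near,
                                                   seed = config$seed)
    }
    if (nrow(sp$far)) {
      far <- recenter_far(sp$far)
      grp <- if (config$pool_far_observers) {
        c("flanker_type", "edge_separation_deg")
      } else {
        c("observer_id", "flanker_type", "edge_separation_deg")
      }
      out$two_gap_far_labels <- label_proportions(
        far, group_by = grp, delta_col = "delta2_deg",
        seed = config$seed)
    }
  }
  structure(out, class = "crowd_analysis")
}

per_condition_mixtures <- function(trials, config) {
  key <- group_key(trials, c("observer_id", "edge_separation_deg"))
  res <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key),
                               function(idx) {
    fit <- fit_mixture(trials$error_deg[idx], trials$delta1_deg[idx],
                       model = "standard",
                       n_restarts = config$mixture_restarts,
                       kappa_bounds = config$kappa_bounds,
                       seed = config$seed)
    cbind(trials[idx[1], c("observer_id", "flanker_type",
                           "edge_separation_deg")],
          data.frame(n = fit$n,
                     p_target = fit$estimates[["p_target"]],
                     p_substitution = fit$estimates[["p_substitution"]],
                     p_guess = fit$estimates[["p_guess"]],
                     kappa = fit$estimates[["kappa"]],
                     circ_sd_deg = fit$circ_sd_deg,
                     log_likelihood = fit$log_likelihood,
                     converged = fit$converged))
  }))
  rownames(res) <- NULL
  res
}

per_condition_slopes <- function(trials) {
  key <- group_key(trials, c("observer_id", "edge_separation_deg"))
  res <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key),
                               function(idx) {
    sf <- linear_slope(trials$error_deg[idx], trials$delta1_deg[idx])
    cbind(trials[idx[1], c("observer_id", "flanker_type",
                           "edge_separation_deg")],
          data.frame(n = sf$n, slope = sf$slope,
                     intercept = sf$intercept,
                     r_squared = sf$r_squared))
  }))
  rownames(res) <- NULL
  res
}

#' @export
print.crowd_analysis <- function(x, ...) {
  cat("Crowding continuous-report analysis\n")
  for (nm in setdiff(names(x), "config")) {
    tab <- x[[nm]]
    if (is.data.frame(tab)) {
      cat(sprintf("  $%s: %d rows\n", nm, nrow(tab)))
    }
  }
  cat(sprintf("  seed %d; far-gap threshold %g deg; %d bootstrap resamples\n",
              x$config$seed, x$config$far_threshold_deg, x$config$n_boot))
  invisible(x)
}

#' Parameter-recovery study of the proportion estimators
#'
#' Validates each estimator on synthetic data with known ground truth
#' before it is trusted on real data. For every scenario (a generative
#' `(p_target, p_substitution)` pair, a noise SD and a trial count —
#' defaulting to the 100-trial, one-condition validation design), the
#' study simulates `n_replicates` datasets via
#' [simulate_validation_dataset()] and applies the requested estimators:
#' trial-wise nearest-model labelling, the standard mixture MLE, the
#' averaging-extended mixture (recording how often its instability flag
#' fires), and the grid-search simulation estimator. Bias, mean absolute
#' error and RMSE of the estimated target proportion are tabulated per
#' scenario and estimator.
#'
#' @param scenarios data.frame with columns `p_target`,
#'   `p_substitution`, `noise_sd_deg` and optionally `n_trials`
#'   (default 100).
#' @param estimators subset of `c("labelling", "standard_mixture",
#'   "averaging_mixture", "monte_carlo")`.
#' @param n_replicates replicate datasets per scenario.
#' @param design a [crowding_design()] supplying the offset distribution.
#' @param mc_sims_per_cell simulated datasets per grid cell for the
#'   grid-search estimator.
#' @param seed master seed; every replicate derives its own seed from it.
#' @return object of class `"recovery_report"`: a data.frame with one
#'   row per scenario x estimator (generative parameters, mean estimate,
#'   bias, MAE, RMSE, instability rate for the averaging mixture,
#'   failure count).
#' @export
run_recovery_study <- function(scenarios,
                               estimators = c("labelling",
                                              "standard_mixture",
                                              "averaging_mixture",
                                              "monte_carlo"),
                               n_replicates = 100,
                               design = crowding_design(),
                               mc_sims_per_cell = 200, seed = 1L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(is.data.frame(scenarios),
            all(c("p_target", "p_substitution", "noise_sd_deg") %in%
                  names(scenarios)))
  if (!"n_trials" %in% names(scenarios)) scenarios$n_trials <- 100L
  set.seed(seed)
  rows <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    est <- matrix(NA_real_, n_replicates, length(estimators),
                  dimnames = list(NULL, estimators))
    unstable <- rep(NA, n_replicates)
    for (r in seq_len(n_replicates)) {
      dat <- simulate_validation_dataset(
        sc$p_target, sc$p_substitution, sc$noise_sd_deg,
        n_trials = sc$n_trials, design = design, seed = rep_seeds[r])
      for (nm in estimators) {
        est[r, nm] <- tryCatch(switch(
          nm,
          labelling = {
            lab <- nearest_model_label(dat$error_deg, dat$delta1_deg)
            mean(lab == "target")
          },
          standard_mixture = {
            fit <- fit_mixture(dat$error_deg, dat$delta1_deg,
                               model = "standard", seed = rep_seeds[r])
            fit$estimates[["p_target"]]
          },
          averaging_mixture = {
            fit <- fit_mixture(dat$error_deg, dat$delta1_deg,
                               model = "averaging", seed = rep_seeds[r])
            unstable[r] <- fit$unstable
            fit$estimates[["p_target"]]
          },
          monte_carlo = {
            mc <- monte_carlo_proportions(
              dat$error_deg, dat$delta1_deg,
              noise_sd_deg = sc$noise_sd_deg,
              n_sims_per_cell = mc_sims_per_cell, seed = rep_seeds[r])
            mc$p_target
          }), error = function(e) NA_real_)
      }
    }
    for (nm in estimators) {
      v <- est[, nm]
      okv <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        p_target = sc$p_target, p_substitution = sc$p_substitution,
        noise_sd_deg = sc$noise_sd_deg, n_trials = sc$n_trials,
        estimator = nm, n_replicates = n_replicates,
        mean_estimate = mean(okv),
        bias = mean(okv) - sc$p_target,
        mae = mean(abs(okv - sc$p_target)),
        rmse = sqrt(mean((okv - sc$p_target)^2)),
        instability_rate = if (nm == "averaging_mixture") {
          mean(unstable, na.rm = TRUE)
        } else NA_real_,
        n_failed = sum(is.na(v)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Parameter-recovery study (estimated vs generative p_target)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
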