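#' Generative observer model for continuous-report crowding trials
#'
#' Describes an observer whose report on each trial is drawn from a
#' mixture over report strategies: a report at the target orientation, at
#' the weighted average of target and near flanker gap, at the near
#' flanker gap (near substitution), at the far flanker gap (far
#' substitution), or a uniform random guess. All non-guess components are
#' perturbed by circular noise. Components that require a gap absent from
#' the trial's condition (e.g. far substitution on a one-gap trial) are
#' dropped and the remaining probabilities renormalised.
#'
#' @param p_target,p_average,p_sub_near,p_sub_far,p_guess component
#'   probabilities; must sum to 1.
#' @param average_weight interpolation weight w in \[0, 1\] of the
#'   averaging component: its mean is `target + w * delta1` along the
#'   short arc (0 = pure target, 1 = pure near flanker).
#' @param noise_sd_deg circular SD in degrees of the report noise applied
#'   to all components except the guess (which is already uniform).
#' @param noise_family `"von_mises"` (default) or `"wrapped_normal"`; at
#'   SDs below roughly 30 degrees the two are nearly indistinguishable.
#' @return object of class `"observer_model"`.
#' @examples
#' observer_model(p_target = 0.6, p_sub_near = 0.3, p_guess = 0.1,
#'                noise_sd_deg = 15)
#' @export
observer_model <- function(p_target = 1, p_average = 0, p_sub_near = 0,
                           p_sub_far = 0, p_guess = 0,
                           average_weight = 0.5, noise_sd_deg = 15,
                           noise_family = c("von_mises",
                                            "wrapped_normal")) {
  noise_family <- match.arg(noise_family)
  p <- c(target = p_target, average = p_average, sub_near = p_sub_near,
         sub_far = p_sub_far, guess = p_guess)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("component probabilities must sum to 1")
  if (average_weight < 0 || average_weight > 1) {
    stop("average_weight must lie in [0, 1]")
  }
  if (noise_sd_deg < 0) stop("noise_sd_deg must be non-negative")
  structure(list(p = p, average_weight = average_weight,
                 noise_sd_deg = noise_sd_deg,
                 noise_family = noise_family),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Observer report mixture:\n")
  print(round(x$p, 4))
  cat(sprintf("  averaging weight w = %g; noise SD = %g deg (%s)\n",
              x$average_weight, x$noise_sd_deg, x$noise_family))
  invisible(x)
}

# which mixture components are available for a flanker type
component_availability <- function(flanker_type) {
  has_gap1 <- flanker_type == "one_gap" | flanker_type == "two_gap"
  has_gap2 <- flanker_type == "two_gap"
  cbind(target = TRUE, average = has_gap1, sub_near = has_gap1,
        sub_far = has_gap2, guess = TRUE)
}

# circular noise draws centred on zero with a given circular SD; below the
# SD floor representable by the bounded von Mises concentration the two
# families coincide to numerical precision, so wrapped normal is used there
draw_noise <- function(n, sd_deg, family) {
  if (n == 0L || sd_deg == 0) return(numeric(n))
  if (family == "von_mises" && sd_deg > kappa_to_circ_sd(500)) {
    wrap_deg(rvonmises_deg(n, 0, circ_sd_to_kappa(sd_deg)))
  } else {
    wrap_deg(stats::rnorm(n, 0, sd_deg))
  }
}

#' Sample flanker-gap orientations for a trial
#'
#' Draws the flanker-gap orientation(s) the stimulus program would have
#' used: on one-gap trials the gap is drawn from a normal distribution
#' centred on the target orientation with SD `design$flanker_offset_sd_deg`
#' (22.5 degrees by default, the range producing maximal crowding); on
#' two-gap trials a second gap is additionally drawn from a normal
#' distribution centred `design$far_gap_center_deg` (180 degrees) from the
#' first gap with the same SD. No-gap and unflanked trials have no gaps.
#'
#' @param target_deg target orientation(s) in degrees; vectorised.
#' @param flanker_type a single flanker type or a vector matching
#'   `target_deg` (`"unflanked"`, `"no_gap"`, `"one_gap"`, `"two_gap"`).
#' @param design a [crowding_design()].
#' @param seed optional integer seed.
#' @return data.frame with columns `gap1_deg` and `gap2_deg` in
#'   \[0, 360), `NA` where the condition has no such gap.
#' @examples
#' g <- sample_flanker_gaps(rep(0, 1000), "one_gap", seed = 1)
#' sd(wrap_deg(g$gap1_deg))  # about 22.5
#' @export
sample_flanker_gaps <- function(target_deg, flanker_type,
                                design = crowding_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(target_deg)
  flanker_type <- rep_len(as.character(flanker_type), n)
  gap1 <- rep(NA_real_, n)
  gap2 <- rep(NA_real_, n)
  has1 <- flanker_type %in% c("one_gap", "two_gap")
  if (any(has1)) {
    gap1[has1] <- wrap360(target_deg[has1] +
                            stats::rnorm(sum(has1), 0,
                                         design$flanker_offset_sd_deg))
  }
  has2 <- flanker_type == "two_gap"
  if (any(has2)) {
    gap2[has2] <- wrap360(gap1[has2] +
                            stats::rnorm(sum(has2),
                                         design$far_gap_center_deg,
                                         design$flanker_offset_sd_deg))
  }
  data.frame(gap1_deg = gap1, gap2_deg = gap2)
}

#' Simulate observer reports for a trial table
#'
#' For each trial, draws a report strategy from the observer model's
#' mixture (renormalised over the components available in that trial's
#' condition), computes the component mean — target orientation, circular
#' interpolation `target + w * delta1`, near gap, far gap, or uniform — and
#' adds circular noise to all but the guess component.
#'
#' @param trials data.frame with columns `flanker_type`, `target_deg`,
#'   `gap1_deg`, `gap2_deg`.
#' @param model an [observer_model()].
#' @param seed optional integer seed.
#' @param keep_truth if `TRUE`, attach the drawn component label as
#'   attribute-free column `truth_label`.
#' @return `trials` with columns `report_deg` (in \[0, 360)) and, if
#'   requested, `truth_label`.
#' @export
simulate_report <- function(trials, model, seed = NULL,
                            keep_truth = TRUE) {
  stopifnot(inherits(model, "observer_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  ft <- as.character(trials$flanker_type)
  avail <- component_availability(ft)
  W <- sweep(avail, 2, model$p, `*`)
  tot <- rowSums(W)
  if (any(tot <= 0)) {
    stop("observer model places all probability on components absent ",
         "from some trials' conditions")
  }
  W <- W / tot
  # inverse-CDF draw of the component per trial (cumsum across the five
  # columns, vectorised over trials)
  u <- stats::runif(n)
  cum <- W
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
  comp_idx <- rowSums(u > cum) + 1L
  comp_idx[comp_idx > ncol(cum)] <- ncol(cum)
  comp <- colnames(avail)[comp_idx]

  delta1 <- wrap_deg_na(trials$gap1_deg - trials$target_deg)
  mean_deg <- trials$target_deg
  mean_deg[comp == "average"] <- trials$target_deg[comp == "average"] +
    model$average_weight * delta1[comp == "average"]
  mean_deg[comp == "sub_near"] <- trials$gap1_deg[comp == "sub_near"]
  mean_deg[comp == "sub_far"] <- trials$gap2_deg[comp == "sub_far"]

  report <- numeric(n)
  noisy <- comp != "guess"
  report[noisy] <- wrap360(mean_deg[noisy] +
                             draw_noise(sum(noisy), model$noise_sd_deg,
                                        model$noise_family))
  report[!noisy] <- stats::runif(sum(!noisy), 0, 360)
  trials$report_deg <- report
  if (keep_truth) trials$truth_label <- comp
  trials
}

# wrap that passes NA through
wrap_deg_na <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- wrap_deg(x[ok])
  out
}

#' Simulate a full continuous-report crowding experiment
#'
#' Generates one observer's complete dataset under the design: every
#' condition repeated `reps_per_condition_per_session` times in each of
#' `n_sessions` sessions (the default design gives 320 trials per session
#' and 1600 in total, 100 per condition), with target orientations drawn
#' uniformly on \[0, 360), flanker gaps drawn by [sample_flanker_gaps()],
#' trial order randomised within session, and reports drawn from the
#' observer model. Fully reproducible from `seed`.
#'
#' @param design a [crowding_design()].
#' @param model an [observer_model()].
#' @param observer_id label stored in the `observer_id` column.
#' @param seed optional integer seed.
#' @param keep_truth store the generative component label per trial.
#' @return data.frame of trials with columns `observer_id`, `session`,
#'   `flanker_type`, `edge_separation_deg`, `target_deg`, `gap1_deg`,
#'   `gap2_deg`, `report_deg`, `error_deg`, `delta1_deg`, `delta2_deg`
#'   and optionally `truth_label`.
#' @export
simulate_experiment <- function(design = crowding_design(),
                                model = observer_model(),
                                observer_id = "S1", seed = NULL,
                                keep_truth = TRUE) {
  validate_design(design)
  if (!is.null(seed)) set.seed(seed)
  conds <- enumerate_conditions(design)
  reps <- design$reps_per_condition_per_session
  per_session <- conds[rep(seq_len(nrow(conds)), each = reps),
                       c("flanker_type", "edge_separation_deg")]
  sessions <- vector("list", design$n_sessions)
  for (s in seq_len(design$n_sessions)) {
    tr <- per_session[sample.int(nrow(per_session)), , drop = FALSE]
    tr$session <- s
    sessions[[s]] <- tr
  }
  trials <- do.call(rbind, sessions)
  rownames(trials) <- NULL
  n <- nrow(trials)
  trials$observer_id <- observer_id
  trials$target_deg <- stats::runif(n, 0, 360)
  gaps <- sample_flanker_gaps(trials$target_deg,
                              as.character(trials$flanker_type), design)
  trials$gap1_deg <- gaps$gap1_deg
  trials$gap2_deg <- gaps$gap2_deg
  trials <- simulate_report(trials, model, keep_truth = keep_truth)
  trials <- compute_errors(trials)
  cols <- c("observer_id", "session", "flanker_type",
            "edge_separation_deg", "target_deg", "gap1_deg", "gap2_deg",
            "report_deg", "error_deg", "delta1_deg", "delta2_deg")
  if (keep_truth) cols <- c(cols, "truth_label")
  trials[, cols]
}

#' Simulate the two-component validation dataset
#'
#' Generates the dataset used to validate the proportion estimators: a
#' one-gap-style set of trials whose reports are either at the target
#' orientation (probability `p_target`) or at the flanker-gap orientation
#' (probability `p_substitution`), plus circular noise. Gap offsets are
#' drawn from the design's experimental distribution (SD 22.5 degrees) by
#' default, or fixed at `fixed_delta_deg`. Ground-truth component labels
#' are returned so recovery studies can score estimators per trial.
#'
#' Noise is wrapped-normal by default: this generator mirrors a
#' Gaussian-noise simulation, while the fitted mixture models use von
#' Mises components — at these SDs the two families are nearly
#' indistinguishable, which is itself part of what the recovery study
#' checks.
#'
#' @param p_target,p_substitution component probabilities summing to 1.
#' @param noise_sd_deg circular noise SD in degrees.
#' @param n_trials number of trials (default 100, one condition's worth).
#' @param design a [crowding_design()] (supplies the gap-offset SD).
#' @param fixed_delta_deg if non-`NULL`, use this constant target--gap
#'   offset instead of sampling offsets.
#' @param noise_family `"wrapped_normal"` (default) or `"von_mises"`.
#' @param seed optional integer seed.
#' @return trial data.frame as from [simulate_experiment()] (one-gap
#'   rows only) including `truth_label`.
#' @export
simulate_validation_dataset <- function(p_target, p_substitution,
                                        noise_sd_deg, n_trials = 100,
                                        design = crowding_design(),
                                        fixed_delta_deg = NULL,
                                        noise_family = c("wrapped_normal",
                                                         "von_mises"),
                                        seed = NULL) {
  noise_family <- match.arg(noise_family)
  if (abs(p_target + p_substitution - 1) > 1e-9) {
    stop("p_target + p_substitution must equal 1")
  }
  if (!is.null(seed)) set.seed(seed)
  trials <- data.frame(
    observer_id = "sim", session = 1L,
    flanker_type = factor("one_gap",
                          levels = c("unflanked", "no_gap", "one_gap",
                                     "two_gap")),
    edge_separation_deg = design$edge_separations_deg[1],
    target_deg = stats::runif(n_trials, 0, 360)
  )
  if (is.null(fixed_delta_deg)) {
    gaps <- sample_flanker_gaps(trials$target_deg, "one_gap", design)
    trials$gap1_deg <- gaps$gap1_deg
  } else {
    trials$gap1_deg <- wrap360(trials$target_deg + fixed_delta_deg)
  }
  trials$gap2_deg <- NA_real_
  model <- observer_model(p_target = p_target, p_sub_near = p_substitution,
                          noise_sd_deg = noise_sd_deg,
                          noise_family = noise_family)
  trials <- simulate_report(trials, model, keep_truth = TRUE)
  compute_errors(trials)
}
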