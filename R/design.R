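#' Stimulus design of the crowding experiment
#'
#' Bundles every stimulus and session constant of the continuous-report
#' crowding experiment in one object so the synthetic generator and all
#' analysis stages share a single parameterisation. Defaults encode the
#' study conditions: a Landolt-C target centred 10 degrees in the
#' periphery (2 degree diameter, 0.4 degree line and gap width), ring
#' flankers at edge-to-edge separations of 0.4, 0.92, 1.62, 2.58 or 3.9
#' degrees (plus an unflanked condition), flanker-gap offsets drawn with
#' SD 22.5 degrees around the target orientation, a second gap centred
#' 180 degrees away, and 20 repetitions of each of 16 conditions per
#' session for 5 sessions.
#'
#' The unflanked condition is represented by the sentinel value `NA` in
#' `edge_separation_deg` columns, never a numeric infinity.
#'
#' @param eccentricity_deg target eccentricity in degrees of visual angle.
#' @param target_diameter_deg target outer diameter in degrees.
#' @param line_width_deg stroke width of target and flankers in degrees.
#' @param gap_width_deg gap width (at the line-width midpoint) in degrees.
#' @param edge_separations_deg strictly increasing positive edge-to-edge
#'   target--flanker separations in degrees.
#' @param flanker_types character subset of
#'   `c("unflanked", "no_gap", "one_gap", "two_gap")`.
#' @param flanker_offset_sd_deg SD (degrees) of the normal distribution
#'   from which flanker-gap orientation offsets are drawn.
#' @param far_gap_center_deg centre (degrees) of the second-gap offset
#'   relative to the first gap; in (0, 180].
#' @param reps_per_condition_per_session repetitions of each condition in
#'   one session.
#' @param n_sessions number of sessions.
#' @param target_duration_ms stimulus duration (metadata only; the
#'   generator does not model temporal dynamics).
#' @return an object of class `"crowding_design"` (a validated list).
#' @examples
#' d <- crowding_design()
#' nrow(enumerate_conditions(d))  # 16
#' @export
crowding_design <- function(eccentricity_deg = 10,
                            target_diameter_deg = 2,
                            line_width_deg = 0.4,
                            gap_width_deg = 0.4,
                            edge_separations_deg = c(0.4, 0.92, 1.62,
                                                     2.58, 3.9),
                            flanker_types = c("unflanked", "no_gap",
                                              "one_gap", "two_gap"),
                            flanker_offset_sd_deg = 22.5,
                            far_gap_center_deg = 180,
                            reps_per_condition_per_session = 20,
                            n_sessions = 5,
                            target_duration_ms = 500) {
  design <- list(
    eccentricity_deg = eccentricity_deg,
    target_diameter_deg = target_diameter_deg,
    line_width_deg = line_width_deg,
    gap_width_deg = gap_width_deg,
    edge_separations_deg = edge_separations_deg,
    flanker_types = flanker_types,
    flanker_offset_sd_deg = flanker_offset_sd_deg,
    far_gap_center_deg = far_gap_center_deg,
    reps_per_condition_per_session = reps_per_condition_per_session,
    n_sessions = n_sessions,
    target_duration_ms = target_duration_ms
  )
  validate_design(design)
  structure(design, class = "crowding_design")
}

validate_design <- function(d) {
  stopifnot(
    d$eccentricity_deg > 0,
    d$target_diameter_deg > 0,
    d$line_width_deg > 0,
    d$gap_width_deg > 0,
    d$flanker_offset_sd_deg >= 0,
    d$far_gap_center_deg > 0, d$far_gap_center_deg <= 180,
    d$reps_per_condition_per_session >= 1,
    d$n_sessions >= 1
  )
  sep <- d$edge_separations_deg
  if (length(sep) == 0 || any(sep <= 0) || any(diff(sep) <= 0)) {
    stop("edge_separations_deg must be strictly increasing and positive")
  }
  bad <- setdiff(d$flanker_types,
                 c("unflanked", "no_gap", "one_gap", "two_gap"))
  if (length(bad)) stop("unknown flanker type(s): ",
                        paste(bad, collapse = ", "))
  invisible(d)
}

#' @export
print.crowding_design <- function(x, ...) {
  cat("Crowding experiment design\n")
  cat(sprintf("  eccentricity: %g deg; target diameter: %g deg; line/gap width: %g/%g deg\n",
              x$eccentricity_deg, x$target_diameter_deg,
              x$line_width_deg, x$gap_width_deg))
  cat("  edge separations (deg):",
      paste(x$edge_separations_deg, collapse = ", "), "\n")
  cat("  flanker types:", paste(x$flanker_types, collapse = ", "), "\n")
  cat(sprintf("  gap-offset SD: %g deg; far-gap centre: %g deg\n",
              x$flanker_offset_sd_deg, x$far_gap_center_deg))
  nc <- nrow(enumerate_conditions(x))
  cat(sprintf("  %d conditions x %d reps x %d sessions = %d trials/observer\n",
              nc, x$reps_per_condition_per_session, x$n_sessions,
              nc * x$reps_per_condition_per_session * x$n_sessions))
  invisible(x)
}

#' Flanker radius as a proportion of eccentricity
#'
#' Expresses a target--flanker condition as the flanker outer radius
#' divided by the eccentricity of its centre (units of Bouma's constant):
#' `(target_diameter/2 + edge_separation) / eccentricity`, since the
#' flanker's outer radius equals the target's outer radius plus the
#' edge-to-edge separation. For the five standard separations this gives
#' 0.14, 0.19, 0.26, 0.36 and 0.49 (to 2 d.p.). Full precision is
#' returned; rounding is left to reporting code.
#'
#' @param edge_separation_deg edge-to-edge separation(s) in degrees
#'   (>= 0); vectorised.
#' @param design a [crowding_design()].
#' @return unitless proportion(s).
#' @export
proportional_radius <- function(edge_separation_deg,
                                design = crowding_design()) {
  if (any(!is.finite(edge_separation_deg)) ||
      any(edge_separation_deg < 0)) {
    stop("edge_separation_deg must be finite and non-negative")
  }
  if (design$eccentricity_deg <= 0 || design$target_diameter_deg <= 0) {
    stop("design must have positive eccentricity and target diameter")
  }
  (design$target_diameter_deg / 2 + edge_separation_deg) /
    design$eccentricity_deg
}

#' Enumerate the experiment's conditions
#'
#' Expands a design into its condition table in a fixed canonical order:
#' unflanked first, then flanker types in the order no-gap, one-gap,
#' two-gap, each by increasing separation. The order the observer actually
#' experienced conditions in is a generator concern ([simulate_experiment()]
#' randomises trial order within session); a fixed enumeration keeps
#' per-condition outputs comparable across runs.
#'
#' @param design a [crowding_design()].
#' @return data.frame with columns `flanker_type` (factor),
#'   `edge_separation_deg` (NA for unflanked) and `proportional_radius`
#'   (NA for unflanked).
#' @export
enumerate_conditions <- function(design = crowding_design()) {
  validate_design(design)
  type_order <- c("unflanked", "no_gap", "one_gap", "two_gap")
  types <- intersect(type_order, design$flanker_types)
  rows <- list()
  if ("unflanked" %in% types) {
    rows[[1]] <- data.frame(flanker_type = "unflanked",
                            edge_separation_deg = NA_real_)
  }
  for (ft in setdiff(types, "unflanked")) {
    rows[[length(rows) + 1L]] <-
      data.frame(flanker_type = ft,
                 edge_separation_deg = design$edge_separations_deg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$flanker_type <- factor(out$flanker_type, levels = type_order)
  out$proportional_radius <- ifelse(
    is.na(out$edge_separation_deg), NA_real_,
    proportional_radius(ifelse(is.na(out$edge_separation_deg), 0,
                               out$edge_separation_deg), design))
  out
}

#' Read or write a design as a YAML configuration file
#'
#' Serialises all design fields so a run can be reproduced from its config
#' snapshot. `read_design()` fills unspecified fields with the defaults of
#' [crowding_design()].
#'
#' @param design a [crowding_design()].
#' @param path file path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a `crowding_design`.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(crowding_design))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown design field(s): ",
                        paste(bad, collapse = ", "))
  do.call(crowding_design, cfg)
}
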