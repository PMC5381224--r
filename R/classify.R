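#' Derive wrapped report errors and flanker deltas
#'
#' Fills the derived angular columns of a trial table: the report error
#' `error_deg = wrap(report - target)` and the flanker-gap offsets
#' `delta1_deg = wrap(gap1 - target)`, `delta2_deg = wrap(gap2 - target)`,
#' all wrapped into (-180, 180]. Positive values are clockwise of the
#' target. Rows with a missing report are dropped with a warning naming
#' how many were excluded.
#'
#' @param trials data.frame with at least `target_deg` and `report_deg`;
#'   `gap1_deg`/`gap2_deg` optional.
#' @return the trial table with `error_deg`, `delta1_deg`, `delta2_deg`
#'   columns filled.
#' @export
compute_errors <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("target_deg", "report_deg") %in% names(trials)))
  missing_rep <- is.na(trials$report_deg)
  if (any(missing_rep)) {
    warning(sum(missing_rep), " trial(s) with missing report excluded")
    trials <- trials[!missing_rep, , drop = FALSE]
  }
  trials$error_deg <- wrap_deg(trials$report_deg - trials$target_deg)
  g1 <- if ("gap1_deg" %in% names(trials)) trials$gap1_deg else NA_real_
  g2 <- if ("gap2_deg" %in% names(trials)) trials$gap2_deg else NA_real_
  trials$delta1_deg <- wrap_deg_na(g1 - trials$target_deg)
  trials$delta2_deg <- wrap_deg_na(g2 - trials$target_deg)
  trials
}

# grouping key robust to NA cells (the unflanked separation sentinel)
group_key <- function(df, cols) {
  cols <- intersect(cols, names(df))
  parts <- lapply(df[cols], function(v) {
    v <- as.character(v); v[is.na(v)] <- "none"; v
  })
  interaction(parts, drop = TRUE, lex.order = TRUE)
}

#' Split two-gap trials into near and far-gap reports
#'
#' Two-gap report errors form two clusters, one around the target and one
#' around its polar opposite (the far flanker gap). Reports with an
#' absolute error strictly greater than `threshold_deg` (90 degrees) are
#' classified as far-gap reports; errors of exactly the threshold count as
#' near. Returns the two subsets and a per-condition summary of the
#' far-gap proportion with percentile-bootstrap confidence intervals.
#'
#' @param trials two-gap trial table with errors computed
#'   (see [compute_errors()]).
#' @param threshold_deg classification cut in degrees (default 90).
#' @param group_by columns defining a condition for the summary.
#' @param n_boot,level,seed bootstrap settings for the proportion CIs.
#' @return list with elements `near`, `far` (disjoint subsets whose row
#'   counts sum to `nrow(trials)`) and `summary` (data.frame with
#'   `n`, `n_far`, `proportion_far`, `ci_lower`, `ci_upper` per group).
#' @export
split_far_gap <- function(trials, threshold_deg = 90,
                          group_by = c("observer_id", "flanker_type",
                                       "edge_separation_deg"),
                          n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot("error_deg" %in% names(trials))
  if (!all(as.character(trials$flanker_type) == "two_gap")) {
    stop("split_far_gap expects only two-gap trials")
  }
  is_far <- abs(trials$error_deg) > threshold_deg
  if (!is.null(seed)) set.seed(seed)
  group_by <- intersect(group_by, names(trials))
  key <- group_key(trials, group_by)
  summ <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key),
                                function(idx) {
    flags <- is_far[idx]
    ci <- bootstrap_ci(flags, mean, n_boot = n_boot, level = level)
    cbind(trials[idx[1], group_by, drop = FALSE],
          data.frame(n = length(idx), n_far = sum(flags),
                     proportion_far = mean(flags),
                     ci_lower = ci$lower, ci_upper = ci$upper))
  }))
  rownames(summ) <- NULL
  list(near = trials[!is_far, , drop = FALSE],
       far = trials[is_far, , drop = FALSE],
       summary = summ)
}

#' Re-center far-gap reports
#'
#' Far-gap reports cluster around the target's polar opposite. Subtracting
#' 180 degrees from both the report error and the target--far-gap offset
#' (with wrapping) brings them into the same frame as the near analyses:
#' after re-centering, an error of 0 corresponds to a report of the
#' target's polar opposite, and reports following the far gap fall on the
#' line of unity against the re-centred `delta2_deg`.
#'
#' @param far data.frame of far-gap trials (from [split_far_gap()]) with
#'   `error_deg` and `delta2_deg` present.
#' @return the table with `error_deg` and `delta2_deg` re-centred.
#' @export
recenter_far <- function(far) {
  stopifnot(all(c("error_deg", "delta2_deg") %in% names(far)))
  if (any(is.na(far$delta2_deg))) {
    stop("delta2_deg missing; re-centering requires two-gap trials")
  }
  far$error_deg <- wrap_deg(far$error_deg - 180)
  far$delta2_deg <- wrap_deg(far$delta2_deg - 180)
  far
}

#' Label a report error by its nearest model prediction
#'
#' Compares each report error against the three model predictions for its
#' trial — a target report (error 0), an average report (error
#' `delta / 2`) and a substitution report (error `delta`) — using circular
#' (wrapped) distances, and returns the nearest. Ties are broken by the
#' fixed priority target > average > substitution, so labelling is
#' deterministic.
#'
#' @param error_deg wrapped report error(s) in degrees.
#' @param delta_deg the relevant flanker-gap offset(s): `delta1_deg` for
#'   near analyses, the re-centred `delta2_deg` for far analyses.
#' @return factor with levels `target`, `average`, `substitution`.
#' @examples
#' nearest_model_label(c(0, 22, 39, 10), 40)
#' @export
nearest_model_label <- function(error_deg, delta_deg) {
  n <- max(length(error_deg), length(delta_deg))
  error_deg <- rep_len(error_deg, n)
  delta_deg <- rep_len(delta_deg, n)
  if (any(is.na(delta_deg))) stop("delta_deg must be present for labelling")
  d_target <- abs(wrap_deg(error_deg))
  d_average <- abs(wrap_deg(error_deg - delta_deg / 2))
  d_sub <- abs(wrap_deg(error_deg - delta_deg))
  # argmin with priority target > average > substitution on ties
  lab <- rep("substitution", n)
  lab[d_average <= d_sub] <- "average"
  lab[d_target <= d_average & d_target <= d_sub] <- "target"
  factor(lab, levels = c("target", "average", "substitution"))
}

#' Per-condition proportions of report types
#'
#' Labels every trial with [nearest_model_label()] and tabulates, per
#' group, the proportion of target, average and substitution reports
#' (summing to 1 within each non-empty group), with optional
#' percentile-bootstrap confidence intervals on each proportion.
#'
#' @param trials trial table with errors computed.
#' @param group_by columns defining a group; use
#'   `c("flanker_type", "edge_separation_deg")` to pool observers.
#' @param delta_col which offset column supplies the model axis
#'   (`"delta1_deg"` for near analyses, `"delta2_deg"` for re-centred
#'   far-gap analyses).
#' @param ci compute bootstrap CIs for each proportion.
#' @param n_boot,level,seed bootstrap settings.
#' @return data.frame, one row per (group, report type), with columns
#'   `label`, `proportion`, `n` and, if `ci`, `ci_lower`/`ci_upper`.
#' @export
label_proportions <- function(trials,
                              group_by = c("observer_id", "flanker_type",
                                           "edge_separation_deg"),
                              delta_col = "delta1_deg", ci = FALSE,
                              n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot("error_deg" %in% names(trials), delta_col %in% names(trials))
  labs <- nearest_model_label(trials$error_deg, trials[[delta_col]])
  if (!is.null(seed)) set.seed(seed)
  group_by <- intersect(group_by, names(trials))
  key <- group_key(trials, group_by)
  lev <- levels(labs)
  out <- do.call(rbind, lapply(split(seq_along(labs), key),
                               function(idx) {
    li <- labs[idx]
    props <- as.numeric(table(li) / length(li))
    res <- cbind(trials[rep(idx[1], length(lev)), group_by,
                        drop = FALSE],
                 data.frame(label = factor(lev, levels = lev),
                            proportion = props, n = length(idx)))
    if (ci) {
      cis <- lapply(lev, function(lv) {
        bootstrap_ci(as.character(li), function(z) mean(z == lv),
                     n_boot = n_boot, level = level)
      })
      res$ci_lower <- vapply(cis, `[[`, numeric(1), "lower")
      res$ci_upper <- vapply(cis, `[[`, numeric(1), "upper")
    }
    res
  }))
  rownames(out) <- NULL
  out
}
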