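trial_schema_required <- c("observer_id", "session", "flanker_type",
                           "edge_separation_deg", "target_deg",
                           "gap1_deg", "gap2_deg", "report_deg")

#' Read and validate a trial table from CSV
#'
#' Reads a trial-level CSV (one row per trial; degrees throughout; empty
#' cells for absent gaps) and validates it against the package schema:
#' required columns `observer_id`, `session`, `flanker_type`,
#' `edge_separation_deg`, `target_deg`, `gap1_deg`, `gap2_deg`,
#' `report_deg`; orientations within \[0, 360); gap presence matching the
#' flanker type. Violations are reported with row numbers. Derived error
#' columns are (re)computed on read.
#'
#' @param path CSV file path.
#' @return validated trial data.frame with derived `error_deg`,
#'   `delta1_deg`, `delta2_deg` columns.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_schema_required, names(tab))
  if (length(missing_cols)) {
    stop("trial table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_trials(tab)
  tab$flanker_type <- factor(tab$flanker_type,
                             levels = c("unflanked", "no_gap", "one_gap",
                                        "two_gap"))
  compute_errors(tab)
}

validate_trials <- function(tab) {
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf(
        "%s (rows %s)", what,
        paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  bad_type <- which(!tab$flanker_type %in%
                      c("unflanked", "no_gap", "one_gap", "two_gap"))
  note(bad_type, "unknown flanker_type")
  for (col in c("target_deg", "report_deg", "gap1_deg", "gap2_deg")) {
    v <- tab[[col]]
    note(which(!is.na(v) & (v < 0 | v >= 360)),
         paste0(col, " outside [0, 360)"))
  }
  ft <- tab$flanker_type
  note(which(ft %in% c("one_gap", "two_gap") & is.na(tab$gap1_deg)),
       "gap1_deg missing on gapped-flanker trial")
  note(which(ft == "two_gap" & is.na(tab$gap2_deg)),
       "gap2_deg missing on two-gap trial")
  note(which(ft %in% c("unflanked", "no_gap") &
               (!is.na(tab$gap1_deg) | !is.na(tab$gap2_deg))),
       "gap recorded on gapless trial")
  note(which(!is.na(ft) & ft != "unflanked" &
               is.na(tab$edge_separation_deg)),
       "edge_separation_deg missing on flanked trial")
  if (length(problems)) {
    stop("trial table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(tab)
}

#' Write a trial table to CSV (with sidecar metadata)
#'
#' Writes the schema columns (plus `truth_label` when present) as plain
#' CSV with empty cells for absent gaps, and optionally a sidecar JSON
#' file echoing generator metadata (seed, model parameters) so a
#' synthetic table documents its own provenance. Round-trips losslessly
#' through [read_trials()] up to the derived error columns, which are
#' recomputed on read.
#'
#' @param trials trial data.frame.
#' @param path output CSV path.
#' @param metadata optional named list written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, metadata = NULL) {
  keep <- c(trial_schema_required,
            intersect("truth_label", names(trials)))
  missing_cols <- setdiff(trial_schema_required, names(trials))
  if (length(missing_cols)) {
    stop("trial table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials[, keep], path, row.names = FALSE, na = "")
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
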