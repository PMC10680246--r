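PANEL_COLS <- c("day", "fbg", "ppg_breakfast", "ppg_lunch", "ppg_dinner",
                "bg_0300")

#' Read and validate a glucose-panel CSV
#'
#' Dialect: comma-separated, UTF-8, mandatory header, one row per day,
#' columns `day, fbg, ppg_breakfast, ppg_lunch, ppg_dinner, bg_0300`, all
#' glucose in mmol/L with a decimal point. Readings must lie in
#' (0, 60) mmol/L; `bg_0300` may be missing (NA) but the scheduled daytime
#' readings may not.
#'
#' @param path CSV file path.
#' @return Data frame with the panel columns, ordered by day.
#' @export
read_glucose_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PANEL_COLS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(PANEL_COLS, "day")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v <= 0 | v >= 60))
    if (length(bad)) {
      stop(sprintf("%s: implausible %s at data line %d (%.1f mmol/L)",
                   path, col, bad[1], v[bad[1]]))
    }
  }
  if (anyNA(df$day) || any(df$day < 1) || anyDuplicated(df$day)) {
    stop(sprintf("%s: `day` must be unique integers >= 1", path))
  }
  df[order(df$day), PANEL_COLS]
}

#' @rdname read_glucose_panels
#' @param panels Panel data frame.
#' @export
write_glucose_panels <- function(panels, path) {
  utils::write.csv(panels[, intersect(PANEL_COLS, names(panels))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write simulated trial results to a directory
#'
#' Emits `records.csv` (one row per patient), `hypo_events.csv` (one row
#' per hypoglycemic reading) and `meta.json` (seed, arm sizes,
#' configuration hash, package version) — everything [read_trial_results()]
#' needs to reanalyze the run.
#'
#' @param trial A `wit2_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_results <- function(trial, dir) {
  stopifnot(inherits(trial, "wit2_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$hypo, file.path(dir, "hypo_events.csv"),
                   row.names = FALSE)
  meta <- trial$meta
  meta$n_arms <- as.list(meta$n_arms)   # keep arm names in the JSON object
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial_results
#' @export
read_trial_results <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  hypo <- utils::read.csv(file.path(dir, "hypo_events.csv"),
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$n_arms <- unlist(meta$n_arms)
  structure(list(records = records, hypo = hypo, meta = meta),
            class = "wit2_trial")
}

#' Write a per-day dose ledger as CSV
#'
#' Accepts the `ledger` data frame produced by [replay_protocol()] or by
#' [run_patient()] with `trace = TRUE` (columns: day, per-kg doses,
#' administered whole units, per-injection reason codes).
#'
#' @param ledger Ledger data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_dose_ledger <- function(ledger, path) {
  stopifnot(is.data.frame(ledger), "day" %in% names(ledger))
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation run configuration from YAML
#'
#' Recognized top-level keys: any [cohort_config()] argument, plus `arm`
#' behaviour switches `hypo_action` and `bolus_stop` and optional
#' `n_arms` (length-2). Unknown keys are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return List with `$config` (a `wit2_cohort_config`), `$n_arms`,
#'   `$hypo_action`, `$bolus_stop`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- c("n_arms", "hypo_action", "bolus_stop")
  known <- c(names(formals(cohort_config)), extra)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(cohort_config, raw[setdiff(names(raw), extra)])
  list(
    config = cfg,
    n_arms = if (!is.null(raw$n_arms)) as.integer(unlist(raw$n_arms)),
    hypo_action = if (is.null(raw$hypo_action)) "reduce" else raw$hypo_action,
    bolus_stop = if (is.null(raw$bolus_stop)) "suspend" else raw$bolus_stop
  )
}
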