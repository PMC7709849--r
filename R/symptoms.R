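#' The ten daily symptoms
#'
#' Column names used for daily severity reports, in the order the morning
#' rating presents them: pain; fatigue/tiredness; sleep disturbance; trouble
#' concentrating or remembering; feeling sad or down; feeling anxious or
#' worried; shortness of breath; numbness or tingling; nausea; diarrhea or
#' constipation. Each is rated 0 (not present) to 10 (as bad as you can
#' imagine).
#'
#' @return Character vector of length 10.
#' @export
symptom_names <- function() {
  c("pain", "fatigue", "sleep_disturbance", "concentration", "sadness",
    "anxiety", "shortness_of_breath", "numbness_tingling", "nausea",
    "bowel_changes")
}

#' Validate a table of daily symptom reports
#'
#' Checks that every report carries all 10 symptoms, severities are integers
#' in 0..10, and no date appears twice. Severities supplied as strings (e.g.
#' `"7"`) are coerced.
#'
#' @param reports A data frame with a `date` column and one column per
#'   symptom in [symptom_names()].
#' @return A validated, date-sorted tibble.
#' @examples
#' r <- tibble::tibble(date = as.Date("2025-03-01"))
#' r[symptom_names()] <- as.list(rep(0L, 10))
#' validate_reports(r)
#' @export
validate_reports <- function(reports) {
  reports <- tibble::as_tibble(reports)
  if (!"date" %in% names(reports)) abort("reports: missing 'date' column")
  missing_sym <- setdiff(symptom_names(), names(reports))
  if (length(missing_sym) > 0) {
    abort(paste0("reports: missing symptom column(s): ",
                 paste(missing_sym, collapse = ", ")))
  }
  extra <- setdiff(names(reports), c("date", symptom_names()))
  if (length(extra) > 0) {
    abort(paste0("reports: unknown column(s): ", paste(extra, collapse = ", ")))
  }
  reports$date <- as.Date(reports$date)
  if (anyNA(reports$date)) abort("reports: unparseable date")
  if (anyDuplicated(reports$date)) {
    dup <- reports$date[duplicated(reports$date)][1]
    abort(paste0("reports: duplicate report for date ", dup))
  }
  for (s in symptom_names()) {
    v <- reports[[s]]
    vi <- suppressWarnings(as.integer(v))
    if (anyNA(vi) || any(vi != as.numeric(v))) {
      abort(paste0("reports: non-integer severity in '", s, "'"))
    }
    if (any(vi < 0L | vi > 10L)) {
      abort(paste0("reports: severity out of 0..10 in '", s, "'"))
    }
    reports[[s]] <- vi
  }
  dplyr::arrange(reports[c("date", symptom_names())], .data$date)
}

#' Is a report a severe-symptom report?
#'
#' A day counts as severe when any of the 10 symptoms is rated at or above
#' the cutoff (default 7, inclusive).
#'
#' @param reports A validated report tibble (one or more rows).
#' @param severe_cutoff Severity cutoff, default 7.
#' @return Logical vector, one element per report row.
#' @examples
#' r <- tibble::tibble(date = as.Date("2025-03-01"))
#' r[symptom_names()] <- as.list(rep(0L, 10)); r$pain <- 7L
#' classify_severe(r)
#' @export
classify_severe <- function(reports, severe_cutoff = 7L) {
  m <- as.matrix(reports[symptom_names()])
  apply(m, 1, max) >= severe_cutoff
}

#' Daily effective symptom state and sedentary threshold
#'
#' For each study day, the effective report is the day's own rating if one
#' was completed, otherwise the most recent earlier rating carried forward
#' (last observation carried forward, no expiry). Days with no rating on or
#' before them have no effective report and use the non-severe threshold.
#' The selected sedentary-bout threshold is `threshold_severe` when any
#' effective severity is at or above `severe_cutoff`, else `threshold_normal`.
#'
#' @param reports Symptom reports for one participant (passed through
#'   [validate_reports()]).
#' @param schedule A [study_schedule()]; states are produced for every study day.
#' @param config An [engine_config()].
#' @return A tibble with one row per study day: `date`, `phase`,
#'   `has_own_report`, `is_carried_forward`, `report_date` (date of the
#'   effective report, `NA` if none), `max_severity`, `severe_day`,
#'   `sb_threshold`.
#' @export
daily_symptom_states <- function(reports, schedule, config = engine_config()) {
  config <- as_engine_config(config)
  reports <- validate_reports(reports)
  days <- study_days(schedule)

  if (nrow(reports) == 0) {
    eff_idx <- rep(NA_integer_, nrow(days))
  } else {
    # index of most recent report on or before each day
    eff_idx <- findInterval(as.numeric(days$date), as.numeric(reports$date))
    eff_idx[eff_idx == 0L] <- NA_integer_
  }
  report_date <- reports$date[eff_idx]
  max_sev <- if (nrow(reports) > 0) {
    apply(as.matrix(reports[symptom_names()]), 1, max)[eff_idx]
  } else {
    rep(NA_integer_, nrow(days))
  }
  severe <- !is.na(max_sev) & max_sev >= config$severe_cutoff

  dplyr::mutate(days,
    has_own_report = !is.na(report_date) & report_date == .data$date,
    is_carried_forward = !is.na(report_date) & report_date != .data$date,
    report_date = report_date,
    max_severity = as.integer(max_sev),
    severe_day = severe,
    sb_threshold = ifelse(severe, config$threshold_severe, config$threshold_normal)
  )
}

#' Sedentary threshold for a symptom state
#'
#' Config pass-through: the severe threshold on severe days, the normal
#' threshold otherwise.
#'
#' @param states A tibble from [daily_symptom_states()] (or any tibble with a
#'   logical `severe_day` column).
#' @param config An [engine_config()].
#' @return Integer vector of thresholds in minutes, one per row of `states`.
#' @export
select_threshold <- function(states, config = engine_config()) {
  config <- as_engine_config(config)
  ifelse(states$severe_day, config$threshold_severe, config$threshold_normal)
}
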