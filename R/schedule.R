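#' Study schedule: perioperative phase boundaries
#'
#' A participant's study window runs from consent (at least two weeks before
#' surgery) to 30 days after hospital discharge. Every study day belongs to
#' exactly one phase: preoperative days are `[consent_date, surgery_date)`,
#' inpatient days are `[surgery_date, discharge_date]` (the surgery day counts
#' as inpatient), and postdischarge days are `(discharge_date, end_date]`.
#'
#' @param consent_date,surgery_date,discharge_date,end_date Calendar dates
#'   (`Date` or anything `as.Date()` accepts) with
#'   `consent_date < surgery_date <= discharge_date < end_date`.
#'
#' @return A list with class `"study_schedule"`.
#' @examples
#' sched <- study_schedule("2025-03-01", "2025-03-20", "2025-03-28", "2025-04-27")
#' phase_of(sched, as.Date("2025-03-20"))   # surgery day -> "inpatient"
#' @export
study_schedule <- function(consent_date, surgery_date, discharge_date, end_date) {
  d <- lapply(list(consent_date = consent_date, surgery_date = surgery_date,
                   discharge_date = discharge_date, end_date = end_date), as.Date)
  if (anyNA(d)) abort("study_schedule: dates must be parseable and non-missing")
  if (!(d$consent_date < d$surgery_date)) {
    abort("study_schedule: consent_date must precede surgery_date")
  }
  if (!(d$surgery_date <= d$discharge_date)) {
    abort("study_schedule: surgery_date must be on or before discharge_date")
  }
  if (!(d$discharge_date < d$end_date)) {
    abort("study_schedule: discharge_date must precede end_date")
  }
  structure(d, class = "study_schedule")
}

#' @export
print.study_schedule <- function(x, ...) {
  cat("<study_schedule>\n")
  cat(sprintf("  preoperative:  %s .. %s (%d d)\n", x$consent_date,
              x$surgery_date - 1, as.integer(x$surgery_date - x$consent_date)))
  cat(sprintf("  inpatient:     %s .. %s (%d d)\n", x$surgery_date,
              x$discharge_date,
              as.integer(x$discharge_date - x$surgery_date) + 1L))
  cat(sprintf("  postdischarge: %s .. %s (%d d)\n", x$discharge_date + 1,
              x$end_date, as.integer(x$end_date - x$discharge_date)))
  invisible(x)
}

#' Phase of a study day
#'
#' @param schedule A [study_schedule()].
#' @param date A `Date` vector within the study window.
#' @return Character vector: `"preoperative"`, `"inpatient"` or `"postdischarge"`.
#' @examples
#' sched <- study_schedule("2025-03-01", "2025-03-20", "2025-03-28", "2025-04-27")
#' phase_of(sched, as.Date(c("2025-03-19", "2025-03-28", "2025-03-29")))
#' @export
phase_of <- function(schedule, date) {
  stopifnot(inherits(schedule, "study_schedule"))
  date <- as.Date(date)
  if (any(date < schedule$consent_date | date > schedule$end_date)) {
    abort("phase_of: date outside the study window")
  }
  dplyr::case_when(
    date < schedule$surgery_date ~ "preoperative",
    date <= schedule$discharge_date ~ "inpatient",
    TRUE ~ "postdischarge"
  )
}

#' All study days with their phases
#'
#' @param schedule A [study_schedule()].
#' @return A tibble with columns `date` and `phase`, one row per study day.
#' @export
study_days <- function(schedule) {
  stopifnot(inherits(schedule, "study_schedule"))
  dates <- seq(schedule$consent_date, schedule$end_date, by = "day")
  tibble::tibble(date = dates, phase = phase_of(schedule, dates))
}

phase_levels <- c("preoperative", "inpatient", "postdischarge")
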