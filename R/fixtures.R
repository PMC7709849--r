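#' Construct step streams and symptom reports in code
#'
#' Small constructors used throughout examples and tests to build inputs
#' without files.
#'
#' `sedentary_stream()` builds a fully-worn minute grid over one or more
#' days with constant steps (default 0: a fully sedentary wearer).
#' `symptom_report()` builds a single-day report with all symptoms at a base
#' severity and named overrides. `empty_reports()` is a zero-row report
#' table (participant never rated symptoms).
#'
#' @param dates `Date` vector of days to cover.
#' @param from,to First and last minute of each day, `"HH:MM"`.
#' @param steps Steps per minute (recycled over the grid).
#' @param heart_rate Heart rate per minute, `NA` for absent.
#' @return A validated step stream tibble.
#' @examples
#' sedentary_stream(as.Date("2025-03-01"), from = "08:00", to = "10:00")
#' symptom_report("2025-03-01", pain = 8)
#' @export
sedentary_stream <- function(dates, from = "08:00", to = "20:59",
                             steps = 0L, heart_rate = NA_real_) {
  dates <- as.Date(dates)
  mins <- seq.int(parse_hhmm(from), parse_hhmm(to))
  ts <- as.POSIXct(unlist(lapply(dates, function(d) {
    as.numeric(day_minute_ts(d, mins))
  })), tz = "UTC", origin = "1970-01-01")
  validate_stream(tibble::tibble(
    timestamp = ts,
    steps = rep_len(as.integer(steps), length(ts)),
    heart_rate = rep_len(as.numeric(heart_rate), length(ts))
  ))
}

#' @rdname sedentary_stream
#' @param date Report date.
#' @param ... Named severities overriding `base` (names from
#'   [symptom_names()]).
#' @param base Severity for symptoms not named in `...`.
#' @export
symptom_report <- function(date, ..., base = 0L) {
  over <- list(...)
  bad <- setdiff(names(over), symptom_names())
  if (length(bad) > 0) {
    abort(paste0("symptom_report: unknown symptom(s): ", paste(bad, collapse = ", ")))
  }
  sev <- setNames(rep(as.integer(base), 10), symptom_names())
  sev[names(over)] <- as.integer(unlist(over))
  out <- tibble::tibble(date = as.Date(date))
  out[symptom_names()] <- as.list(sev)
  validate_reports(out)
}

#' @rdname sedentary_stream
#' @export
empty_reports <- function() {
  out <- tibble::tibble(date = as.Date(character()))
  out[symptom_names()] <- list(integer())
  out
}
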