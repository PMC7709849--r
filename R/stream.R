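#' Validate a per-minute step stream
#'
#' A step stream is a tibble with one row per minute the device logged data:
#' `timestamp` (minute-resolution datetime, strictly increasing), `steps`
#' (non-negative integer steps in that minute) and optionally `heart_rate`
#' (positive beats/min, `NA` when not sampled). Minutes with no device data
#' are simply absent — non-wear is never zero-filled, so it stays
#' distinguishable from sedentary wear.
#'
#' Timestamps are timezone-naive local clock time; internally they are stored
#' as UTC `POSIXct` so no daylight-saving arithmetic is applied.
#'
#' @param stream A data frame with columns `timestamp`, `steps` and
#'   optionally `heart_rate`.
#' @return A validated tibble (empty streams are valid: device never worn).
#' @examples
#' validate_stream(tibble::tibble(
#'   timestamp = as.POSIXct("2025-03-01 09:00", tz = "UTC") + 60 * (0:2),
#'   steps = c(0L, 12L, 0L)
#' ))
#' @export
validate_stream <- function(stream) {
  stream <- tibble::as_tibble(stream)
  need <- setdiff(c("timestamp", "steps"), names(stream))
  if (length(need) > 0) {
    abort(paste0("stream: missing column(s): ", paste(need, collapse = ", ")))
  }
  if (!"heart_rate" %in% names(stream)) stream$heart_rate <- NA_real_
  stream <- stream[c("timestamp", "steps", "heart_rate")]
  if (nrow(stream) == 0) {
    stream$timestamp <- as.POSIXct(character(), tz = "UTC")
    stream$steps <- integer()
    stream$heart_rate <- numeric()
    return(stream)
  }
  ts <- as.POSIXct(stream$timestamp, tz = "UTC")
  if (anyNA(ts)) abort("stream: unparseable timestamp")
  secs <- as.numeric(ts)
  if (any(secs %% 60 != 0)) abort("stream: timestamps must be at whole-minute resolution")
  if (is.unsorted(secs, strictly = TRUE)) {
    i <- which(diff(secs) <= 0)[1] + 1L
    abort(paste0("stream: timestamps not strictly increasing at row ", i))
  }
  steps <- suppressWarnings(as.integer(stream$steps))
  if (anyNA(steps) || any(steps != as.numeric(stream$steps))) {
    abort("stream: steps must be non-negative integers")
  }
  if (any(steps < 0L)) abort("stream: negative step count")
  hr <- as.numeric(stream$heart_rate)
  if (any(!is.na(hr) & hr <= 0)) abort("stream: heart_rate must be > 0 when present")
  tibble::tibble(timestamp = ts, steps = steps, heart_rate = hr)
}

# minutes-of-day (0..1439) for a POSIXct vector stored as UTC
minute_of_day <- function(ts) {
  as.integer((as.numeric(ts) %/% 60) %% 1440)
}

stream_date <- function(ts) {
  as.Date(as.numeric(ts) %/% 86400, origin = "1970-01-01")
}

day_minute_ts <- function(date, minute) {
  as.POSIXct(as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
               minute * 60, tz = "UTC", origin = "1970-01-01")
}
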