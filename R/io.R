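#' Read and write per-minute step streams as CSV
#'
#' The on-disk format mirrors a wearable intraday export: a CSV with header
#' `timestamp,steps[,heart_rate]` and RFC 3339-style minute timestamps
#' (`2025-03-01T08:00:00`; a space instead of `T` is accepted). Malformed
#' rows are reported with their line numbers; unsorted or duplicate
#' timestamps and negative steps are parse errors.
#'
#' @param path File path.
#' @return `read_step_stream()`: a validated step stream tibble.
#' @export
read_step_stream <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("timestamp", "steps") %in% names(raw))) {
    abort(paste0("step stream ", path, ": header must contain timestamp,steps"))
  }
  tchr <- sub("T", " ", raw$timestamp)
  ts <- as.POSIXct(strptime(tchr, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  short <- is.na(ts)
  ts[short] <- as.POSIXct(strptime(tchr[short], "%Y-%m-%d %H:%M", tz = "UTC"))
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(paste0("step stream ", path, ": unparseable timestamp at line ",
                 bad[1] + 1L))
  }
  if (anyDuplicated(ts)) {
    abort(paste0("step stream ", path, ": duplicate timestamp at line ",
                 which(duplicated(ts))[1] + 1L))
  }
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    abort(paste0("step stream ", path, ": timestamps out of order at line ",
                 which(diff(as.numeric(ts)) <= 0)[1] + 2L))
  }
  if (any(raw$steps < 0, na.rm = TRUE)) {
    abort(paste0("step stream ", path, ": negative steps at line ",
                 which(raw$steps < 0)[1] + 1L))
  }
  out <- tibble::tibble(timestamp = ts, steps = raw$steps)
  out$heart_rate <- if ("heart_rate" %in% names(raw)) raw$heart_rate else NA_real_
  validate_stream(out)
}

#' @rdname read_step_stream
#' @param stream A validated step stream.
#' @export
write_step_stream <- function(stream, path) {
  stream <- validate_stream(stream)
  out <- stream
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (all(is.na(out$heart_rate))) out$heart_rate <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write daily symptom logs
#'
#' CSV (one row per day, columns `date` plus the 10 symptom names) or JSON
#' (array of objects with the same fields), chosen by file extension.
#' Validation — all 10 symptoms present, severities integers 0-10, no
#' duplicate dates — is delegated to [validate_reports()]; severities given
#' as strings are coerced.
#'
#' @param path File path (`.csv` or `.json`).
#' @return `read_symptom_log()`: a validated, date-sorted report tibble.
#' @export
read_symptom_log <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  validate_reports(raw)
}

#' @rdname read_symptom_log
#' @param reports A validated report tibble.
#' @export
write_symptom_log <- function(reports, path) {
  reports <- validate_reports(reports)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- reports
    out$date <- as.character(out$date)
    jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  } else {
    readr::write_csv(reports, path, progress = FALSE)
  }
  invisible(path)
}

#' Read and write engine event logs as JSON lines
#'
#' One event per line: `{"schema_version":1,"timestamp":...,"kind":...,
#' "payload":{...}}`. Written logs round-trip exactly through
#' `read_events()`.
#'
#' @param path File path.
#' @return `read_events()`: an event tibble with the [run_engine()] schema.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ev <- new_event_collector()
  for (ln in lines) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    p <- x$payload
    ev$add(
      as.POSIXct(x$timestamp, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
      x$kind,
      prompt_index = if (is.null(p$prompt_index)) NA_integer_ else as.integer(p$prompt_index),
      prompt_time = if (is.null(p$prompt_time)) NULL else
        as.POSIXct(p$prompt_time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
      snoozed = if (is.null(p$snoozed)) NA else as.logical(p$snoozed),
      choice = if (is.null(p$choice)) NA_character_ else p$choice,
      reasons = if (is.null(p$reasons)) character() else as.character(p$reasons)
    )
  }
  ev$collect()
}

#' @rdname read_events
#' @param events An event tibble from [run_engine()].
#' @export
write_events <- function(events, path) {
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  lines <- purrr::map_chr(seq_len(nrow(events)), function(i) {
    payload <- list()
    if (!is.na(events$prompt_index[i])) payload$prompt_index <- events$prompt_index[i]
    if (!is.na(events$prompt_time[i])) payload$prompt_time <- fmt(events$prompt_time[i])
    if (!is.na(events$snoozed[i])) payload$snoozed <- events$snoozed[i]
    if (!is.na(events$choice[i])) payload$choice <- events$choice[i]
    if (length(events$reasons[[i]]) > 0) payload$reasons <- I(events$reasons[[i]])
    jsonlite::toJSON(list(schema_version = 1L,
                          timestamp = fmt(events$timestamp[i]),
                          kind = events$kind[i],
                          payload = payload),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read and write study schedules
#'
#' A one-row CSV with columns `consent_date,surgery_date,discharge_date,end_date`.
#'
#' @param path File path.
#' @return `read_schedule()`: a [study_schedule()].
#' @export
read_schedule <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("consent_date", "surgery_date", "discharge_date", "end_date")
  if (!all(need %in% names(raw)) || nrow(raw) != 1) {
    abort(paste0("schedule ", path, ": expected one row with columns ",
                 paste(need, collapse = ",")))
  }
  study_schedule(raw$consent_date, raw$surgery_date, raw$discharge_date,
                 raw$end_date)
}

#' @rdname read_schedule
#' @param schedule A [study_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "study_schedule"))
  readr::write_csv(tibble::tibble(
    consent_date = schedule$consent_date, surgery_date = schedule$surgery_date,
    discharge_date = schedule$discharge_date, end_date = schedule$end_date
  ), path, progress = FALSE)
  invisible(path)
}

#' Serialize a metrics report as JSON
#'
#' @param metrics A `"periop_metrics"` object.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "periop_metrics"))
  jsonlite::write_json(list(summary = metrics$summary,
                            tidy = tidy(metrics)),
                       path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Load engine/simulator configuration overrides from YAML
#'
#' The file may contain top-level `engine:` and `sim:` maps whose entries
#' override [engine_config()] and [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `engine` (an [engine_config()]) and `sim`
#'   (a named list of [sim_config()] overrides, possibly empty).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  eng <- do.call(engine_config, y$engine %||% list())
  sim_over <- y$sim %||% list()
  # named per-phase maps in YAML arrive as lists; flatten to named vectors
  sim_over <- lapply(sim_over, function(v) {
    if (is.list(v) && !is.null(names(v)) &&
        all(vapply(v, function(e) is.numeric(e) && length(e) == 1, logical(1)))) {
      unlist(v)
    } else {
      v
    }
  })
  list(engine = eng, sim = sim_over)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, input file digests, seed, package
#' version and creation time of a pipeline run, so identical manifests imply
#' identical outputs.
#'
#' @param dir Output directory (one manifest per directory).
#' @param config Configuration list to snapshot.
#' @param inputs Character vector of input file paths to digest.
#' @param seed Integer seed of the run.
#' @export
write_manifest <- function(dir, config, inputs = character(), seed = NA_integer_) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    tool = "periopwalk",
    version = as.character(utils::packageVersion("periopwalk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = seed,
    input_digests = digests,
    config = config
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
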