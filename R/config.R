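#' Engine configuration
#'
#' Bundles every tunable constant of the prompting policy. The defaults are
#' the deployed intervention's published values: a sedentary bout is "fewer
#' than 50 cumulative steps since the last reference point"; prompts fire
#' after 60 consecutive sedentary minutes on ordinary days and 120 minutes on
#' days where any symptom is rated 7 or higher; a snoozed prompt is re-sent
#' 15 minutes later; positive feedback requires 30 or more steps within 15
#' minutes of a prompt.
#'
#' @param sb_step_cap Steps that end a sedentary bout and reset the SB clock.
#' @param threshold_normal Sedentary minutes before a prompt on a non-severe day.
#' @param threshold_severe Sedentary minutes before a prompt on a severe-symptom day.
#' @param severe_cutoff Severity (0-10) at or above which a day counts as severe.
#' @param snooze_delay Minutes after a snoozed prompt before the re-prompt.
#' @param feedback_window Minutes after a prompt within which steps count
#'   toward positive feedback.
#' @param feedback_steps Steps within `feedback_window` that trigger feedback.
#' @param quiet_hours Daily no-prompt window as `"HH:MM-HH:MM"` (start-end);
#'   the SB clock restarts when the active window opens each morning.
#' @param reminder_time Time of the daily symptom-rating reminder, `"HH:MM"`.
#' @param suppress_during_nonwear If `TRUE`, minutes with no device record
#'   freeze the SB clock and cannot carry a prompt.
#'
#' @return A list with class `"engine_config"`.
#' @examples
#' cfg <- engine_config()
#' cfg$threshold_severe
#' @export
engine_config <- function(sb_step_cap = 50L,
                          threshold_normal = 60L,
                          threshold_severe = 120L,
                          severe_cutoff = 7L,
                          snooze_delay = 15L,
                          feedback_window = 15L,
                          feedback_steps = 30L,
                          quiet_hours = "21:00-08:00",
                          reminder_time = "08:00",
                          suppress_during_nonwear = TRUE) {
  cfg <- list(
    sb_step_cap = as.integer(sb_step_cap),
    threshold_normal = as.integer(threshold_normal),
    threshold_severe = as.integer(threshold_severe),
    severe_cutoff = as.integer(severe_cutoff),
    snooze_delay = as.integer(snooze_delay),
    feedback_window = as.integer(feedback_window),
    feedback_steps = as.integer(feedback_steps),
    quiet_hours = quiet_hours,
    reminder_time = reminder_time,
    suppress_during_nonwear = isTRUE(suppress_during_nonwear)
  )
  durs <- c("sb_step_cap", "threshold_normal", "threshold_severe",
            "snooze_delay", "feedback_window", "feedback_steps")
  bad <- durs[vapply(cfg[durs], function(x) is.na(x) || x <= 0L, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("engine_config: ", paste(bad, collapse = ", "),
                 " must be positive"))
  }
  if (cfg$threshold_severe < cfg$threshold_normal) {
    abort("engine_config: threshold_severe must be >= threshold_normal")
  }
  if (is.na(cfg$severe_cutoff) || cfg$severe_cutoff <= 0L || cfg$severe_cutoff > 10L) {
    abort("engine_config: severe_cutoff must be in 1..10")
  }
  qh <- parse_quiet_hours(quiet_hours)
  cfg$active_start_min <- qh$active_start   # minute-of-day active window opens
  cfg$active_end_min <- qh$active_end       # first minute-of-day no longer active
  cfg$reminder_min <- parse_hhmm(reminder_time)
  structure(cfg, class = "engine_config")
}

parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse time of day: '", x, "'"))
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23 || mi > 59) abort(paste0("invalid time of day: '", x, "'"))
  h * 60L + mi
}

# quiet hours "21:00-08:00" spanning midnight -> active window [08:00, 21:00)
parse_quiet_hours <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(paste0("cannot parse quiet_hours: '", x, "'"))
  q_start <- parse_hhmm(parts[1])
  q_end <- parse_hhmm(parts[2])
  if (q_start == q_end) abort("quiet_hours must not be empty or the full day")
  if (q_start < q_end) {
    # quiet block inside the day: active window wraps; the engine operates on
    # the contiguous daytime block, so require the conventional overnight shape
    abort("quiet_hours must span midnight (e.g. '21:00-08:00')")
  }
  list(active_start = q_end, active_end = q_start)
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  cat(sprintf("  SB step cap:        %d steps\n", x$sb_step_cap))
  cat(sprintf("  thresholds:         %d min (normal) / %d min (severe, cutoff >= %d)\n",
              x$threshold_normal, x$threshold_severe, x$severe_cutoff))
  cat(sprintf("  snooze delay:       %d min\n", x$snooze_delay))
  cat(sprintf("  feedback:           >= %d steps within %d min\n",
              x$feedback_steps, x$feedback_window))
  cat(sprintf("  quiet hours:        %s (reminder %s)\n", x$quiet_hours, x$reminder_time))
  cat(sprintf("  non-wear suppress:  %s\n", x$suppress_during_nonwear))
  invisible(x)
}

as_engine_config <- function(x) {
  if (inherits(x, "engine_config")) return(x)
  if (is.null(x)) return(engine_config())
  if (is.list(x)) return(do.call(engine_config, x))
  abort("config must be an engine_config or a named list of overrides")
}
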