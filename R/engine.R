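#' Run the walking-prompt engine over a step stream
#'
#' The deterministic minute-stepped state machine at the heart of the
#' intervention. For every study day it steps through the active window
#' (outside the configured quiet hours), accruing sedentary time since the
#' last reference point (the last prompt, 50-step reset, or active-window
#' start) and emits:
#'
#' * `reminder` — the daily morning symptom-rating reminder;
#' * `prompt` — a walk prompt, at the first minute at which the day's
#'   sedentary threshold (60 min, or 120 min on severe-symptom days) has
#'   elapsed since the reference with fewer than `sb_step_cap` cumulative
#'   steps, or at a scheduled snooze re-prompt; each prompt resets the
#'   reference and arms the feedback window;
#' * `sb_reset` — the sedentary clock reset when `sb_step_cap` (50)
#'   cumulative steps accrue since the reference;
#' * `response` — a Yes / No / Snooze answer supplied via `responses`
#'   (Snooze schedules a re-prompt `snooze_delay` minutes later);
#' * `feedback` — the positive-feedback message, at the first minute at
#'   which `feedback_steps` (30) cumulative steps are logged within
#'   `feedback_window` (15) minutes of a prompt, regardless of the response.
#'
#' Boundary conventions: "exceeded N consecutive minutes" fires at the first
#' minute N minutes after the reference; minutes with no device record
#' freeze the sedentary clock and cannot carry a prompt when
#' `suppress_during_nonwear` is set; the clock restarts when the active
#' window opens each morning; a pending snooze re-prompt is cancelled by an
#' `sb_reset` and dropped if its minute falls in quiet hours or on an
#' unworn minute; unanswered prompts expire silently.
#'
#' @param stream A step stream (see [validate_stream()]).
#' @param symptom_states Per-day states from [daily_symptom_states()]; must
#'   cover every study day.
#' @param schedule A [study_schedule()].
#' @param config An [engine_config()].
#' @param responses Optional tibble of prompt responses with columns
#'   `prompt_index` (1-based index of the prompt in emission order),
#'   `choice` (`"Yes"`, `"No"` or `"Snooze"`) and optionally `reasons`
#'   (list-column; required non-empty for `"No"`).
#' @return A tibble of events ordered in time: `timestamp`, `kind`,
#'   `prompt_index`, `prompt_time`, `snoozed`, `choice`, `reasons`.
#' @examples
#' sched <- study_schedule("2025-03-01", "2025-03-02", "2025-03-02", "2025-03-03")
#' states <- daily_symptom_states(empty_reports(), sched)
#' stream <- sedentary_stream(as.Date("2025-03-01"), from = "08:00", to = "20:59")
#' ev <- run_engine(stream, states, sched)
#' head(ev[ev$kind == "prompt", ])
#' @export
run_engine <- function(stream, symptom_states, schedule,
                       config = engine_config(), responses = NULL) {
  config <- as_engine_config(config)
  stream <- validate_stream(stream)
  responses <- validate_responses(responses)
  days <- study_days(schedule)
  miss <- setdiff(as.character(days$date), as.character(symptom_states$date))
  if (length(miss) > 0) {
    abort(paste0("run_engine: symptom_states missing study day(s): ",
                 paste(head(miss, 3), collapse = ", ")))
  }

  s_date <- stream_date(stream$timestamp)
  s_min <- minute_of_day(stream$timestamp)
  m0 <- config$active_start_min
  m1 <- config$active_end_min        # prompts allowed up to and including m1
  fw <- config$feedback_window
  cap <- config$sb_step_cap
  suppress <- config$suppress_during_nonwear

  ev <- new_event_collector()
  prompt_counter <- 0L

  for (i in seq_len(nrow(days))) {
    date <- days$date[i]
    thr <- symptom_states$sb_threshold[match(date, symptom_states$date)]
    ev$add(day_minute_ts(date, config$reminder_min), "reminder")

    sel <- s_date == date
    worn_at <- logical(1441L)
    steps_at <- integer(1441L)
    dm <- s_min[sel]
    in_win <- dm >= m0 & dm <= m1
    worn_at[dm[in_win] - m0 + 1L] <- TRUE
    steps_at[dm[in_win] - m0 + 1L] <- stream$steps[sel][in_win]

    elapsed <- 0L; steps_ref <- 0L
    pending <- NA_integer_
    armed <- FALSE; armed_prompt <- NA_integer_; armed_until <- NA_integer_
    steps_since_prompt <- 0L

    for (m in seq.int(m0 + 1L, m1)) {
      j <- m - m0 + 1L
      worn <- worn_at[j]
      st <- steps_at[j]
      if (worn) {
        steps_ref <- steps_ref + st
        if (armed && m <= armed_until) steps_since_prompt <- steps_since_prompt + st
      }
      if (armed && m <= armed_until && steps_since_prompt >= config$feedback_steps) {
        ev$add(day_minute_ts(date, m), "feedback",
               prompt_index = armed_prompt,
               prompt_time = day_minute_ts(date, armed_until - fw))
        armed <- FALSE
      }
      if (armed && m > armed_until) armed <- FALSE
      if (steps_ref >= cap) {
        ev$add(day_minute_ts(date, m), "sb_reset")
        elapsed <- 0L; steps_ref <- 0L; pending <- NA_integer_
        next
      }
      allowed <- worn || !suppress
      if (allowed) elapsed <- elapsed + 1L
      snooze_due <- !is.na(pending) && pending == m
      if (snooze_due && !allowed) {
        pending <- NA_integer_   # re-prompt lands on an unworn minute: dropped
        snooze_due <- FALSE
      }
      if (allowed && (snooze_due || elapsed >= thr)) {
        pending <- NA_integer_
        prompt_counter <- prompt_counter + 1L
        tstamp <- day_minute_ts(date, m)
        ev$add(tstamp, "prompt", prompt_index = prompt_counter,
               snoozed = snooze_due)
        elapsed <- 0L; steps_ref <- 0L
        armed <- TRUE; armed_prompt <- prompt_counter; armed_until <- m + fw
        steps_since_prompt <- 0L
        if (!is.null(responses)) {
          r <- which(responses$prompt_index == prompt_counter)
          if (length(r) == 1) {
            ans <- apply_response(tstamp, responses$choice[r],
                                  responses$reasons[[r]], config)
            ev$add(tstamp, "response", prompt_index = prompt_counter,
                   prompt_time = tstamp, choice = responses$choice[r],
                   reasons = responses$reasons[[r]])
            if (!is.na(ans$reprompt_at_min)) {
              pending <- m + config$snooze_delay
              if (pending > m1) pending <- NA_integer_
            }
          }
        }
      }
    }
  }
  order_events(ev$collect())
}

# canonical event ordering: by timestamp, with same-minute ties resolved by
# the engine's within-minute evaluation order
event_kind_rank <- function(kind) {
  match(kind, c("reminder", "feedback", "sb_reset", "prompt", "response"))
}

order_events <- function(events) {
  events[order(as.numeric(events$timestamp), event_kind_rank(events$kind)), ]
}

#' Apply a participant response to a prompt
#'
#' Validates the response contract — `Yes` acknowledges, `No` must carry one
#' or more reasons from Busy / Pain / Nausea / Other, `Snooze` schedules a
#' re-prompt `snooze_delay` minutes later — and returns the resulting event
#' row. None of the three alters the feedback logic: the positive-feedback
#' message depends only on steps logged after the prompt.
#'
#' @param prompt_time Timestamp of the prompt being answered.
#' @param choice `"Yes"`, `"No"` or `"Snooze"`.
#' @param reasons Character vector of reasons; required non-empty for `"No"`,
#'   forbidden otherwise.
#' @param config An [engine_config()].
#' @return A list with `event` (a one-row response tibble) and `reprompt_at`
#'   (timestamp of the scheduled re-prompt, or `NA` for Yes/No).
#' @export
apply_response <- function(prompt_time, choice, reasons = NULL,
                           config = engine_config()) {
  config <- as_engine_config(config)
  if (!choice %in% c("Yes", "No", "Snooze")) {
    abort("apply_response: choice must be Yes, No or Snooze")
  }
  reasons <- reasons %||% character()
  if (choice == "No") {
    if (length(reasons) == 0) abort("apply_response: No requires at least one reason")
    bad <- setdiff(reasons, no_reasons())
    if (length(bad) > 0) {
      abort(paste0("apply_response: unknown reason(s): ", paste(bad, collapse = ", ")))
    }
  } else if (length(reasons) > 0) {
    abort("apply_response: reasons are only allowed with No")
  }
  reprompt_min <- if (choice == "Snooze") config$snooze_delay else NA_integer_
  event <- tibble::tibble(
    timestamp = prompt_time, kind = "response",
    prompt_index = NA_integer_, prompt_time = prompt_time,
    snoozed = NA, choice = choice, reasons = list(reasons)
  )
  list(event = event,
       reprompt_at = if (is.na(reprompt_min)) as.POSIXct(NA) else
         prompt_time + 60 * reprompt_min,
       reprompt_at_min = reprompt_min)
}

#' Permitted reasons for declining a prompt
#' @return Character vector `c("Busy", "Pain", "Nausea", "Other")`.
#' @export
no_reasons <- function() c("Busy", "Pain", "Nausea", "Other")

validate_responses <- function(responses) {
  if (is.null(responses)) return(NULL)
  responses <- tibble::as_tibble(responses)
  need <- setdiff(c("prompt_index", "choice"), names(responses))
  if (length(need) > 0) {
    abort(paste0("responses: missing column(s): ", paste(need, collapse = ", ")))
  }
  if (!"reasons" %in% names(responses)) {
    responses$reasons <- rep(list(character()), nrow(responses))
  }
  if (anyDuplicated(responses$prompt_index)) {
    abort("responses: duplicate prompt_index")
  }
  responses
}

new_event_collector <- function() {
  e_ts <- numeric(); e_kind <- character(); e_idx <- integer()
  e_ptime <- numeric(); e_snz <- logical(); e_choice <- character()
  e_reasons <- list()
  list(
    add = function(timestamp, kind, prompt_index = NA_integer_,
                   prompt_time = NULL, snoozed = NA,
                   choice = NA_character_, reasons = character()) {
      n <- length(e_ts) + 1L
      e_ts[n] <<- as.numeric(timestamp)
      e_kind[n] <<- kind
      e_idx[n] <<- prompt_index
      e_ptime[n] <<- if (is.null(prompt_time)) NA_real_ else as.numeric(prompt_time)
      e_snz[n] <<- snoozed
      e_choice[n] <<- choice
      e_reasons[[n]] <<- reasons
    },
    collect = function() {
      tibble::tibble(
        timestamp = as.POSIXct(e_ts, tz = "UTC", origin = "1970-01-01"),
        kind = e_kind,
        prompt_index = e_idx,
        prompt_time = as.POSIXct(e_ptime, tz = "UTC", origin = "1970-01-01"),
        snoozed = e_snz,
        choice = e_choice,
        reasons = e_reasons
      )
    }
  )
}
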