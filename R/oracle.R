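#' Brute-force reference scan of the prompt policy
#'
#' An independent re-implementation of [run_engine()] used for testing: an
#' event-driven scan that, for every candidate event, recomputes elapsed
#' sedentary time and cumulative steps from prefix sums over the day's
#' minute grid rather than carrying incremental counters. Its output is
#' required to equal [run_engine()]'s exactly on any input.
#'
#' @inheritParams run_engine
#' @return A tibble of events with the same schema as [run_engine()].
#' @export
oracle_scan <- function(stream, symptom_states, schedule,
                        config = engine_config(), responses = NULL) {
  config <- as_engine_config(config)
  stream <- validate_stream(stream)
  responses <- validate_responses(responses)
  days <- study_days(schedule)
  miss <- setdiff(as.character(days$date), as.character(symptom_states$date))
  if (length(miss) > 0) {
    abort(paste0("oracle_scan: symptom_states missing study day(s): ",
                 paste(head(miss, 3), collapse = ", ")))
  }

  m0 <- config$active_start_min
  m1 <- config$active_end_min
  grid <- seq.int(m0 + 1L, m1)          # minutes at which events may occur
  W <- length(grid)
  s_date <- stream_date(stream$timestamp)
  s_min <- minute_of_day(stream$timestamp)

  ev <- new_event_collector()
  prompt_counter <- 0L

  for (i in seq_len(nrow(days))) {
    date <- days$date[i]
    thr <- symptom_states$sb_threshold[match(date, symptom_states$date)]
    ev$add(day_minute_ts(date, config$reminder_min), "reminder")

    sel <- s_date == date
    dm <- s_min[sel]
    worn <- grid %in% dm
    steps <- integer(W)
    steps[match(dm[dm %in% grid], grid)] <- stream$steps[sel][dm %in% grid]
    accrue <- worn | !config$suppress_during_nonwear
    cum_acc <- cumsum(accrue)           # elapsed minutes from window start
    cum_steps <- cumsum(ifelse(worn, steps, 0L))

    # state: ref = position (0 = window start) such that elapsed/steps are
    # measured over grid positions (ref, pos]
    ref <- 0L
    pending_pos <- NA_integer_
    prompts <- integer(0)               # positions of prompts this day
    prompt_ids <- integer(0)

    repeat {
      base_acc <- if (ref == 0L) 0L else cum_acc[ref]
      base_stp <- if (ref == 0L) 0L else cum_steps[ref]
      cand <- which(seq_len(W) > ref &
                      (cum_steps - base_stp) >= config$sb_step_cap)
      reset_pos <- if (length(cand)) cand[1] else NA_integer_
      cand <- which(seq_len(W) > ref & accrue &
                      (cum_acc - base_acc) >= thr)
      prompt_pos <- if (length(cand)) cand[1] else NA_integer_
      nxt <- suppressWarnings(min(reset_pos, prompt_pos, pending_pos, na.rm = TRUE))
      if (!is.finite(nxt)) break
      if (!is.na(reset_pos) && reset_pos <= nxt) {
        ev$add(day_minute_ts(date, grid[reset_pos]), "sb_reset")
        ref <- reset_pos
        pending_pos <- NA_integer_
        next
      }
      # a prompt (threshold-driven, snooze-driven, or both on the same minute)
      from_snooze <- !is.na(pending_pos) && pending_pos == nxt
      pending_pos <- NA_integer_
      prompt_counter <- prompt_counter + 1L
      tstamp <- day_minute_ts(date, grid[nxt])
      ev$add(tstamp, "prompt", prompt_index = prompt_counter,
             snoozed = from_snooze)
      prompts <- c(prompts, nxt)
      prompt_ids <- c(prompt_ids, prompt_counter)
      ref <- nxt
      if (!is.null(responses)) {
        r <- which(responses$prompt_index == prompt_counter)
        if (length(r) == 1) {
          ans <- apply_response(tstamp, responses$choice[r],
                                responses$reasons[[r]], config)
          ev$add(tstamp, "response", prompt_index = prompt_counter,
                 prompt_time = tstamp, choice = responses$choice[r],
                 reasons = responses$reasons[[r]])
          if (!is.na(ans$reprompt_at_min)) {
            p <- nxt + config$snooze_delay
            # dropped when it falls outside the window or on an unworn minute
            if (p <= W && accrue[p]) pending_pos <- p
          }
        }
      }
    }

    # feedback: per prompt, first minute in (prompt, prompt + window], not
    # beyond the next prompt (whose arming replaces the slot) or the day end,
    # at which cumulative steps since the prompt reach the criterion
    if (length(prompts) > 0) {
      nxt_prompt <- c(prompts[-1], Inf)
      for (k in seq_along(prompts)) {
        p <- prompts[k]
        hi <- min(p + config$feedback_window, nxt_prompt[k], W)
        if (hi <= p) next
        rng <- seq.int(p + 1L, hi)
        cum <- cumsum(ifelse(worn[rng], steps[rng], 0L))
        hit <- which(cum >= config$feedback_steps)
        if (length(hit) > 0) {
          ev$add(day_minute_ts(date, grid[rng[hit[1]]]), "feedback",
                 prompt_index = prompt_ids[k],
                 prompt_time = day_minute_ts(date, grid[p]))
        }
      }
    }
  }
  order_events(ev$collect())
}
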