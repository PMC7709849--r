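# shared fixture builders; everything is generated in code

D0 <- as.Date("2025-06-01")

day_ts <- function(hhmm, date = D0) {
  as.POSIXct(paste(date, paste0(hhmm, ":00")), tz = "UTC")
}

one_day_schedule <- function(date = D0) {
  study_schedule(date, date + 1, date + 1, date + 2)
}

nonsevere_states <- function(schedule, config = engine_config()) {
  daily_symptom_states(empty_reports(), schedule, config)
}

# day summaries encoding the published per-phase counts: 364 preoperative
# days (330 worn, 264 rated, 90 severe), 143 inpatient (51 worn, 32 rated,
# 15 severe), 420 postdischarge (272 worn, 173 rated, 67 severe)
table2_day_summaries <- function() {
  build <- function(phase, n_days, n_worn, n_rated, n_severe, start) {
    tibble::tibble(
      date = start + seq_len(n_days) - 1,
      phase = phase,
      worn = seq_len(n_days) <= n_worn,
      symptom_reported = seq_len(n_days) <= n_rated,
      severe_day = ifelse(seq_len(n_days) <= n_rated,
                          seq_len(n_days) <= n_severe, NA),
      total_steps = ifelse(seq_len(n_days) <= n_worn, 1000L, 0L),
      sb_bouts = purrr::map(seq_len(n_days), function(i)
        if (i <= n_worn) c(30, 60) else numeric()),
      prompts_sent = 0L,
      prompts_walked = 0L
    )
  }
  dplyr::bind_rows(
    build("preoperative", 364, 330, 264, 90, as.Date("2020-01-01")),
    build("inpatient", 143, 51, 32, 15, as.Date("2021-01-01")),
    build("postdischarge", 420, 272, 173, 67, as.Date("2022-01-01"))
  )
}

# a randomized one/two-day engine fixture with non-wear gaps, step bursts,
# severe and non-severe days, and scripted responses including snoozes
random_fixture <- function(seed) {
  set.seed(seed)
  windows <- c("18:00-09:00", "21:00-08:00", "14:00-06:00")
  config <- engine_config(
    sb_step_cap = sample(c(30L, 50L), 1),
    threshold_normal = sample(c(25L, 40L, 60L), 1),
    threshold_severe = sample(c(90L, 120L), 1),
    snooze_delay = sample(c(5L, 10L, 15L), 1),
    feedback_window = sample(c(10L, 15L), 1),
    feedback_steps = sample(c(20L, 30L), 1),
    quiet_hours = sample(windows, 1),
    suppress_during_nonwear = runif(1) < 0.8
  )
  n_days <- sample(1:2, 1)
  sched <- study_schedule(D0, D0 + 1, D0 + n_days, D0 + n_days + 1)
  days <- study_days(sched)

  from_min <- config$active_start_min
  to_min <- config$active_end_min
  parts <- purrr::map(seq_len(nrow(days)), function(i) {
    mins <- seq.int(from_min, to_min)
    worn <- rep(TRUE, length(mins))
    # a few non-wear gaps
    for (g in seq_len(sample(0:3, 1))) {
      a <- sample(length(mins), 1)
      worn[a:min(length(mins), a + sample(5:60, 1))] <- FALSE
    }
    steps <- ifelse(runif(length(mins)) < 0.12,
                    sample(0:80, length(mins), replace = TRUE), 0L)
    tibble::tibble(
      timestamp = periopwalk:::day_minute_ts(days$date[i], mins[worn]),
      steps = as.integer(steps[worn]),
      heart_rate = ifelse(runif(sum(worn)) < 0.5, NA_real_, 70)
    )
  })
  stream <- validate_stream(dplyr::bind_rows(parts))

  reports <- if (runif(1) < 0.7) {
    dplyr::bind_rows(purrr::map(seq_len(nrow(days)), function(i) {
      if (runif(1) < 0.6) {
        symptom_report(days$date[i],
                       pain = sample(0:10, 1), fatigue = sample(0:10, 1))
      } else {
        NULL
      }
    }))
  } else {
    NULL
  }
  if (is.null(reports) || nrow(reports) == 0) reports <- empty_reports()
  states <- daily_symptom_states(reports, sched, config)

  responses <- tibble::tibble(
    prompt_index = 1:20,
    choice = sample(c("Yes", "No", "Snooze"), 20, replace = TRUE,
                    prob = c(0.3, 0.2, 0.5)),
    reasons = purrr::map(1:20, function(i) character())
  )
  responses$reasons[responses$choice == "No"] <-
    purrr::map(which(responses$choice == "No"),
               function(i) sample(no_reasons(), 1))
  list(stream = stream, states = states, schedule = sched,
       config = config, responses = responses)
}
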