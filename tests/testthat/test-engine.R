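full_day_stream <- function(date = D0, steps = 0L) {
  sedentary_stream(date, from = "08:00", to = "21:00", steps = steps)
}

test_that("prompt timing follows the symptom-tailored thresholds", {
  sched <- one_day_schedule()
  stream <- full_day_stream()

  ev <- run_engine(stream, nonsevere_states(sched), sched)
  prompts <- ev$timestamp[ev$kind == "prompt" & as.Date(ev$timestamp) == D0]
  expect_equal(format(prompts[1], "%H:%M"), "09:00")          # 60 min after window open
  expect_equal(as.numeric(diff(prompts), units = "mins"), rep(60, 12))

  severe <- daily_symptom_states(symptom_report(D0, fatigue = 9), sched)
  ev2 <- run_engine(stream, severe, sched)
  prompts2 <- ev2$timestamp[ev2$kind == "prompt" & as.Date(ev2$timestamp) == D0]
  expect_equal(format(prompts2[1], "%H:%M"), "10:00")         # 120 min
  expect_equal(as.numeric(diff(prompts2), units = "mins"), rep(120, 5))
})

test_that("a 50-step burst resets the sedentary clock instead of prompting", {
  sched <- one_day_schedule()
  stream <- full_day_stream()
  stream$steps[stream$timestamp == day_ts("08:30")] <- 50L
  ev <- run_engine(stream, nonsevere_states(sched), sched)
  day1 <- ev[as.Date(ev$timestamp) == D0, ]
  expect_equal(day1$kind[day1$kind != "reminder"][1], "sb_reset")
  expect_equal(day1$timestamp[day1$kind == "sb_reset"][1], day_ts("08:30"))
  # prompt 60 min after the reset, i.e. 90 min after the window opened
  expect_equal(day1$timestamp[day1$kind == "prompt"][1], day_ts("09:30"))

  # sub-cap walking never resets: 49 steps leave the original prompt time
  stream2 <- full_day_stream()
  stream2$steps[stream2$timestamp == day_ts("08:30")] <- 49L
  ev2 <- run_engine(stream2, nonsevere_states(sched), sched)
  expect_false(any(ev2$kind == "sb_reset" & as.Date(ev2$timestamp) == D0))
  expect_equal(ev2$timestamp[ev2$kind == "prompt"][1], day_ts("09:00"))
})

test_that("snooze schedules a re-prompt and No records reasons", {
  sched <- one_day_schedule()
  stream <- full_day_stream()
  responses <- tibble::tibble(
    prompt_index = 1:2, choice = c("Snooze", "No"),
    reasons = list(character(), c("Pain", "Nausea"))
  )
  ev <- run_engine(stream, nonsevere_states(sched), sched, responses = responses)
  prompts <- ev[ev$kind == "prompt" & as.Date(ev$timestamp) == D0, ]
  expect_equal(prompts$timestamp[1], day_ts("09:00"))
  expect_equal(prompts$timestamp[2], day_ts("09:15"))         # snooze +15 min
  expect_true(prompts$snoozed[2])
  resp <- ev[ev$kind == "response", ]
  expect_equal(resp$choice[1:2], c("Snooze", "No"))
  expect_equal(resp$reasons[[2]], c("Pain", "Nausea"))
  # the re-prompt resets the clock: next threshold prompt 60 min after it
  expect_equal(prompts$timestamp[3], day_ts("10:15"))
})

test_that("response validation rejects malformed choices and reasons", {
  t0 <- day_ts("09:00")
  expect_error(apply_response(t0, "Maybe"), "choice")
  expect_error(apply_response(t0, "No"), "reason")
  expect_error(apply_response(t0, "No", "Tired"), "unknown reason")
  expect_error(apply_response(t0, "Yes", "Busy"), "only allowed with No")
  expect_error(apply_response(t0, "Snooze", "Busy"), "only allowed with No")
  ok <- apply_response(t0, "Snooze")
  expect_equal(as.numeric(ok$reprompt_at - t0, units = "mins"), 15)
  expect_true(is.na(apply_response(t0, "Yes")$reprompt_at))
})

test_that("feedback requires the step criterion inside the window, regardless of response", {
  sched <- one_day_schedule()
  mk <- function(steps_at, n) {
    s <- full_day_stream()
    s$steps[s$timestamp == day_ts(steps_at)] <- as.integer(n)
    s
  }
  # 30 steps at prompt+10 -> feedback at that minute
  ev <- run_engine(mk("09:10", 30), nonsevere_states(sched), sched)
  fb <- ev[ev$kind == "feedback", ]
  expect_equal(nrow(fb), 1)
  expect_equal(fb$timestamp, day_ts("09:10"))
  expect_equal(fb$prompt_time, day_ts("09:00"))
  # 29 steps never trigger it
  ev29 <- run_engine(mk("09:10", 29), nonsevere_states(sched), sched)
  expect_false(any(ev29$kind == "feedback"))
  # steps outside the 15-minute window do not count
  ev_late <- run_engine(mk("09:16", 40), nonsevere_states(sched), sched)
  expect_false(any(ev_late$kind == "feedback"))
  # a No response does not disable feedback
  resp <- tibble::tibble(prompt_index = 1L, choice = "No", reasons = list("Busy"))
  ev_no <- run_engine(mk("09:10", 40), nonsevere_states(sched), sched,
                      responses = resp)
  expect_equal(sum(ev_no$kind == "feedback"), 1)
})

test_that("non-wear freezes the sedentary clock when suppression is on", {
  sched <- one_day_schedule()
  stream <- full_day_stream()
  gap <- stream$timestamp >= day_ts("08:20") & stream$timestamp <= day_ts("08:49")
  stream <- stream[!gap, ]                       # 30 unworn minutes
  ev <- run_engine(stream, nonsevere_states(sched), sched)
  # 60 worn sedentary minutes accrue only by 09:30
  expect_equal(ev$timestamp[ev$kind == "prompt"][1], day_ts("09:30"))

  cfg_off <- engine_config(suppress_during_nonwear = FALSE)
  ev2 <- run_engine(stream, nonsevere_states(sched, cfg_off), sched, cfg_off)
  expect_equal(ev2$timestamp[ev2$kind == "prompt"][1], day_ts("09:00"))
})

test_that("no prompts in quiet hours; clock restarts each morning", {
  sched <- study_schedule(D0, D0 + 1, D0 + 1, D0 + 2)
  stream <- sedentary_stream(c(D0, D0 + 1, D0 + 2), from = "06:00", to = "23:00")
  ev <- run_engine(stream, nonsevere_states(sched), sched)
  prompts <- ev$timestamp[ev$kind == "prompt"]
  mins <- as.integer(format(prompts, "%H")) * 60 + as.integer(format(prompts, "%M"))
  expect_true(all(mins >= 8 * 60 & mins <= 21 * 60))
  # first prompt each day is 60 min after the window opens
  for (d in c(D0, D0 + 1, D0 + 2)) {
    first <- min(prompts[as.Date(prompts) == d])
    expect_equal(format(first, "%H:%M"), "09:00")
  }
})

test_that("engine requires symptom states for every study day", {
  sched <- one_day_schedule()
  st <- nonsevere_states(sched)
  expect_error(run_engine(full_day_stream(), st[-1, ], sched), "missing study day")
})

test_that("an empty stream yields reminders only under suppression", {
  sched <- one_day_schedule()
  empty <- validate_stream(tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"), steps = integer()
  ))
  ev <- run_engine(empty, nonsevere_states(sched), sched)
  expect_true(all(ev$kind == "reminder"))
  expect_equal(nrow(ev), 3)                      # one per study day
})
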