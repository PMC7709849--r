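small_sim <- function(...) {
  sim_config(n_participants = 2, postdischarge_days = 8,
             phase_duration_mean = c(preoperative = 12, inpatient = 7), ...)
}

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(small_sim(seed = 5))
  b <- simulate_cohort(small_sim(seed = 5))
  attr(a, "sim_config") <- attr(b, "sim_config") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(small_sim(seed = 6))
  attr(c2, "sim_config") <- NULL
  expect_false(identical(a, c2))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(simulate_cohort(small_sim(seed = 9)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("zero wear probability leaves a phase with no records", {
  cfg <- small_sim(seed = 8, p_wear = c(preoperative = 0, inpatient = 1,
                                        postdischarge = 1))
  cohort <- simulate_cohort(cfg)
  for (i in seq_len(nrow(cohort))) {
    stream <- cohort$stream[[i]]
    phases <- phase_of(cohort$schedule[[i]], as.Date(stream$timestamp,
                                                     tz = "UTC"))
    expect_false(any(phases == "preoperative"))
    expect_true(any(phases == "inpatient"))
  }
})

test_that("phase durations stay inside the published ranges", {
  cohort <- simulate_cohort(sim_config(n_participants = 12, seed = 14))
  for (i in seq_len(nrow(cohort))) {
    sc <- cohort$schedule[[i]]
    preop <- as.integer(sc$surgery_date - sc$consent_date)
    inpat <- as.integer(sc$discharge_date - sc$surgery_date) + 1L
    post <- as.integer(sc$end_date - sc$discharge_date)
    expect_true(preop >= 11 && preop <= 40)
    expect_true(inpat >= 6 && inpat <= 15)
    expect_equal(post, 30)
  }
})

test_that("per-phase day generation recovers the configured activity calibration", {
  cfg <- sim_config()
  pre <- simulate_phase_days("preoperative", 200, cfg, seed = 31)
  se <- sd(pre$total_steps) / sqrt(nrow(pre))
  expect_lt(abs(mean(pre$total_steps) - cfg$steps_mean[["preoperative"]]), 3 * se)
  expect_true(all(pre$total_steps >= 0))

  inp <- simulate_phase_days("inpatient", 200, cfg, seed = 32)
  bouts <- unlist(purrr::map(inp$stream, sb_bout_durations))
  se_b <- sd(bouts) / sqrt(length(bouts))
  expect_lt(abs(mean(bouts) - cfg$bout_target_mean[["inpatient"]]), 3 * se_b)
})

test_that("metrics recover the configured compliance probabilities", {
  # ~200 patient-days per phase
  cfg <- sim_config(n_participants = 7, seed = 44,
                    phase_duration_mean = c(preoperative = 29, inpatient = 10.4))
  cohort <- simulate_cohort(cfg)
  ds <- dplyr::bind_rows(purrr::map(seq_len(nrow(cohort)), function(i) {
    summarize_days(cohort$stream[[i]], cohort$reports[[i]], NULL,
                   cohort$schedule[[i]])
  }))
  s <- aggregate_metrics(ds)$summary
  for (ph in c("preoperative", "inpatient", "postdischarge")) {
    row <- s[s$stratum == ph, ]
    p <- cfg$p_wear[[ph]]
    se <- sqrt(p * (1 - p) / row$worn_N)
    expect_lt(abs(row$worn_n / row$worn_N - p), 3 * se + 1e-9)
    p <- cfg$p_report[[ph]]
    se <- sqrt(p * (1 - p) / row$symptom_reported_N)
    expect_lt(abs(row$symptom_reported_n / row$symptom_reported_N - p), 3 * se)
    p <- cfg$p_severe[[ph]]
    se <- sqrt(p * (1 - p) / row$severe_N)
    expect_lt(abs(row$severe_n / row$severe_N - p), 3 * se)
  }
})

test_that("response simulation honors the walk probabilities", {
  sched <- study_schedule(D0 - 1, D0, D0 + 40, D0 + 41)  # mostly inpatient
  prompts <- tibble::tibble(
    timestamp = day_ts("10:00", D0) + 86400 * (0:499 %% 40) + 60 * (0:499),
    kind = "prompt", prompt_index = 1:500,
    prompt_time = as.POSIXct(NA), snoozed = FALSE,
    choice = NA_character_, reasons = vector("list", 500)
  )
  prompts <- prompts[order(prompts$timestamp), ]
  cfg <- sim_config()
  resp <- simulate_responses(prompts, sched, cfg, seed = 77)
  expect_equal(nrow(resp), 500)
  expect_true(all(resp$phase == "inpatient"))
  p <- cfg$p_walk[["inpatient"]]
  se <- sqrt(p * (1 - p) / 500)
  expect_lt(abs(mean(resp$walked) - p), 3 * se)
  expect_true(all(resp$choice %in% c("Yes", "No", "Snooze")))
  no_rows <- resp$choice == "No"
  expect_true(all(lengths(resp$reasons[no_rows]) > 0))
  expect_true(all(lengths(resp$reasons[!no_rows]) == 0))

  # degenerate walk probabilities
  all_walk <- simulate_responses(prompts, sched,
                                 sim_config(p_walk = c(preoperative = 1,
                                                       inpatient = 1,
                                                       postdischarge = 1)),
                                 seed = 78)
  expect_true(all(all_walk$walked))
  expect_true(all(purrr::map_int(all_walk$injections, nrow) > 0))
  none <- simulate_responses(prompts, sched,
                             sim_config(p_walk = c(preoperative = 0,
                                                   inpatient = 0,
                                                   postdischarge = 0)),
                             seed = 79)
  expect_false(any(none$walked))
})

test_that("the closed loop runs end to end and walkers earn feedback", {
  cfg <- sim_config(n_participants = 1, seed = 55, postdischarge_days = 6,
                    phase_duration_mean = c(preoperative = 6, inpatient = 6),
                    p_wear = c(preoperative = 1, inpatient = 1, postdischarge = 1),
                    p_walk = c(preoperative = 1, inpatient = 1, postdischarge = 1))
  cohort <- simulate_cohort(cfg)
  sched <- cohort$schedule[[1]]
  states <- daily_symptom_states(cohort$reports[[1]], sched, cfg$engine)
  ev <- run_engine(cohort$stream[[1]], states, sched, cfg$engine)
  resp <- simulate_responses(ev, sched, cfg, seed = 56)
  augmented <- inject_steps(cohort$stream[[1]], resp)
  ds <- summarize_days(augmented, cohort$reports[[1]], ev, sched, cfg$engine)
  m <- aggregate_metrics(ds)
  ov <- m$summary[m$summary$stratum == "overall", ]
  expect_gt(ov$prompts_sent, 0)
  # every prompt was followed by an injected walk burst
  expect_equal(ov$prompts_walked, ov$prompts_sent)
  expect_equal(ov$walk_fraction, 1)
})
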