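test_that("bout extraction follows the step-cap reset semantics", {
  # 240 worn minutes, all zero -> one bout of 240
  day <- sedentary_stream(D0, from = "08:00", to = "11:59")
  expect_equal(sb_bout_durations(day), 240)

  # zeros except 50 steps at minute 100 -> bouts of 100 and 140
  day2 <- day
  day2$steps[100] <- 50L
  expect_equal(sb_bout_durations(day2), c(100, 140))

  # 49 steps never cross the cap: still one bout
  day3 <- day
  day3$steps[100] <- 49L
  expect_equal(sb_bout_durations(day3), 240)

  # constant 60 steps/min: every minute crosses, no bout longer than 1
  busy <- sedentary_stream(D0, from = "08:00", to = "11:59", steps = 60L)
  expect_true(all(sb_bout_durations(busy) == 1))

  # empty slice, empty result
  expect_equal(sb_bout_durations(day[0, ]), numeric())

  # zero-run convention for sensitivity analysis
  expect_equal(sb_bout_durations(day2, method = "zero_runs"), c(99, 140))
})

test_that("bout durations sum to at most the worn minutes", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(30:400, 1)
    keep <- sort(sample(780, n))
    day <- sedentary_stream(D0, from = "08:00", to = "20:59")[keep, ]
    day$steps <- ifelse(runif(n) < 0.2, sample(0:80, n, replace = TRUE), 0L)
    b <- sb_bout_durations(day)
    expect_lte(sum(b), n)
    expect_true(all(b >= 1))
  }
})

test_that("wear is any steps or any heart rate; severe only when rated", {
  sched <- study_schedule(D0, D0 + 1, D0 + 1, D0 + 3)
  # day 1: heart rate only; day 2: no records; day 3: steps; day 4: zero
  # steps and no heart rate (device docked but syncing zeros)
  stream <- dplyr::bind_rows(
    sedentary_stream(D0, from = "09:00", to = "10:00", heart_rate = 72),
    sedentary_stream(D0 + 2, from = "09:00", to = "10:00", steps = 5L),
    sedentary_stream(D0 + 3, from = "09:00", to = "10:00")
  )
  reports <- symptom_report(D0 + 2, pain = 9)
  ds <- summarize_days(stream, reports, NULL, sched)
  expect_equal(ds$worn, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ds$total_steps, c(0L, 0L, 305L, 0L))
  expect_equal(ds$symptom_reported, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(ds$severe_day, c(NA, NA, TRUE, NA))
})

test_that("prompts walked counts the feedback criterion from the stream", {
  sched <- one_day_schedule()
  stream <- sedentary_stream(D0, from = "08:00", to = "21:00")
  stream$steps[stream$timestamp == day_ts("09:10")] <- 40L  # within 15 min of 09:00
  st <- nonsevere_states(sched)
  ev <- run_engine(stream, st, sched)
  ds <- summarize_days(stream, empty_reports(), ev, sched)
  d1 <- ds[ds$date == D0, ]
  expect_gte(d1$prompts_sent, 1)
  expect_equal(d1$prompts_walked, 1L)
  # engine feedback and metrics walk detection agree here
  expect_equal(sum(ev$kind == "feedback"), 1)
})

test_that("aggregation reproduces the published compliance arithmetic", {
  m <- aggregate_metrics(table2_day_summaries())
  s <- m$summary
  overall <- s[s$stratum == "overall", ]
  expect_equal(overall$worn_n, 653)
  expect_equal(overall$worn_N, 927)
  expect_equal(overall$symptom_reported_n, 469)
  expect_equal(overall$severe_n, 172)
  expect_equal(overall$severe_N, 469)
  pre <- s[s$stratum == "preoperative", ]
  expect_equal(pre$worn_n / pre$worn_N, 330 / 364)
  expect_equal(pre$symptom_reported_n, 264)
  inp <- s[s$stratum == "inpatient", ]
  expect_equal(inp$symptom_reported_n, 32)
  expect_equal(inp$severe_n, 15)
})

test_that("overall numerators and denominators are phase sums", {
  set.seed(33)
  cohort <- simulate_cohort(sim_config(n_participants = 3, seed = 91,
                                       postdischarge_days = 10,
                                       phase_duration_mean = c(preoperative = 12,
                                                               inpatient = 7)))
  ds <- dplyr::bind_rows(purrr::map(seq_len(nrow(cohort)), function(i) {
    summarize_days(cohort$stream[[i]], cohort$reports[[i]], NULL,
                   cohort$schedule[[i]])
  }))
  s <- aggregate_metrics(ds)$summary
  ph <- s[s$stratum != "overall", ]
  ov <- s[s$stratum == "overall", ]
  for (col in c("days", "symptom_reported_n", "symptom_reported_N", "severe_n",
                "severe_N", "worn_n", "worn_N", "prompts_sent", "prompts_walked")) {
    expect_equal(sum(ph[[col]]), ov[[col]], info = col)
  }
  td <- tidy(aggregate_metrics(ds))
  expect_true(all(td$estimate[td$metric %in%
    c("symptom_compliance", "severe_day_fraction", "wear_compliance")] >= 0 &
    td$estimate[td$metric %in%
    c("symptom_compliance", "severe_day_fraction", "wear_compliance")] <= 1,
    na.rm = TRUE))
})

test_that("step and bout statistics cover worn days only", {
  sched <- study_schedule(D0, D0 + 1, D0 + 1, D0 + 2)
  stream <- sedentary_stream(D0, from = "08:00", to = "11:59", steps = 1L)
  ds <- summarize_days(stream, empty_reports(), NULL, sched)
  s <- aggregate_metrics(ds)$summary
  ov <- s[s$stratum == "overall", ]
  expect_equal(ov$worn_n, 1)
  expect_equal(ov$steps_mean, 240)      # the single worn day, not zero-padded
  expect_false(is.na(ov$bout_mean))
})

test_that("the rendered table carries the published overall wear row", {
  txt <- render_metrics_table(aggregate_metrics(table2_day_summaries()))
  expect_true(any(grepl("653/927", txt)))
  expect_true(any(grepl("469/927", txt)))
  expect_true(any(grepl("172/469", txt)))
  g <- glance(aggregate_metrics(table2_day_summaries()))
  expect_equal(g$wear_compliance, 653 / 927)
  expect_equal(g$symptom_compliance, 469 / 927)
})
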