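#' Simulator configuration, calibrated to the published phase statistics
#'
#' Defaults encode the study conditions: phase durations (preoperative mean
#' 26 days, range 11-40; inpatient mean 10.4 days, range 6-15; postdischarge
#' fixed 30 days), daily step totals (mean/SD 5865/3113 preoperative,
#' 1594/1567 inpatient, 2054/1753 postdischarge, truncated at 0), target
#' mean sedentary-bout durations (23 / 177 / 72 minutes), severe-day
#' probabilities among rated days (0.34 / 0.47 / 0.39), symptom-reporting
#' probabilities (264/364, 32/143, 173/420), wear probabilities (330/364,
#' 51/143, 272/420) and walk-after-prompt probabilities (0.14 inpatient,
#' 0.32 otherwise, recovering the overall 27%).
#'
#' Daily step totals are drawn from a normal with the configured SD whose
#' location is moment-matched (see the methods vignette) so that the
#' realized day-total mean — after truncation at zero and the minimum steps
#' needed to fund each walking burst — equals the configured target mean.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param start_date Consent date of the first participant; consents are
#'   staggered weekly.
#' @param phase_duration_mean,phase_duration_sd,phase_duration_range Named
#'   per-phase duration parameters (days); postdischarge is fixed.
#' @param steps_mean,steps_sd Named per-phase daily step total parameters.
#' @param bout_target_mean Named per-phase target mean sedentary-bout
#'   duration (minutes) as extracted by [sb_bout_durations()].
#' @param p_severe,p_report,p_wear,p_walk Named per-phase probabilities.
#' @param response_probs Yes/No/Snooze response distribution at prompts.
#' @param noise_max Maximum sub-threshold "fidget" steps sprinkled into each
#'   sedentary bout (kept below the 50-step cap so bouts are preserved).
#' @param engagement_sd SD of a per-participant random effect (on the logit
#'   of wear and reporting probabilities); 0 disables it.
#' @param engine An [engine_config()]; fixes the daily active window.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 15L,
                       seed = 1L,
                       start_date = as.Date("2025-03-03"),
                       phase_duration_mean = c(preoperative = 26, inpatient = 10.4),
                       phase_duration_sd = c(preoperative = 7, inpatient = 2.5),
                       phase_duration_range = list(preoperative = c(11, 40),
                                                   inpatient = c(6, 15)),
                       postdischarge_days = 30L,
                       steps_mean = c(preoperative = 5865, inpatient = 1594,
                                      postdischarge = 2054),
                       steps_sd = c(preoperative = 3113, inpatient = 1567,
                                    postdischarge = 1753),
                       bout_target_mean = c(preoperative = 23, inpatient = 177,
                                            postdischarge = 72),
                       p_severe = c(preoperative = 90 / 264, inpatient = 15 / 32,
                                    postdischarge = 67 / 173),
                       p_report = c(preoperative = 264 / 364, inpatient = 32 / 143,
                                    postdischarge = 173 / 420),
                       p_wear = c(preoperative = 330 / 364, inpatient = 51 / 143,
                                  postdischarge = 272 / 420),
                       p_walk = c(preoperative = 0.32, inpatient = 45 / 311,
                                  postdischarge = 0.32),
                       response_probs = c(Yes = 0.5, No = 0.3, Snooze = 0.2),
                       noise_max = 10L,
                       engagement_sd = 0,
                       engine = engine_config()) {
  probs <- list(p_severe = p_severe, p_report = p_report, p_wear = p_wear,
                p_walk = p_walk)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!all(phase_levels %in% names(p))) {
      abort(paste0("sim_config: ", nm, " must name all three phases"))
    }
    if (any(p < 0 | p > 1)) abort(paste0("sim_config: ", nm, " outside [0, 1]"))
  }
  if (any(steps_mean <= 0) || any(steps_sd <= 0) || any(bout_target_mean <= 0)) {
    abort("sim_config: step and bout parameters must be positive")
  }
  W <- engine$active_end_min - engine$active_start_min
  if (any(bout_target_mean >= W)) {
    abort("sim_config: bout targets must be shorter than the active window")
  }
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    start_date = as.Date(start_date),
    phase_duration_mean = phase_duration_mean,
    phase_duration_sd = phase_duration_sd,
    phase_duration_range = phase_duration_range,
    postdischarge_days = as.integer(postdischarge_days),
    steps_mean = steps_mean, steps_sd = steps_sd,
    bout_target_mean = bout_target_mean,
    p_severe = p_severe, p_report = p_report, p_wear = p_wear, p_walk = p_walk,
    response_probs = response_probs / sum(response_probs),
    noise_max = as.integer(noise_max),
    engagement_sd = engagement_sd,
    engine = engine,
    active_minutes = W
  )
  # renewal-interval mean giving the target *extracted* pooled bout mean:
  # a day of W active minutes always partitions into bouts summing to W, and
  # a Poisson renewal leaves E[#bouts] = W/mu + 1 (the day-end partial bout),
  # so mu = W / (W/target - 1) makes W / E[#bouts] equal the target
  cfg$bout_interval_mean <- vapply(phase_levels, function(p) {
    t <- bout_target_mean[[p]]
    W / (W / t - 1)
  }, numeric(1))
  names(cfg$bout_interval_mean) <- phase_levels
  # moment-matched location for daily step totals (see vignette)
  cfg$steps_mu <- vapply(phase_levels, function(p) {
    calibrate_step_mu(
      target = steps_mean[[p]], s = steps_sd[[p]],
      floor_mean = expected_step_floor(cfg, p)
    )
  }, numeric(1))
  names(cfg$steps_mu) <- phase_levels
  structure(cfg, class = "sim_config")
}

# expected minimum daily steps implied by the bout structure: each completed
# bout ends in a walking burst of at least sb_step_cap steps, plus the mean
# fidget noise per bout
expected_step_floor <- function(cfg, phase) {
  n_bouts <- cfg$active_minutes / cfg$bout_interval_mean[[phase]] + 1
  cfg$engine$sb_step_cap * (n_bouts - 1) + (cfg$noise_max / 2) * n_bouts
}

# solve E[max(N(mu, s), f)] = target in mu; the floor f >= 0 subsumes the
# truncation of day totals at zero
calibrate_step_mu <- function(target, s, floor_mean) {
  f <- floor_mean
  g <- function(mu) {
    z <- (f - mu) / s
    f + (mu - f) * stats::pnorm(-z) + s * stats::dnorm(z) - target
  }
  stats::uniroot(g, lower = target - 6 * s, upper = target + s,
                 extendInt = "yes")$root
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_participants, "participants, seed", x$seed, "\n")
  m <- rbind(steps_mean = x$steps_mean, bout_target = x$bout_target_mean,
             p_report = round(x$p_report, 3), p_wear = round(x$p_wear, 3),
             p_severe = round(x$p_severe, 3), p_walk = round(x$p_walk, 3))
  print(m)
  invisible(x)
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

r_trunc_int <- function(n, mean, sd, range) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(out[seq_len(n)])
}

# one worn day's minute records for a phase: alternating sedentary intervals
# (exponential, calibrated mean) ending in single-minute walking bursts
simulate_day_minutes <- function(cfg, phase, date) {
  eng <- cfg$engine
  W <- cfg$active_minutes
  mu <- cfg$bout_interval_mean[[phase]]
  # bout lengths covering the active window
  lens <- integer(0)
  while (sum(lens) < W) {
    lens <- c(lens, pmax(1L, as.integer(round(rexp(8, 1 / mu)))))
  }
  cut <- which(cumsum(lens) >= W)[1]
  lens <- lens[seq_len(cut)]
  lens[cut] <- W - sum(lens[-cut])
  if (lens[cut] == 0L) lens <- lens[-cut]
  k <- length(lens) - 1L          # completed bouts, each ends in a burst
  steps <- integer(W)
  ends <- cumsum(lens)
  # fidget noise: small sub-cap step counts inside bouts
  noise_total <- 0L
  for (b in seq_along(lens)) {
    if (lens[b] < 3L) next
    nz <- sample.int(cfg$noise_max + 1L, 1L) - 1L
    if (nz == 0L) next
    first <- ends[b] - lens[b] + 1L
    spots <- first + sample.int(lens[b] - 1L, min(nz, lens[b] - 1L)) - 1L
    add <- rep(nz %/% length(spots), length(spots))
    add[seq_len(nz %% length(spots))] <- add[seq_len(nz %% length(spots))] + 1L
    steps[spots] <- steps[spots] + as.integer(add)
    noise_total <- noise_total + nz
  }
  # day total: calibrated normal, floored at what the bursts require
  total <- round(rnorm(1, cfg$steps_mu[[phase]], cfg$steps_sd[[phase]]))
  if (k > 0L) {
    burst_budget <- max(total - noise_total, eng$sb_step_cap * k)
    extra <- as.integer(stats::rmultinom(1, burst_budget - eng$sb_step_cap * k,
                                         rep(1 / k, k)))
    steps[ends[seq_len(k)]] <- steps[ends[seq_len(k)]] +
      eng$sb_step_cap + extra
  }
  minutes <- seq.int(eng$active_start_min, eng$active_start_min + W - 1L)
  tibble::tibble(
    timestamp = day_minute_ts(date, minutes),
    steps = steps,
    heart_rate = round(pmax(40, rnorm(W, 75, 8)))
  )
}

simulate_day_report <- function(cfg, phase, date) {
  severe <- runif(1) < cfg$p_severe[[phase]]
  sev <- sample(0:6, 10, replace = TRUE,
                prob = c(0.35, 0.25, 0.15, 0.10, 0.07, 0.05, 0.03))
  if (severe) {
    # fatigue and pain are the symptoms most often rated severe
    w <- setNames(rep(0.05, 10), symptom_names())
    w[c("pain", "fatigue")] <- 0.30
    idx <- sample.int(10, 1, prob = w / sum(w))
    sev[idx] <- sample(7:10, 1)
  }
  out <- tibble::tibble(date = date)
  out[symptom_names()] <- as.list(as.integer(sev))
  out
}

#' Simulate a perioperative cohort
#'
#' Generates seeded synthetic participants — study schedules, per-minute step
#' streams, daily symptom reports — whose per-phase statistics converge to
#' the configured calibration as the cohort grows. Unworn days have no
#' records at all; worn days carry a full active-window minute grid with
#' steps allocated by the calibrated bout/walk renewal process and
#' heart-rate samples.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per participant: `participant_id`,
#'   `schedule` (list of [study_schedule()]), `stream` (list of step-stream
#'   tibbles) and `reports` (list of report tibbles). The config is attached
#'   as attribute `"sim_config"`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2, seed = 42))
#' cohort$schedule[[1]]
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rows <- purrr::map(seq_len(config$n_participants), function(i) {
      consent <- config$start_date + 7 * (i - 1)
      preop <- r_trunc_int(1, config$phase_duration_mean[["preoperative"]],
                           config$phase_duration_sd[["preoperative"]],
                           config$phase_duration_range[["preoperative"]])
      inpat <- r_trunc_int(1, config$phase_duration_mean[["inpatient"]],
                           config$phase_duration_sd[["inpatient"]],
                           config$phase_duration_range[["inpatient"]])
      sched <- study_schedule(consent, consent + preop,
                              consent + preop + inpat - 1,
                              consent + preop + inpat - 1 + config$postdischarge_days)
      eff <- if (config$engagement_sd > 0) rnorm(1, 0, config$engagement_sd) else 0
      shift <- function(p) stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) + eff)
      days <- study_days(sched)
      stream_parts <- list()
      report_parts <- list()
      for (j in seq_len(nrow(days))) {
        ph <- days$phase[j]
        if (runif(1) < shift(config$p_wear[[ph]])) {
          stream_parts[[length(stream_parts) + 1L]] <-
            simulate_day_minutes(config, ph, days$date[j])
        }
        if (runif(1) < shift(config$p_report[[ph]])) {
          report_parts[[length(report_parts) + 1L]] <-
            simulate_day_report(config, ph, days$date[j])
        }
      }
      stream <- if (length(stream_parts) > 0) {
        validate_stream(dplyr::bind_rows(stream_parts))
      } else {
        validate_stream(tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                                       steps = integer()))
      }
      reports <- if (length(report_parts) > 0) {
        validate_reports(dplyr::bind_rows(report_parts))
      } else {
        empty_reports()
      }
      tibble::tibble(
        participant_id = sprintf("sim-%03d", i),
        schedule = list(sched), stream = list(stream), reports = list(reports)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "sim_config") <- config
    out
  })
}

#' Simulate worn patient-days of a single phase
#'
#' Convenience generator for calibration checks: `n_days` fully worn days
#' drawn from one phase's daily-step and bout calibration, without the
#' surrounding schedule or compliance sampling.
#'
#' @param phase `"preoperative"`, `"inpatient"` or `"postdischarge"`.
#' @param n_days Number of worn days to generate.
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config's).
#' @return A tibble with one row per day: `day`, `date`, `total_steps`, and
#'   `stream` (list-column of the day's minute records).
#' @export
simulate_phase_days <- function(phase, n_days, config = sim_config(),
                                seed = config$seed) {
  phase <- match.arg(phase, phase_levels)
  with_seed(seed, {
    dates <- config$start_date + seq_len(n_days) - 1
    rows <- purrr::map(seq_len(n_days), function(i) {
      minutes <- simulate_day_minutes(config, phase, dates[i])
      tibble::tibble(day = i, date = dates[i],
                     total_steps = sum(minutes$steps), stream = list(minutes))
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate participant responses and walking behavior at prompts
#'
#' For each prompt event, samples a Yes/No/Snooze choice from the configured
#' categorical distribution, reasons for No, and a walk/no-walk indicator
#' from the phase's walk-after-prompt probability. Walkers receive an
#' injected step burst (at least the feedback criterion) within the feedback
#' window; merge it into the stream with [inject_steps()] before computing
#' metrics.
#'
#' @param events Engine events from [run_engine()].
#' @param schedule The participant's [study_schedule()] (to phase the prompts).
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config's).
#' @return A tibble with one row per prompt: `prompt_index`, `prompt_time`,
#'   `phase`, `choice`, `reasons` (list-column), `walked`, and `injections`
#'   (list-column of `timestamp`/`steps` rows for walkers).
#' @export
simulate_responses <- function(events, schedule, config = sim_config(),
                               seed = config$seed) {
  prompts <- events[events$kind == "prompt", ]
  eng <- config$engine
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(prompts)), function(i) {
      t0 <- prompts$timestamp[i]
      ph <- phase_of(schedule, stream_date(t0))
      choice <- sample(names(config$response_probs), 1,
                       prob = config$response_probs)
      reasons <- if (choice == "No") {
        sample(no_reasons(), sample.int(2, 1))
      } else {
        character()
      }
      walked <- runif(1) < config$p_walk[[ph]]
      inj <- if (walked) {
        offset <- sample.int(max(eng$feedback_window - 2L, 1L), 1)
        tibble::tibble(
          timestamp = t0 + 60 * c(offset, offset + 1L),
          steps = as.integer(c(ceiling(eng$feedback_steps / 2) + 5L,
                               floor(eng$feedback_steps / 2) + 5L))
        )
      } else {
        tibble::tibble(timestamp = as.POSIXct(numeric(), tz = "UTC",
                                              origin = "1970-01-01"),
                       steps = integer())
      }
      tibble::tibble(prompt_index = prompts$prompt_index[i], prompt_time = t0,
                     phase = ph, choice = choice, reasons = list(reasons),
                     walked = walked, injections = list(inj))
    })
    if (length(rows) == 0) {
      return(tibble::tibble(prompt_index = integer(),
                            prompt_time = as.POSIXct(numeric(), tz = "UTC",
                                                     origin = "1970-01-01"),
                            phase = character(), choice = character(),
                            reasons = list(), walked = logical(),
                            injections = list()))
    }
    dplyr::bind_rows(rows)
  })
}

#' Merge simulated walking bursts into a step stream
#'
#' Adds injected steps to the minutes named in `responses$injections`,
#' creating records for minutes the device had none.
#'
#' @param stream A validated step stream.
#' @param responses Output of [simulate_responses()].
#' @return The augmented, validated stream.
#' @export
inject_steps <- function(stream, responses) {
  stream <- validate_stream(stream)
  inj <- dplyr::bind_rows(responses$injections)
  if (nrow(inj) == 0) return(stream)
  inj <- dplyr::summarise(dplyr::group_by(inj, .data$timestamp),
                          add = sum(.data$steps), .groups = "drop")
  merged <- dplyr::full_join(stream, inj, by = "timestamp")
  merged <- dplyr::arrange(merged, .data$timestamp)
  merged$steps <- dplyr::coalesce(merged$steps, 0L) +
    as.integer(dplyr::coalesce(merged$add, 0L))
  validate_stream(merged[c("timestamp", "steps", "heart_rate")])
}
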