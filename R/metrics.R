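#' Sedentary-bout durations for one day of worn minutes
#'
#' Partitions a day's worn minutes into sedentary bouts using the same
#' semantics as the prompt engine's clock: a bout ends at the minute where
#' cumulative steps since the bout started reach `sb_step_cap` (the crossing
#' minute belongs to the ending bout), and the trailing partial bout is
#' counted. An alternative convention (`method = "zero_runs"`, maximal runs
#' of zero-step minutes) is provided for sensitivity analysis.
#'
#' @param stream_day A validated step stream restricted to one calendar day
#'   (its rows are the worn minutes).
#' @param config An [engine_config()].
#' @param method `"step_cap"` (default, engine semantics) or `"zero_runs"`.
#' @return Numeric vector of bout durations in minutes (empty for an empty
#'   slice). Durations always sum to at most the number of worn minutes.
#' @examples
#' day <- sedentary_stream(as.Date("2025-03-01"), from = "08:00", to = "11:59")
#' day$steps[101] <- 50L
#' sb_bout_durations(day)   # bouts of 101 and 139 minutes
#' @export
sb_bout_durations <- function(stream_day, config = engine_config(),
                              method = c("step_cap", "zero_runs")) {
  config <- as_engine_config(config)
  method <- match.arg(method)
  stream_day <- validate_stream(stream_day)
  n <- nrow(stream_day)
  if (n == 0) return(numeric())
  if (length(unique(stream_date(stream_day$timestamp))) > 1) {
    abort("sb_bout_durations: stream slice spans more than one day")
  }
  steps <- stream_day$steps
  if (method == "zero_runs") {
    r <- rle(steps == 0L)
    return(as.numeric(r$lengths[r$values]))
  }
  bouts <- numeric()
  cum <- 0L
  len <- 0L
  for (i in seq_len(n)) {
    len <- len + 1L
    cum <- cum + steps[i]
    if (cum >= config$sb_step_cap) {
      bouts <- c(bouts, len)
      cum <- 0L
      len <- 0L
    }
  }
  if (len > 0L) bouts <- c(bouts, len)
  bouts
}

#' Per-day feasibility summaries
#'
#' Builds one row per study day combining wear, symptom reporting, activity
#' and prompt outcomes. A day counts as worn when the device logged any
#' steps (more than 0) or any heart-rate data (more than 0 beats/min).
#' Severe-day status is defined only on days with their own completed
#' rating. `prompts_walked` counts prompts followed by at least
#' `feedback_steps` steps within `feedback_window` minutes.
#'
#' @param stream A validated step stream for one participant.
#' @param reports Symptom reports (see [validate_reports()]).
#' @param events Engine events from [run_engine()], or `NULL` if prompts were
#'   not logged.
#' @param schedule A [study_schedule()].
#' @param config An [engine_config()].
#' @return A tibble with one row per study day: `date`, `phase`, `worn`,
#'   `symptom_reported`, `severe_day`, `total_steps`, `sb_bouts`
#'   (list-column of bout durations), `prompts_sent`, `prompts_walked`.
#' @export
summarize_days <- function(stream, reports, events, schedule,
                           config = engine_config()) {
  config <- as_engine_config(config)
  stream <- validate_stream(stream)
  reports <- validate_reports(reports)
  days <- study_days(schedule)
  s_date <- stream_date(stream$timestamp)

  prompt_times <- if (!is.null(events) && nrow(events) > 0) {
    events$timestamp[events$kind == "prompt"]
  } else {
    as.POSIXct(numeric(), tz = "UTC", origin = "1970-01-01")
  }
  p_date <- stream_date(prompt_times)
  stream_secs <- as.numeric(stream$timestamp)

  severe_lookup <- if (nrow(reports) > 0) {
    setNames(classify_severe(reports, config$severe_cutoff),
             as.character(reports$date))
  } else {
    logical()
  }

  rows <- purrr::map(seq_len(nrow(days)), function(i) {
    d <- days$date[i]
    slice <- stream[s_date == d, ]
    worn <- any(slice$steps > 0L) ||
      any(!is.na(slice$heart_rate) & slice$heart_rate > 0)
    reported <- as.character(d) %in% names(severe_lookup)
    pt <- prompt_times[p_date == d]
    walked <- 0L
    if (length(pt) > 0 && nrow(slice) > 0) {
      for (p in as.numeric(pt)) {
        in_win <- stream_secs > p & stream_secs <= p + 60 * config$feedback_window
        if (sum(stream$steps[in_win]) >= config$feedback_steps) {
          walked <- walked + 1L
        }
      }
    }
    tibble::tibble(
      date = d, phase = days$phase[i],
      worn = worn,
      symptom_reported = reported,
      severe_day = if (reported) unname(severe_lookup[as.character(d)]) else NA,
      total_steps = sum(slice$steps),
      sb_bouts = list(if (worn) sb_bout_durations(slice, config) else numeric()),
      prompts_sent = length(pt),
      prompts_walked = walked
    )
  })
  dplyr::bind_rows(rows)
}

#' Phase-stratified feasibility and activity metrics
#'
#' Aggregates day summaries into the study's headline feasibility table:
#' symptom-reporting compliance, severe-symptom-day fraction (of rated days),
#' wear compliance, daily step count and sedentary-bout duration statistics
#' (over worn days only), and prompt/walk rates (over days with logged
#' prompts), per perioperative phase and overall. Overall numerators and
#' denominators are the sums of the phase-level ones.
#'
#' @param day_summaries A tibble from [summarize_days()] (rows from several
#'   participants can simply be bound together).
#' @return An object of class `"periop_metrics"`: a list with `summary`
#'   (one row per phase plus `"overall"`) and `days` (the input). Methods:
#'   [tidy()], [glance()], [autoplot()], `print()`, and
#'   [render_metrics_table()].
#' @export
aggregate_metrics <- function(day_summaries) {
  ds <- tibble::as_tibble(day_summaries)
  need <- setdiff(c("date", "phase", "worn", "symptom_reported", "severe_day",
                    "total_steps", "sb_bouts", "prompts_sent", "prompts_walked"),
                  names(ds))
  if (length(need) > 0) {
    abort(paste0("aggregate_metrics: day summaries missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  one_stratum <- function(d, label) {
    worn <- d[d$worn, ]
    day_bout_means <- purrr::map_dbl(worn$sb_bouts, function(b) {
      if (length(b) == 0) NA_real_ else mean(b)
    })
    pooled <- unlist(worn$sb_bouts)
    pd <- d[d$prompts_sent > 0, ]
    rng <- function(x) if (length(x) == 0 || all(is.na(x))) c(NA_real_, NA_real_) else
      range(x, na.rm = TRUE)
    sr <- rng(worn$total_steps)
    br <- rng(day_bout_means)
    tibble::tibble(
      stratum = label,
      days = nrow(d),
      symptom_reported_n = sum(d$symptom_reported),
      symptom_reported_N = nrow(d),
      severe_n = sum(d$severe_day %in% TRUE),
      severe_N = sum(d$symptom_reported),
      worn_n = sum(d$worn),
      worn_N = nrow(d),
      steps_mean = if (nrow(worn) > 0) mean(worn$total_steps) else NA_real_,
      steps_sd = if (nrow(worn) > 1) sd(worn$total_steps) else NA_real_,
      steps_min = sr[1], steps_max = sr[2],
      bout_mean = if (any(!is.na(day_bout_means))) mean(day_bout_means, na.rm = TRUE) else NA_real_,
      bout_sd = if (sum(!is.na(day_bout_means)) > 1) sd(day_bout_means, na.rm = TRUE) else NA_real_,
      bout_min = br[1], bout_max = br[2],
      bout_pooled_mean = if (length(pooled) > 0) mean(pooled) else NA_real_,
      prompt_days = nrow(pd),
      prompts_per_day = if (nrow(pd) > 0)
        sum(pd$prompts_sent) / nrow(pd) else NA_real_,
      prompts_sent = sum(d$prompts_sent),
      prompts_walked = sum(d$prompts_walked),
      walk_fraction = if (sum(d$prompts_sent) > 0)
        sum(d$prompts_walked) / sum(d$prompts_sent) else NA_real_
    )
  }
  strata <- dplyr::bind_rows(
    purrr::map(phase_levels, function(p) one_stratum(ds[ds$phase == p, ], p)),
    one_stratum(ds, "overall")
  )
  structure(list(summary = strata, days = ds), class = "periop_metrics")
}

#' @export
print.periop_metrics <- function(x, ...) {
  cat(render_metrics_table(x), sep = "\n")
  invisible(x)
}

#' Render the metrics as a markdown table
#'
#' Produces a plain-text/markdown table with the phases as columns and the
#' feasibility rows (compliance as `% (n/N)`, activity as `mean (SD, range)`)
#' as rows.
#'
#' @param x A `"periop_metrics"` object.
#' @return Character vector of table lines.
#' @export
render_metrics_table <- function(x) {
  stopifnot(inherits(x, "periop_metrics"))
  s <- x$summary
  pct <- function(n, N) {
    ifelse(N > 0, sprintf("%.0f (%d/%d)", 100 * n / N, n, N), "—")
  }
  msr <- function(m, sdv, lo, hi, digits = 0) {
    ifelse(is.na(m), "—",
           sprintf("%.*f (%.*f, %.*f-%.*f)", digits, m, digits,
                   ifelse(is.na(sdv), 0, sdv), digits, lo, digits, hi))
  }
  cols <- c("Variable", tools::toTitleCase(s$stratum))
  rows <- list(
    c("Symptom reporting compliance, % (n/N)",
      pct(s$symptom_reported_n, s$symptom_reported_N)),
    c("Severe symptom days, % (n/N)", pct(s$severe_n, s$severe_N)),
    c("Smartwatch wearing compliance, % (n/N)", pct(s$worn_n, s$worn_N)),
    c("Daily step count, mean (SD, range)",
      msr(s$steps_mean, s$steps_sd, s$steps_min, s$steps_max)),
    c("Average sedentary behavior bout duration (minutes), mean (SD, range)",
      msr(s$bout_mean, s$bout_sd, s$bout_min, s$bout_max)),
    c("Prompts per day with logged prompts, mean",
      ifelse(is.na(s$prompts_per_day), "—",
             sprintf("%.2f", s$prompts_per_day))),
    c("Walked after prompt, % (n/N)", pct(s$prompts_walked, s$prompts_sent))
  )
  widths <- purrr::map_int(seq_along(cols), function(j) {
    max(nchar(c(cols[j], purrr::map_chr(rows, j))))
  })
  fmt <- function(cells) {
    paste0("| ", paste(purrr::map_chr(seq_along(cells), function(j) {
      formatC(cells[j], width = widths[j], flag = "-")
    }), collapse = " | "), " |")
  }
  c(fmt(cols),
    paste0("|", paste(purrr::map_chr(widths, function(w)
      strrep("-", w + 2)), collapse = "|"), "|"),
    purrr::map_chr(rows, fmt))
}

#' @export
tidy.periop_metrics <- function(x, ...) {
  s <- x$summary
  dplyr::bind_rows(
    tibble::tibble(stratum = s$stratum, metric = "symptom_compliance",
                   estimate = s$symptom_reported_n / s$symptom_reported_N,
                   n = s$symptom_reported_n, N = s$symptom_reported_N),
    tibble::tibble(stratum = s$stratum, metric = "severe_day_fraction",
                   estimate = ifelse(s$severe_N > 0, s$severe_n / s$severe_N, NA_real_),
                   n = s$severe_n, N = s$severe_N),
    tibble::tibble(stratum = s$stratum, metric = "wear_compliance",
                   estimate = s$worn_n / s$worn_N,
                   n = s$worn_n, N = s$worn_N),
    tibble::tibble(stratum = s$stratum, metric = "daily_steps_mean",
                   estimate = s$steps_mean, n = NA_integer_, N = s$worn_n),
    tibble::tibble(stratum = s$stratum, metric = "sb_bout_mean",
                   estimate = s$bout_mean, n = NA_integer_, N = s$worn_n),
    tibble::tibble(stratum = s$stratum, metric = "walk_after_prompt",
                   estimate = s$walk_fraction,
                   n = s$prompts_walked, N = s$prompts_sent)
  )
}

#' @export
glance.periop_metrics <- function(x, ...) {
  o <- x$summary[x$summary$stratum == "overall", ]
  tibble::tibble(
    days = o$days,
    symptom_compliance = o$symptom_reported_n / o$symptom_reported_N,
    severe_day_fraction = ifelse(o$severe_N > 0, o$severe_n / o$severe_N, NA_real_),
    wear_compliance = o$worn_n / o$worn_N,
    daily_steps_mean = o$steps_mean,
    sb_bout_mean = o$bout_mean,
    walk_after_prompt = o$walk_fraction
  )
}

#' @export
autoplot.periop_metrics <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$metric %in% c("symptom_compliance", "wear_compliance",
                            "severe_day_fraction", "walk_after_prompt") &
             td$stratum != "overall", ]
  td$stratum <- factor(td$stratum, levels = phase_levels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$stratum, y = .data$estimate,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Compliance over the perioperative course") +
    ggplot2::theme_minimal()
}
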