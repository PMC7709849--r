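---
title: "How periopwalk models symptom-tailored walking prompts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How periopwalk models symptom-tailored walking prompts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periopwalk)
```

## The intervention model

`periopwalk` implements a just-in-time adaptive intervention (JITAI) for
reducing prolonged sedentary behavior (SB) around major abdominal surgery.
The sensed input is a per-minute step stream from a wrist-worn device; the
self-reported input is a daily 10-symptom severity rating (0–10 per
symptom). The engine converts these into walk prompts whose frequency
adapts to the patient's day-to-day symptom burden:

* **SB definition.** Sedentary time accrues from a *reference point* — the
  last prompt, the last 50-step reset, or the opening of the day's active
  window — while fewer than `sb_step_cap` (50) cumulative steps have been
  logged since that reference. Once 50 steps accrue, the SB clock resets
  (an `sb_reset` event). A literal "fewer than 50 cumulative steps since
  the most recent prompt" rule would never reset once 50 steps accrue and
  would deadlock prompting; the walking reset is the only non-degenerate
  reading of a "prolonged SB bout" trigger.
* **Symptom tailoring.** A day is *severe* when any symptom of its
  effective rating is at or above `severe_cutoff` (7, inclusive). Severe
  days use `threshold_severe` (120 min) as the SB limit; all other days use
  `threshold_normal` (60 min). When no rating was completed that morning,
  the most recent earlier rating is carried forward with no expiry (last
  observation carried forward); a patient who has never rated symptoms is
  treated as non-severe, the more active default, on the grounds that
  ratings begin at enrollment in practice. Ratings are dated, not
  timestamped, so tailoring is resolved per calendar day.
* **Prompting.** A prompt fires at the first whole minute at which the
  day's threshold has elapsed since the reference. With the reference at
  09:00 and a 60-minute threshold the prompt fires at 10:00. Responses are
  Yes, No (with one or more reasons from Busy / Pain / Nausea / Other) or
  Snooze; Snooze schedules a re-prompt `snooze_delay` (15) minutes later.
  Unanswered prompts expire silently.
* **Feedback.** Independently of the response, a positive-feedback event
  fires at the first minute at which `feedback_steps` (30) cumulative
  steps are logged within `feedback_window` (15) minutes of a prompt — at
  most once per prompt.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sb_step_cap` | 50 | steps | walking reset of the SB clock |
| `threshold_normal` | 60 | min | SB limit on non-severe days |
| `threshold_severe` | 120 | min | SB limit on severe days |
| `severe_cutoff` | 7 | severity | inclusive severe-day cutoff |
| `snooze_delay` | 15 | min | snooze re-prompt delay |
| `feedback_window` | 15 | min | post-prompt step-counting window |
| `feedback_steps` | 30 | steps | feedback criterion |
| `quiet_hours` | 21:00–08:00 | — | no prompts overnight |
| `suppress_during_nonwear` | TRUE | — | unworn minutes freeze the SB clock |

## Boundary conventions and degenerate inputs

These choices are deliberate and tested:

* **Quiet hours.** The deployed system's overnight behavior is undescribed;
  prompting a sleeping patient is clearly unintended. No prompts are
  emitted in quiet hours and the SB clock restarts when the active window
  opens. The boundary minute at the start of quiet hours (21:00 sharp) is
  still eligible, so a fully sedentary, fully worn non-severe day with the
  default 13-hour window receives exactly `floor(780 / 60) = 13` prompts.
* **Non-wear.** Minutes with no device record freeze the SB clock and
  cannot carry a prompt (a watch that is off cannot notify); setting
  `suppress_during_nonwear = FALSE` treats absent minutes as sedentary
  wall-clock time for sensitivity analysis. Non-wear is represented by
  absent records, never zero-filling, so it stays distinguishable from
  sedentary wear.
* **Snooze.** A pending re-prompt is cancelled by an `sb_reset` and
  dropped when its minute falls in quiet hours or on an unworn minute;
  walking that does not reach the step cap does not cancel it.
* **Phase partition.** The surgery day counts as inpatient and the day
  after discharge starts postdischarge (half-open intervals), so phase day
  counts always sum to the study total.
* **Empty inputs.** An empty stream (device never worn) is valid and
  yields only daily reminders; an empty report history yields the
  non-severe threshold everywhere.

Correctness of the minute-stepped engine is checked against
`oracle_scan()`, an independent event-driven re-implementation that
recomputes every candidate event from prefix sums rather than carrying
incremental counters; the two must agree event-for-event on randomized
fixtures with mixed severe days, snoozes and non-wear gaps (1000 such
fixtures in the test suite).

## The patient simulator

`simulate_cohort()` generates synthetic perioperative participants so the
full pipeline is testable without any data downloads. Its defaults are the
published phase-level study conditions: phase durations (preoperative mean
26 d, range 11–40; inpatient mean 10.4 d, range 6–15; postdischarge 30 d),
daily step totals (mean/SD 5865/3113, 1594/1567, 2054/1753), mean SB bout
durations (23 / 177 / 72 min), severe-day probabilities among rated days
(0.34 / 0.47 / 0.39), reporting probabilities (0.725 / 0.224 / 0.412) and
wear probabilities (0.91 / 0.36 / 0.65). Walk-after-prompt probabilities
are 0.14 inpatient and 0.32 elsewhere; the non-inpatient value is derived
so that the overall walk rate is the published 27%. Phase durations are
drawn from range-truncated normals (SD 7 and 2.5 d) because only means and
ranges are published.

Within a worn day, steps are allocated by an alternating renewal process:
sedentary intervals drawn from an exponential distribution, each completed
interval ending in a single-minute walking burst of at least 50 steps
(which is what crosses the step cap and delimits the bout), plus a little
sub-cap "fidget" noise (at most 10 steps per bout) inside intervals.
Concentrating each burst in one minute keeps the extracted bout structure
identical to the generated renewal structure. Two calibrations make the
*realized* statistics match the configured targets rather than drifting
from them:

1. **Bout-interval mean.** A day of $W$ active minutes always partitions
   into bouts summing to $W$, and a Poisson renewal process leaves
   $\mathbb{E}[\#\text{bouts}] = W/\mu + 1$ (the day-end partial bout is
   counted). Solving $W / (W/\mu + 1) = \text{target}$ gives
   $\mu = W / (W/\text{target} - 1)$; with $W = 780$ and an inpatient
   target of 177 min, $\mu \approx 229$ min. Using $\mu = \text{target}$
   directly would bias the extracted pooled mean down by ~20%.
2. **Daily step totals.** Totals are drawn from a normal with the
   configured SD whose location solves
   $\mathbb{E}[\max(N(\mu, s), f)] = \text{target}$, where $f$ is the
   expected minimum total implied by the bout structure (each completed
   bout needs a 50-step burst). The floor subsumes truncation at zero, so
   the realized phase mean equals the configured mean instead of sitting a
   few hundred steps above it.

Reporting, wear, and severe-day status are sampled independently per day
(only marginal rates are published); an optional per-participant
`engagement_sd` random effect on the logit of wear and reporting
probabilities mimics participants who disengage entirely after surgery.
Severe reports set one symptom — weighted toward pain and fatigue, the
symptoms most often rated severe — to 7–10.

**What the simulator does not emulate:** within-day or day-to-day
autocorrelation of symptoms and activity, heart-rate physiology (heart
rate is generated only as a wear marker), partial-day wear (worn days
carry a full active-window grid), device sync faults, and readmission.
Passing calibration tests therefore shows that the pipeline recovers the
generator's marginal phase statistics, not that it would reproduce
individual-level temporal dynamics of real patients.

`simulate_responses()` is a one-pass policy: prompts are computed on the
base stream, responses and walk bursts are sampled per prompt, and
walkers' bursts can be merged back with `inject_steps()` before computing
metrics. Re-running the engine on the augmented stream would shift later
prompt times; the one-pass convention keeps the loop well-defined and is
adequate for feasibility metrics.

## Metrics conventions

* A day counts as **worn** when it logged any steps (>0) or any heart-rate
  data (>0 bpm) — so a day of zero-step records with no heart rate is
  *not* worn.
* **Severe-day fractions** are computed over rated days only; step and
  bout statistics are computed over worn days only, mirroring the caveat
  that such means describe the compliant subset.
* **Bout durations** for reporting reuse the engine's 50-step reset
  semantics (the crossing minute belongs to the ending bout; the trailing
  partial bout counts); a per-minute zero-run alternative is available via
  `sb_bout_durations(..., method = "zero_runs")`.
* **Prompt rates** are per day with logged prompts; snoozed re-prompts are
  ordinary prompt events (flagged `snoozed`), so rates can be computed
  with and without them.
* Overall numerators and denominators are phase sums by construction.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 3, seed = 42)
cohort <- simulate_cohort(cfg)

p1 <- cohort[1, ]
states <- daily_symptom_states(p1$reports[[1]], p1$schedule[[1]], cfg$engine)
events <- run_engine(p1$stream[[1]], states, p1$schedule[[1]], cfg$engine)
resp <- simulate_responses(events, p1$schedule[[1]], cfg)
stream <- inject_steps(p1$stream[[1]], resp)

days <- summarize_days(stream, p1$reports[[1]], events, p1$schedule[[1]], cfg$engine)
metrics <- aggregate_metrics(days)
metrics          # markdown table, phases as columns
glance(metrics)  # one-row overall summary
autoplot(metrics)
```

## Problem sizes and numerical notes

The test suite and the reproduction script keep simulations at desk scale
by choice: calibration checks use 200–400 simulated patient-days per phase
(about 3 × 10^5 minute records), which puts Monte-Carlo standard errors
around 150 steps/day and 4 minutes of bout duration — tight enough to
detect any systematic miscalibration while running in seconds. Engine ↔
oracle equivalence uses 1000 randomized one/two-day fixtures with varied
configurations (step caps 30/50, thresholds 25–120 min, three different
active windows, suppression on and off). All timestamps are timezone-naive
local clock time stored as UTC, so no daylight-saving arithmetic is ever
applied; all event times are whole minutes, and ties within a minute
resolve in the engine's evaluation order (feedback, then reset, then
prompt, then response).

## Known limitations

* Symptom ratings carry a date but no time, so a rating submitted later in
  the day retailors the *next* day rather than the rest of the current day.
* Carried-forward ratings never expire; a week-old severe rating still
  selects the 120-minute threshold.
* The engine holds one armed feedback window at a time; overlapping
  windows can only arise through snooze re-prompts, where the earlier
  window is evaluated before the re-prompt re-arms it.
* Inferential statistics between phases are out of scope: the published
  significance claims concern the original cohort, not this engine.
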