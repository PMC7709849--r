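Package: periopwalk
Title: Symptom-Tailored Walking Prompts from Perioperative Wearable Step Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minute-resolution just-in-time adaptive intervention (JITAI)
    engine for reducing sedentary behavior around major surgery. Converts
    per-minute wearable step streams and daily 10-symptom severity reports
    into symptom-tailored walk prompts (60-minute sedentary threshold on
    ordinary days, 120 minutes on severe-symptom days), with snooze
    re-prompting, positive-feedback detection and a 50-step sedentary-bout
    reset. Includes a calibrated perioperative patient simulator, a
    feasibility-metrics suite producing phase-stratified compliance and
    activity summaries, readers and writers for the on-disk formats, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
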