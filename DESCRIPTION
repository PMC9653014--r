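Package: mldprofiler
Title: Drug-Sensitivity Profiling and Multiple-Low-Dose Combination
    Screening from Live-Cell Proliferation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for time-lapse microscopy drug-profiling
    assays on patient-derived cancer cell models. Turns fluorescent
    nuclear-object counts into doubling times and areas under the
    proliferation curve, fits four-parameter logistic dose-response
    curves and inverts GI50/GI10 doses with explicit
    determined/undetermined verdicts, orchestrates two-stage
    multiple-low-dose (MLD) combination screens with generic low-dose
    fallbacks, scores drug-pair synergy against Loewe additivity
    (per-cell scores, drug-average localisation vectors, an integrated
    matrix sum), and summarises single-cell fate profiles (first fates,
    death timing, mitotic-event counts, interphase durations). A
    synthetic-data generator with logistic growth, Hill-type rate
    inhibition, Loewe-consistent combination surfaces and a stochastic
    cell-fate state machine makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    knitr,
    readr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
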