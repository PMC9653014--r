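# mldprofiler

Drug-sensitivity profiling and multiple-low-dose (MLD) combination
screening from live-cell proliferation kinetics.

Patient-derived cancer cell models are increasingly profiled by
time-lapse microscopy: fluorescent nuclei are counted every couple of
hours, and the resulting proliferation curves — not a single endpoint
— carry the drug-response readout. This package implements the full
analysis chain for such assays:

- **Growth kinetics** — t = 0 normalization, automatic log-phase
  detection, doubling-time estimation, and trapezoidal area under the
  proliferation curve (AUC), the assay's effect readout.
- **Dose-response** — four-parameter logistic (4PL) fits of AUC
  responses with bounded Levenberg-Marquardt least squares, and
  analytic inversion to GI50/GI10 doses with explicit
  determined/undetermined verdicts (resistant models are a result,
  not an error).
- **Two-stage MLD screening** — per-drug GI10 panels with generic
  fallback doses for resistant models, exhaustive enumeration of
  drug-subset regimens dosed at GI10, AUC-ratio scoring, cohort
  ranking and sensitivity calls, and cross-regimen correlation.
- **Loewe synergy** — expected combination effects by bisection of
  the isobole equation, per-cell synergy scores, drug-average
  localisation vectors, and a grid-refinement-invariant integrated
  synergy statistic. Sham combinations score exactly zero.
- **Single-cell fate profiling** — a validated event grammar for
  time-lapse fate annotations (mitosis, slippage, cytokinesis
  failure, death), first-fate distributions, pre- vs post-mitotic
  death classification, mitotic-event counts and interphase
  durations.
- **Synthetic data** — a generator with logistic growth, Hill-type
  rate inhibition, Loewe-consistent combination surfaces and a
  stochastic cell-fate state machine, so every stage is testable
  end-to-end with planted ground truth.

Everything is tidyverse-native: functions take and return tibbles,
models support broom-style `tidy()`/`glance()`, and results plot via
`autoplot()`/`plot_*()`.

## Worked example

Simulate a culture with a 28 h doubling time, recover the doubling
time, then titrate a drug calibrated to a 1.7 µM GI50 and recover
that too.

```r
library(mldprofiler)

spec <- growth_model_spec(doubling_time_h = 28, sampling_interval_h = 2,
                          horizon_h = 120)
tc <- normalize_to_t0(simulate_growth_curve(spec, noise_sd = 0.05, seed = 1))
estimate_doubling_time(tc, min_span_h = 24)
#> # A tibble: 1 × 8
#>   model_id treatment well  doubling_time_h window_start_h window_end_h fit_r2
#>   <chr>    <chr>     <chr>           <dbl>          <dbl>        <dbl>  <dbl>
#> 1 model    untreated A1               28.0              0          118  0.998
#> # ℹ 1 more variable: n_points <dbl>

drug <- calibrate_drug_for_gi(spec, target_dose_nM = 1700, level = 50,
                              t_end_h = 96, drug_id = "cisplatin")
plate <- simulate_titration_plate(spec, drug,
                                  doses_nM = c(0, 1700 * 3^(-3:3)),
                                  replicates = 3, noise_sd = 0.05, seed = 1)
prof <- profile_titration(plate, levels = c(10, 50))
prof$fit
#> <fourpl_fit> bottom 24.47, top 99.26, EC50 835.8 nM, hill 1.032 (SSE 20.1, n 8)
prof$gi
#> # A tibble: 2 × 4
#>   level dose_nM determined within_tested_range
#>   <dbl>   <dbl> <lgl>      <lgl>              
#> 1    10    126. TRUE       TRUE               
#> 2    50   1580. TRUE       TRUE
```

With 5% count noise the recovered GI50 (1580 nM) sits within 10% of
the planted 1700 nM; noiselessly it recovers to about 1%.

The demo pipeline runs the whole chain on a simulated 16-model
cohort screened with four replication-stress-response inhibitors:

```r
res <- run_pipeline(demo_config(seed = 1))
res$cohort$ranking
#> # A tibble: 11 × 5
#>   regimen                mean_reduction n_models n_excluded  rank
#>   <chr>                           <dbl>    <int>      <int> <int>
#> 1 ATRi+CHK1i+PARGi+WEE1i           85.2       16          0     1
#> 2 ATRi+CHK1i+WEE1i                 83.9       16          0     2
#> 3 CHK1i+PARGi+WEE1i                79.6       16          0     3
#> # … 8 more rows

res$correlations
#> # A tibble: 1 × 4
#>       r  p_value     n correlated
#>   <dbl>    <dbl> <int> <lgl>     
#> 1 0.975 1.38e-10    16 TRUE

res$fate$first_fates$completed_mitosis
#> # A tibble: 2 × 3
#>   treatment  completed_mitosis_strict completed_mitosis_any
#>   <chr>                         <dbl>                 <dbl>
#> 1 ATRi+CHK1i                     0.44                  0.46
#> 2 untreated                      0.88                  0.9
```

The quadruple low-dose regimen ranks first with 15 of 16 models
showing >80% growth reduction, the two CHK1i-containing pairs are
strongly correlated across the cohort, and under the combination
only 44% of tracked cells complete their first mitosis versus 88%
untreated — the kind of cohort-level picture the package is built to
produce. Reruns with the same config are numerically identical; the
manifest records the seed and a config hash.

See `vignette("methods")` for the models, estimator rules and
numerical choices (bisection tolerances, 4PL bounds, the log-phase
window rule, synergy weighting), and the limitations of each method.

## Testing

The test suite (testthat, 3rd edition) checks every module against
independent oracles — closed-form integrals, a deSolve ODE
integration, brute-force window scans, dense-grid isobole searches,
powerset enumeration, and Monte Carlo parameter recovery:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mldprofiler",
                               load_package = "installed")'
```

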