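---
title: "Methods: models, estimators and numerics in mldprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerics in mldprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mldprofiler)
```

This vignette documents the mathematical models, estimator rules and
numerical choices behind every stage of the package, in pipeline
order: growth simulation, doubling-time estimation, AUC-based
dose-response, GI inversion, the two-stage multiple-low-dose (MLD)
screen, Loewe synergy scoring, and single-cell fate profiling. It
states what the synthetic-data generator emulates, what it does not,
and the limitations of each method.

## Growth model

Object counts follow logistic growth with rate
$r = \ln 2 / T_d$ and carrying capacity $K$:

$$N(t) = \frac{K\,N_0\,e^{rt}}{K + N_0\,(e^{rt} - 1)},$$

which reduces to the pure exponential $N_0 \cdot 2^{t/T_d}$ when
$K = \infty$ (the default in `growth_model_spec()`). Defaults:
initial count 500 (a typical 96-well seeding density at the assay
magnification), sampling every 2 h (a common imaging cadence), and a
96-120 h horizon (the standard assay window). Measurement noise is
multiplicative log-normal: counts are multiplied by
$e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, because
segmentation errors scale with the number of objects; the default
$\sigma = 0.05$ corresponds to roughly 5% count error.

**Drug action** is modelled as a multiplicative scaling of the
growth rate. A drug described by `drug_response_spec()` has a
four-parameter logistic (4PL) rate-effect curve $f(d)$ between
`bottom` and `top` (percent of the untreated rate), and a treated
culture grows at rate $r \cdot f(d)/100$. A saturating dose with
`bottom = 0` therefore arrests the culture (flat counts) but does
not, by itself, kill it.

**What the generator emulates:** exponential/logistic proliferation,
dose-dependent cytostatic slowdown, replicate-to-replicate counting
noise, Loewe-consistent two-drug surfaces with an optional additive
synergy offset, and stochastic single-cell fate sequences. **What it
does not emulate:** spatial effects (confluence gradients, edge
wells), segmentation artefacts other than multiplicative noise,
pharmacokinetics (doses are constant over the assay), clonal
heterogeneity within a well, and cell-cycle synchronisation.

### The catastrophe factor

AUC-based responses have a hard floor under pure arrest: a flat
normalized curve at value 1 has AUC $t_{end}$, so the response can
never fall below $t_{end}/\mathrm{AUC}_{untreated} \times 100$ —
for doubling times in the tens of hours and a 96 h window this floor
sits well above 20%. Deep responses (>80% reduction) therefore
require declining counts, i.e. cell death. `simulate_regimen_plate()`
models this with a per-model *catastrophe multiplier*: for regimens
of two or more drugs the combined rate factor is

$$\varphi = 1 - c \cdot \sum_i \left(1 - f_i(d_i)/100\right),$$

which is allowed to go negative (net object loss). This emulates the
biology of combined pathway inhibition at low doses — individually
tolerated insults that jointly push cells into catastrophic
replication failure and post-mitotic death — without simulating the
mechanism. $c = 1$ reproduces plain multiplicative-ish additivity in
the small-inhibition limit; larger $c$ produces the strong
combination responses deep screens are designed to detect.

## Doubling-time estimation

`estimate_doubling_time()` automates "read the slope off the
log-phase portion of the curve". For each well it scans **every
contiguous window** of timepoints whose span is at least
`min_span_h` (default 24 h, about one cell cycle, so a window always
brackets real dynamics) and fits a least-squares line to
$\log_2(\text{value})$ vs time. The window with the highest $r^2$
wins; ties within $10^{-9}$ go to the longer window, then the
earlier start. The doubling time is the inverse slope.

Consequences of the rule: on a noiseless exponential every window is
perfectly linear, so the tie-break selects the full range and the
estimate is exact; on a logistic curve the plateau depresses $r^2$,
so the scan selects the early log phase. Zero-variance windows score
$r^2 = 0$ so they never outrank a real trend, and a series whose
best window has non-positive slope raises a "no growth" error rather
than returning a negative doubling time. Counts at or below zero are
floored at half the smallest positive value before the log transform
(only here, never in AUC computation). The scan is $O(n^2)$ in the
number of timepoints — trivial at assay scale (61 timepoints for
0-120 h at 2 h cadence).

## AUC dose-response and 4PL fitting

The effect readout is the trapezoidal area under the t=0-normalized
count curve over $[0, t_{end}]$ (default 96 h), with linear
interpolation when $t_{end}$ falls between grid points and a hard
error on extrapolation. `summarize_titration()` expresses each
dose's mean AUC as a percent of the dose-0 AUC, so the untreated
response is exactly 100.

`fit_four_pl()` fits
$y(d) = \text{bottom} + (\text{top} - \text{bottom}) / (1 + (d/\text{ec50})^{\text{hill}})$
by bounded Levenberg-Marquardt least squares using the raw
`minpack.lm::nls.lm` optimizer. Numerical choices:

- **Parametrized on $\log(\text{ec50})$** for conditioning: doses
  span decades, and the log parametrization makes the optimizer's
  steps scale-free.
- **Dose 0** is mapped to a large finite negative log-dose (minimum
  log nonzero dose minus $10^4$) so the Hill term underflows to
  exactly 0 and the untreated level anchors `top`; using
  $\log 0 = -\infty$ directly produces NaN gradients.
- **Bounds:** `bottom` in [0, 100]; `top` in [80, 120], softly
  anchored at the untreated level rather than pinned, tolerating
  normalization error; `hill` in (0, 10] — only inhibition curves
  are meaningful here.
- **Multi-start** (three starting points varying `bottom` and
  `hill`), keeping the lowest-deviance converged solution, because
  LM is local.
- **Flat profiles** (response range below 5 percent points) are
  unidentifiable and returned as `converged = FALSE` — resistant
  models are a *result*, not an error — and at least 4 distinct
  nonzero doses are required.

`invert_gi()` solves $y(d) = 100 - x$ for the GI$_x$ dose
analytically (the 4PL inverts in closed form). The result is
**undetermined** — an `NA` dose with `determined = FALSE`, not an
error — when the fitted floor cannot reach the requested inhibition,
when dose 0 already exceeds it, or when the solution lies beyond the
highest tested dose (no extrapolation). `gi_ordering_check()`
asserts the internal-consistency invariant GI$_{10}$ < GI$_{50}$ <
GI$_{90}$.

Note that because drug action scales the growth *rate*, the AUC
response is a monotone transform of the rate-effect curve and the
AUC-based GI50 does **not** equal the rate-effect `ec50`.
`calibrate_drug_for_gi()` inverts this transform (closed-form
exponential AUC plus `uniroot`) to construct a drug whose AUC-based
GI$_x$ lands exactly on a target dose, which is how the package's
parameter-recovery tests plant ground truth.

## Two-stage MLD screen

Stage 1 (`stage1_gi10_panel()`) assembles each model's per-drug
GI10 doses. Where the GI10 is undetermined (resistant, flat profile)
a drug-specific generic fallback dose is substituted and flagged
`provenance = "fallback"`; a drug with neither a determined GI10 nor
a fallback is an error, because stage 2 cannot dose it. Stage 2
(`enumerate_regimens()`, `score_regimen()`) forms all drug subsets
of size ≥ 2 (11 regimens for 4 drugs), doses each drug at its stage-1
level, and scores each regimen as the treated/untreated AUC ratio
× 100. `screen_matrix()` adds the untreated = 100 reference column;
`cohort_summary()` ranks regimens by mean reduction across models
and calls a model *sensitive* when its response falls below
100 − threshold (default threshold 80, i.e. >80% reduction).
`correlate_sensitivity()` compares two regimens' per-model responses
by pairwise-complete Pearson correlation (via `stats::cor.test`),
flagging $r \ge 0.5$ as correlated, and refuses fewer than 3
complete pairs.

## Loewe synergy scoring

The null model is Loewe additivity: the expected effect $E$ of doses
$(d_1, d_2)$ solves the isobole equation

$$\frac{d_1}{D_1(E)} + \frac{d_2}{D_2(E)} = 1,$$

where $D_i(E)$ is the monotherapy dose of drug $i$ producing effect
$E$ (the analytic 4PL inverse). `loewe_expected()` solves this by
**vectorized bisection** on $E$ over
$[\min(\text{bottoms}), \min(\text{tops})]$; the left side is
monotone increasing in $E$, so the root is unique. Tolerance is
$10^{-6}$ percent points with at most 200 iterations (bisection
halves the bracket each step, so 200 is far more than needed; the
tolerance test exits early). Edge handling: below a drug's floor its
required dose is unbounded and the term is 0; when the doses already
exceed what the floor requires the expected effect clamps to the
lower floor, and when they cannot reach the bracket it clamps to the
top. Margins ($d_i = 0$) short-circuit to the other drug's curve
exactly, so a sham combination (a drug "combined" with itself) scores
identically zero — the standard validity check, enforced in the test
suite.

`synergy_matrix()` fits the monotherapy curves from the matrix's own
margins by default (self-contained), or accepts external fits/specs.
Per-cell score = expected − observed (positive = synergy); margins
score 0 by construction. If fitted margins deviate from observed
margins by more than `margin_tol` (default 2 points) a warning is
recorded in the `margin_warning` attribute — a data-quality signal,
not an error.

**Integrated synergy** (`integrated_synergy()`) summarises the
interior as a weighted mean with trapezoid weights in log-dose along
both axes, normalized to total 1. The normalization makes the
statistic *grid-refinement invariant*: a uniform +s surface
integrates to +s at any dose-grid density, so values are comparable
across experiments with different designs. The plain unweighted cell
sum — which grows with grid density — is reported alongside for
comparability with tools that sum raw cells.
`drug_average_synergy()` reports, for each nonzero dose of one drug,
the mean score across the other drug's nonzero doses, localising
where on the dose range synergy concentrates.

## Cell-fate profiling

Records are long-format event sequences per cell with the alphabet
`normal_mitosis`, `abnormal_mitosis`, `mitotic_exit` (slippage),
`cytokinesis_failure`, `interphase_death`, `mitotic_death`, and an
explicit `end_of_observation` terminal that makes survivorship
unambiguous. After a division one daughter is followed, so each
record is a lineage path. `validate_fate_records()` enforces the
grammar: known classes, non-decreasing times, and exactly one
terminal event, last.

Summaries: `first_fate_distribution()` (fractions of first fates,
with completed-mitosis tallies reported both strictly — normal
mitoses only — and inclusively of abnormal mitoses);
`death_timing_classification()` (a death preceded by *any* mitotic
event is post-mitotic; pre + post + survivors = 1 by construction);
`mitotic_event_counts()` (histogram over surviving cells);
`interphase_durations()` (first interphase measured from observation
start, so it is right-shortened — observation begins mid-cycle;
second interphase between consecutive mitotic events; durations above
70 h flagged as long-arrest candidates).

The simulator (`fate_profile_spec()`, `simulate_fate_cohort()`) is a
per-cell state machine: the first event is drawn from a categorical
first-fate law at a uniform fraction of one cycle (mid-cycle start),
then cells cycle with Gaussian interphase durations and per-cycle
death hazards until death or the 96 h horizon. Default cohort size is
50 cells, a realistic manual-annotation effort.

## Problem sizes and runtime

Everything is desk-scale: 16 models × 4 drugs × 9-dose titrations
with 2 replicates, 11 regimens per model, 6 × 6 combination
matrices, and 50-cell fate cohorts. `run_pipeline(demo_config())`
runs the whole chain — growth, dose-response, two-stage screen,
cohort summary, correlation, synergy, fate, manifest — in well under
a minute on one CPU, and reruns with the same config are numerically
identical (the manifest records the seed and a config hash).

## Limitations

- The 4PL is an approximation to the AUC-response family induced by
  rate scaling; noiseless GI recovery is accurate to ~1%, not exact.
- AUC responses cannot distinguish arrest from death above the AUC
  floor; the catastrophe factor is a phenomenological stand-in for
  death, not a mechanistic model.
- The log-phase scan assumes a single contiguous log phase; cultures
  with biphasic growth will be summarised by their best single
  window.
- Loewe scoring requires both monotherapy fits to converge; synergy
  against a completely inactive drug is not defined here.
- The fate simulator draws i.i.d. cells; lineage correlation between
  sisters and density-dependent effects are out of scope.
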