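# Synthetic-data generators: logistic growth, Hill-type rate
# inhibition, Loewe-consistent combination surfaces, and a stochastic
# cell-fate state machine. These define the statistical structure the
# downstream analysis assumes, so every stage is testable without
# external data.

#' Specify a growth model for simulation
#'
#' Growth is logistic with rate `r = log(2) / doubling_time`:
#' \deqn{N(t) = \frac{K N_0 e^{rt}}{K + N_0 (e^{rt} - 1)}}
#' An unbounded carrying capacity (`carrying_capacity = Inf`, the
#' default) reduces this to the pure exponential
#' `N(t) = N0 * 2^(t / Td)`. The plateau mirrors the confluence
#' plateau seen at high seeding densities in live-cell assays.
#'
#' @param doubling_time_h Doubling time in hours (> 0).
#' @param initial_count Objects at t = 0 (> 0).
#' @param carrying_capacity Plateau object count (> initial_count), or
#'   `Inf` for unbounded exponential growth.
#' @param sampling_interval_h Hours between images (default 2).
#' @param horizon_h Assay length in hours (>= 2 sampling intervals).
#' @return A validated `growth_model_spec` list.
#' @export
#' @examples
#' growth_model_spec(28, initial_count = 500)
growth_model_spec <- function(doubling_time_h, initial_count = 500,
                              carrying_capacity = Inf,
                              sampling_interval_h = 2,
                              horizon_h = 120) {
  check_number(doubling_time_h, "doubling_time_h", lower = 1e-9)
  check_number(initial_count, "initial_count", lower = 1e-9)
  check_number(carrying_capacity, "carrying_capacity",
               lower = initial_count, allow_inf = TRUE)
  check_number(sampling_interval_h, "sampling_interval_h", lower = 1e-9)
  check_number(horizon_h, "horizon_h", lower = 2 * sampling_interval_h)
  structure(list(doubling_time_h = doubling_time_h,
                 initial_count = initial_count,
                 carrying_capacity = carrying_capacity,
                 sampling_interval_h = sampling_interval_h,
                 horizon_h = horizon_h),
            class = "growth_model_spec")
}

#' Specify a drug's effect on growth rate
#'
#' The drug scales the growth rate multiplicatively by `f(d) / 100`,
#' where `f` is the decreasing 4PL [four_pl()] curve defined by these
#' parameters (in percent of the untreated rate). There is no
#' explicit death compartment in count simulation; `bottom = 0` means
#' full growth arrest.
#'
#' @param drug_id Drug label.
#' @param ec50 Dose of half-maximal rate inhibition (> 0).
#' @param hill Hill slope (> 0).
#' @param bottom,top Rate-effect asymptotes in percent (bottom < top,
#'   top ~ 100).
#' @param unit Unit of `ec50`: `"nM"` (default) or `"uM"`
#'   (converted to nM on input).
#' @return A validated `drug_response_spec` list (doses in nM).
#' @export
#' @examples
#' drug_response_spec("CHK1i", ec50 = 135.3, hill = 1)
#' drug_response_spec("ATRi", ec50 = 2.11, hill = 1.5, unit = "uM")
drug_response_spec <- function(drug_id, ec50, hill = 1, bottom = 0,
                               top = 100, unit = c("nM", "uM")) {
  unit <- match.arg(unit)
  if (unit == "uM") ec50 <- um_to_nm(ec50)
  check_number(ec50, "ec50", lower = 1e-12)
  check_number(hill, "hill", lower = 1e-12)
  check_number(bottom, "bottom", lower = 0)
  check_number(top, "top", lower = bottom + 1e-9)
  structure(list(drug_id = as.character(drug_id), bottom = bottom,
                 top = top, ec50_nM = ec50, hill = hill),
            class = "drug_response_spec")
}

# % rate effect of a drug spec at given doses (nM)
rate_effect <- function(drug, dose_nM) {
  four_pl(dose_nM, drug$bottom, drug$top, drug$ec50_nM, drug$hill)
}

# closed-form logistic trajectory (vectorised over t); r may be
# negative (net object loss), in which case counts decay towards 0
logistic_counts <- function(t, n0, td, capacity = Inf, rate_factor = 1) {
  r <- log(2) / td * rate_factor
  if (!is.finite(capacity)) return(n0 * exp(r * t))
  capacity * n0 * exp(r * t) / (capacity + n0 * (exp(r * t) - 1))
}

#' Simulate one well's object-count time course
#'
#' Counts follow the closed-form logistic trajectory of
#' [growth_model_spec()], with multiplicative log-normal noise
#' (`count * exp(rnorm(0, noise_sd))`) emulating counting and
#' segmentation error proportional to the count. A fixed seed fixes
#' the output bit-for-bit.
#'
#' @param spec A `growth_model_spec`.
#' @param noise_sd SD of the log-scale multiplicative noise
#'   (fraction; default 0.05, 0 for noiseless).
#' @param seed Integer seed.
#' @param model_id,well,treatment Labels carried into the output.
#' @return A tibble (`model_id`, `well`, `treatment`, `time_h`,
#'   `count`) on the spec's sampling grid.
#' @export
#' @examples
#' simulate_growth_curve(growth_model_spec(28), noise_sd = 0, seed = 1)
simulate_growth_curve <- function(spec, noise_sd = 0.05, seed = 1,
                                  model_id = "model", well = "A1",
                                  treatment = "untreated") {
  stopifnot(inherits(spec, "growth_model_spec"))
  check_number(noise_sd, "noise_sd", lower = 0)
  t <- seq(0, spec$horizon_h, by = spec$sampling_interval_h)
  counts <- logistic_counts(t, spec$initial_count, spec$doubling_time_h,
                            spec$carrying_capacity)
  if (noise_sd > 0) {
    set.seed(seed)
    counts <- counts * exp(rnorm(length(t), 0, noise_sd))
  }
  tibble(model_id = model_id, well = well, treatment = treatment,
         time_h = t, count = counts)
}

#' Simulate a single-drug titration plate
#'
#' Each well grows with rate `r * f(d) / 100`, `f` the drug's percent
#' rate-effect curve; dose-0 wells are untreated. One well per
#' dose-replicate combination.
#'
#' @param growth A `growth_model_spec`.
#' @param drug A `drug_response_spec`.
#' @param doses_nM Doses in nM, must include 0.
#' @param replicates Wells per dose (>= 1).
#' @param noise_sd,seed As in [simulate_growth_curve()].
#' @param model_id Model label.
#' @return A tibble (`model_id`, `drug_id`, `dose_nM`, `well`,
#'   `treatment`, `time_h`, `count`).
#' @export
simulate_titration_plate <- function(growth, drug, doses_nM,
                                     replicates = 3, noise_sd = 0.05,
                                     seed = 1, model_id = "model") {
  stopifnot(inherits(growth, "growth_model_spec"),
            inherits(drug, "drug_response_spec"))
  if (length(doses_nM) == 0) abort("dose list is empty")
  if (!any(doses_nM == 0)) abort("doses must include 0 (untreated)")
  stopifnot(replicates >= 1)
  set.seed(seed)
  t <- seq(0, growth$horizon_h, by = growth$sampling_interval_h)
  grid <- tidyr::expand_grid(dose_nM = sort(unique(doses_nM)),
                             rep = seq_len(replicates))
  purrr::pmap(grid, function(dose_nM, rep) {
    phi <- rate_effect(drug, dose_nM) / 100
    counts <- logistic_counts(t, growth$initial_count,
                              growth$doubling_time_h,
                              growth$carrying_capacity, phi)
    if (noise_sd > 0) counts <- counts * exp(rnorm(length(t), 0, noise_sd))
    tibble(model_id = model_id, drug_id = drug$drug_id,
           dose_nM = dose_nM,
           well = sprintf("d%g_r%d", dose_nM, rep),
           treatment = if (dose_nM == 0) "untreated" else drug$drug_id,
           time_h = t, count = counts)
  }) |> list_rbind()
}

#' Simulate a multi-drug regimen alongside untreated wells
#'
#' For a regimen of `k` drugs at doses `d_i`, the combined growth-rate
#' factor is
#' `phi = 1 - catastrophe * sum_i (1 - f_i(d_i) / 100)` for `k >= 2`
#' (and plain `f(d) / 100` for monotherapy). `catastrophe = 1` is
#' additive inhibition of the rate; larger values emulate the
#' synergistic lethality (replication catastrophe, post-mitotic
#' death) that combined low-dose replication-checkpoint inhibition
#' elicits. `phi` may go negative, in which case object counts
#' decline - the regime in which a regimen can reduce the
#' proliferation AUC by more than the arrest-only floor.
#'
#' @param growth A `growth_model_spec`.
#' @param drugs Named list of `drug_response_spec`s.
#' @param regimen_doses_nM Named vector: dose per drug in the regimen
#'   (names must be in `names(drugs)`).
#' @param catastrophe Interaction multiplier (>= 0) applied for
#'   regimens of size >= 2; default 1 (additive).
#' @param replicates,noise_sd,seed,model_id As in
#'   [simulate_titration_plate()].
#' @return A tibble of treated wells (`treatment` = canonical regimen
#'   label) plus untreated wells.
#' @export
simulate_regimen_plate <- function(growth, drugs, regimen_doses_nM,
                                   catastrophe = 1, replicates = 3,
                                   noise_sd = 0.05, seed = 1,
                                   model_id = "model") {
  stopifnot(inherits(growth, "growth_model_spec"),
            all(names(regimen_doses_nM) %in% names(drugs)),
            all(regimen_doses_nM > 0), catastrophe >= 0)
  set.seed(seed)
  t <- seq(0, growth$horizon_h, by = growth$sampling_interval_h)
  inhib <- map_dbl(names(regimen_doses_nM), function(dr) {
    1 - rate_effect(drugs[[dr]], regimen_doses_nM[[dr]]) / 100
  })
  k <- length(regimen_doses_nM)
  phi <- if (k == 1L) 1 - inhib else 1 - catastrophe * sum(inhib)
  label <- regimen_label(names(regimen_doses_nM))
  one <- function(phi_w, treat, rep) {
    counts <- logistic_counts(t, growth$initial_count,
                              growth$doubling_time_h,
                              growth$carrying_capacity, phi_w)
    if (noise_sd > 0) counts <- counts * exp(rnorm(length(t), 0, noise_sd))
    tibble(model_id = model_id, treatment = treat,
           well = sprintf("%s_r%d", treat, rep), time_h = t,
           count = counts)
  }
  dplyr::bind_rows(
    map(seq_len(replicates), ~ one(1, "untreated", .x)) |> list_rbind(),
    map(seq_len(replicates), ~ one(phi, label, .x)) |> list_rbind())
}

#' Specify a two-drug combination surface
#'
#' @param drug_a,drug_b `drug_response_spec`s for the two agents.
#' @param doses_a_nM,doses_b_nM Dose grids in nM, each including 0.
#' @param synergy_offset Percent points of extra inhibition injected
#'   on interior cells (+ = observed effect lower than the
#'   Loewe-expected effect, i.e. synergy); default 0 (additive).
#' @param noise_sd SD (percent points) of additive Gaussian noise on
#'   interior cells; margins stay exact.
#' @return A validated `combination_surface_spec` list.
#' @export
combination_surface_spec <- function(drug_a, drug_b, doses_a_nM,
                                     doses_b_nM, synergy_offset = 0,
                                     noise_sd = 0) {
  stopifnot(inherits(drug_a, "drug_response_spec"),
            inherits(drug_b, "drug_response_spec"))
  if (!any(doses_a_nM == 0) || !any(doses_b_nM == 0)) {
    abort("both dose grids must include 0")
  }
  check_number(synergy_offset, "synergy_offset")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a_nM = sort(unique(doses_a_nM)),
                 doses_b_nM = sort(unique(doses_b_nM)),
                 synergy_offset = synergy_offset, noise_sd = noise_sd),
            class = "combination_surface_spec")
}

#' Simulate an observed dose-matrix effect surface
#'
#' Margins follow the two monotherapy curves exactly; each interior
#' cell is the Loewe-expected effect of the two curves minus
#' `synergy_offset` (extra inhibition) plus Gaussian noise. An offset
#' of 0 with no noise yields an exactly additive surface.
#'
#' @param spec A `combination_surface_spec`.
#' @param seed Integer seed (interior noise only).
#' @return A `dose_matrix` (see [dose_matrix()]).
#' @export
simulate_combination_matrix <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "combination_surface_spec"))
  set.seed(seed)
  fa <- spec_as_fit(spec$drug_a)
  fb <- spec_as_fit(spec$drug_b)
  grid <- tidyr::expand_grid(dose_a_nM = spec$doses_a_nM,
                             dose_b_nM = spec$doses_b_nM)
  expected <- loewe_expected(grid$dose_a_nM, grid$dose_b_nM, fa, fb)
  interior <- grid$dose_a_nM > 0 & grid$dose_b_nM > 0
  observed <- expected
  observed[interior] <- observed[interior] - spec$synergy_offset +
    if (spec$noise_sd > 0) rnorm(sum(interior), 0, spec$noise_sd) else 0
  dose_matrix(grid$dose_a_nM, grid$dose_b_nM, observed,
              drug_a = spec$drug_a$drug_id, drug_b = spec$drug_b$drug_id)
}

# a drug_response_spec behaves as a converged fourpl_fit wherever a
# fitted curve is expected (true-curve oracle paths, margins)
spec_as_fit <- function(drug) {
  new_fourpl_fit(drug$bottom, drug$top, drug$ec50_nM, drug$hill,
                 converged = TRUE, residual_sse = 0, n = NA_integer_,
                 max_dose_nM = Inf)
}

#' Calibrate a rate-effect drug spec to a target AUC-based GI dose
#'
#' Because the drug scales the growth *rate*, the AUC-based response
#' read out by the assay is a monotone transform of the rate-effect
#' curve, and the dose giving x% AUC inhibition is not the rate EC50.
#' This helper solves (closed form, exponential growth, no noise) for
#' the rate EC50 such that the simulated AUC response at
#' `target_dose_nM` equals `100 - level` - i.e. it plants a drug whose
#' assay GI_level is exactly `target_dose_nM`.
#'
#' @param growth A `growth_model_spec` (capacity must be `Inf`).
#' @param target_dose_nM The desired GI dose (nM).
#' @param level Inhibition level in percent (e.g. 50 for GI50).
#' @param t_end_h Assay window used for the AUC (default 96).
#' @param hill,bottom,top Remaining curve parameters, passed to
#'   [drug_response_spec()].
#' @param drug_id Drug label.
#' @return A `drug_response_spec` whose simulated titration yields the
#'   requested GI dose.
#' @export
#' @examples
#' g <- growth_model_spec(28)
#' d <- calibrate_drug_for_gi(g, target_dose_nM = 1700, level = 50)
calibrate_drug_for_gi <- function(growth, target_dose_nM, level,
                                  t_end_h = 96, hill = 1, bottom = 0,
                                  top = 100, drug_id = "drug") {
  stopifnot(inherits(growth, "growth_model_spec"),
            !is.finite(growth$carrying_capacity))
  check_number(target_dose_nM, "target_dose_nM", lower = 1e-9)
  check_number(level, "level", lower = 1e-9, upper = 100 - 1e-9)
  r <- log(2) / growth$doubling_time_h
  auc_exp <- function(phi) {
    if (abs(phi) < 1e-12) t_end_h else (exp(r * phi * t_end_h) - 1) / (r * phi)
  }
  response_at <- function(ec50) {
    phi <- four_pl(target_dose_nM, bottom, top, ec50, hill) / 100
    auc_exp(phi) / auc_exp(1) * 100
  }
  target <- 100 - level
  sol <- uniroot(function(e) response_at(e) - target,
                 lower = target_dose_nM * 1e-6,
                 upper = target_dose_nM * 1e6, tol = 1e-10)
  drug_response_spec(drug_id, ec50 = sol$root, hill = hill,
                     bottom = bottom, top = top)
}
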