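#' Summarize a titration plate into a dose-response dataset
#'
#' Computes each well's proliferation AUC over \[0, `t_end_h`\], then
#' for every dose the mean AUC as a percentage of the mean dose-0
#' (untreated) AUC. Dose 0 is 100 by construction.
#'
#' @param plate Normalized long time-course tibble with a `dose_nM`
#'   column (see [simulate_titration_plate()] / [normalize_to_t0()]).
#' @param t_end_h AUC window in hours (default 96).
#' @return A tibble (`model_id`/`drug_id` if present, `dose_nM`,
#'   `response`, `replicate_sd`, `n_wells`), sorted by dose.
#' @export
#' @examples
#' plate <- simulate_titration_plate(
#'   growth_model_spec(28, horizon_h = 96),
#'   drug_response_spec("drugX", ec50 = 500),
#'   doses_nM = c(0, 10, 100, 300, 1000, 3000, 10000),
#'   replicates = 1, noise_sd = 0)
#' summarize_titration(normalize_to_t0(plate))
summarize_titration <- function(plate, t_end_h = 96) {
  check_columns(plate, c("dose_nM", "time_h", "value"),
                "titration plate (normalized)")
  if (!any(plate$dose_nM == 0)) abort("plate has no dose-0 (untreated) wells")
  labels <- intersect(c("model_id", "drug_id"), names(plate))
  aucs <- area_under_curve(plate, t_end_h)
  out <- aucs |>
    group_by(across(all_of(c(labels, "dose_nM")))) |>
    summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
              n_wells = dplyr::n(), .groups = "drop_last")
  out <- out |>
    group_by(across(all_of(labels))) |>
    mutate(response = .data$mean_auc / .data$mean_auc[.data$dose_nM == 0][1] * 100,
           replicate_sd = .data$sd_auc / .data$mean_auc[.data$dose_nM == 0][1] * 100) |>
    ungroup() |>
    select(all_of(labels), "dose_nM", "response", "replicate_sd",
           "n_wells") |>
    arrange(across(all_of(c(labels, "dose_nM"))))
  out
}

#' Profile a titration plate end to end
#'
#' Convenience wrapper: normalize, summarize, fit the 4PL and invert
#' the requested GI levels - the complete single-drug
#' drug-sensitivity profiling pass.
#'
#' @param plate Raw long time-course tibble with `dose_nM`.
#' @param levels GI levels in percent (default `c(10, 50)`).
#' @param t_end_h AUC window (default 96).
#' @return A list with `data` (dose-response tibble), `fit`
#'   (`fourpl_fit`) and `gi` ([invert_gi()] tibble; all-`NA` doses
#'   with `determined = FALSE` when the fit does not converge).
#' @export
profile_titration <- function(plate, levels = c(10, 50), t_end_h = 96) {
  data <- summarize_titration(normalize_to_t0(plate), t_end_h)
  fit <- fit_four_pl(data)
  gi <- if (fit$converged) {
    invert_gi(fit, levels)
  } else {
    tibble(level = levels, dose_nM = NA_real_, determined = FALSE,
           within_tested_range = NA)
  }
  list(data = data, fit = fit, gi = gi)
}
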