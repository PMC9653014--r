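# Two-stage multiple-low-dose (MLD) combination screen: GI10 panel
# with generic low-dose fallbacks, regimen enumeration, AUC-based
# scoring, cohort ranking, sensitivity calls and pairwise
# sensitivity correlations.

#' Canonical regimen label
#'
#' Drug ids sorted alphabetically and joined with `+`, so matrices
#' built from differently ordered inputs merge deterministically.
#'
#' @param drug_ids Character vector of drug ids.
#' @return A single label string.
#' @export
#' @examples
#' regimen_label(c("CHK1i", "ATRi"))  # "ATRi+CHK1i"
regimen_label <- function(drug_ids) {
  paste(sort(unique(as.character(drug_ids))), collapse = "+")
}

#' Stage 1: assemble the per-model GI10 dose panel
#'
#' Determined GI10 doses pass through with provenance `"fitted"`;
#' undetermined ones (resistant models whose curve never reaches 10%
#' inhibition within the tested range) are replaced by the drug's
#' generic low dose with provenance `"fallback"`. An undetermined
#' GI10 for a drug without a fallback is an error - the screen
#' requires an explicit choice rather than an invented dose.
#'
#' @param fits Tibble with columns `model_id`, `drug_id`, `fit` (a
#'   list column of `fourpl_fit`s; non-converged fits count as
#'   undetermined).
#' @param fallback_nM Named numeric vector of generic low doses in nM
#'   (e.g. `c(PARGi = 100, ATRi = 2000)`).
#' @param level Inhibition level of the panel in percent (default 10).
#' @return A tibble (`model_id`, `drug_id`, `dose_nM`, `provenance`).
#' @export
stage1_gi10_panel <- function(fits, fallback_nM = c(PARGi = 100,
                                                    ATRi = 2000),
                              level = 10) {
  check_columns(fits, c("model_id", "drug_id", "fit"), "fit table")
  pmap(fits[c("model_id", "drug_id", "fit")],
       function(model_id, drug_id, fit) {
    gi <- if (inherits(fit, "fourpl_fit") && fit$converged) {
      invert_gi(fit, level)
    } else {
      tibble(determined = FALSE, dose_nM = NA_real_)
    }
    if (gi$determined[1]) {
      tibble(model_id = model_id, drug_id = drug_id,
             dose_nM = gi$dose_nM[1], provenance = "fitted")
    } else {
      if (!drug_id %in% names(fallback_nM)) {
        abort(sprintf(
          "GI%g undetermined for %s in %s and no fallback dose configured",
          level, drug_id, model_id))
      }
      tibble(model_id = model_id, drug_id = drug_id,
             dose_nM = unname(fallback_nM[drug_id]),
             provenance = "fallback")
    }
  }) |> list_rbind()
}

#' Enumerate all multi-drug regimens
#'
#' All drug subsets of size >= `min_size`, in canonical order (by
#' size, then alphabetical label). Four drugs at `min_size = 2` give
#' the classic 11 regimens (6 pairs, 4 triples, 1 quadruple).
#'
#' @param drugs Character vector of unique drug ids.
#' @param doses_nM Named numeric vector of the per-drug doses (nM).
#' @param min_size Smallest regimen size (default 2).
#' @return A tibble (`label`, `size`, `drugs` list-column, `doses_nM`
#'   list-column); empty when `min_size > length(drugs)`.
#' @export
#' @examples
#' enumerate_regimens(c("ATRi", "CHK1i", "PARGi", "WEE1i"),
#'                    c(ATRi = 2110, CHK1i = 135.3, PARGi = 100, WEE1i = 100))
enumerate_regimens <- function(drugs, doses_nM, min_size = 2) {
  if (anyDuplicated(drugs)) abort("drug ids must be unique")
  stopifnot(all(drugs %in% names(doses_nM)), all(doses_nM[drugs] > 0))
  drugs <- sort(drugs)
  sizes <- seq(min_size, length(drugs))
  if (min_size > length(drugs)) {
    return(tibble(label = character(), size = integer(),
                  drugs = list(), doses_nM = list()))
  }
  map(sizes, function(k) {
    subsets <- combn(drugs, k, simplify = FALSE)
    tibble(label = map_chr(subsets, regimen_label),
           size = k, drugs = subsets,
           doses_nM = map(subsets, ~ doses_nM[.x]))
  }) |> list_rbind() |> arrange(.data$size, .data$label)
}

#' Score one regimen against untreated wells
#'
#' Normalized proliferation of the regimen: mean treated AUC over
#' \[0, `t_end_h`\] divided by mean untreated AUC, times 100. Scores
#' below `100 - threshold` correspond to the ">threshold% reduction"
#' sensitivity call (see [cohort_summary()]).
#'
#' @param treated,untreated Normalized time-course tibbles covering
#'   \[0, `t_end_h`\].
#' @param t_end_h AUC window (default 96).
#' @return A single percent-of-untreated score.
#' @export
score_regimen <- function(treated, untreated, t_end_h = 96) {
  if (is.null(untreated) || nrow(untreated) == 0L) {
    abort("untreated wells are missing")
  }
  mean(area_under_curve(treated, t_end_h)$auc) /
    mean(area_under_curve(untreated, t_end_h)$auc) * 100
}

#' Assemble a model x regimen screen matrix
#'
#' @param scores Tibble (`model_id`, `regimen`, `value`, optionally
#'   `provenance`); `value` is percent of untreated. An `untreated`
#'   column fixed at 100 is added.
#' @return A `screen_matrix` (long tibble).
#' @export
screen_matrix <- function(scores) {
  check_columns(scores, c("model_id", "regimen", "value"),
                "screen scores")
  untr <- tibble(model_id = unique(scores$model_id),
                 regimen = "untreated", value = 100)
  out <- bind_rows(as_tibble(scores), untr) |>
    arrange(.data$model_id, .data$regimen)
  structure(out, class = c("screen_matrix", class(out)))
}

#' Rank regimens and call sensitivity across a cohort
#'
#' For each regimen the cohort mean reduction in proliferation
#' (`100 - value`, averaged over models with a determined score),
#' ranked in descending order; and for each model x regimen a boolean
#' sensitivity call at the given reduction threshold (default 80%,
#' i.e. normalized proliferation below 20% of untreated). Cells with
#' missing values are excluded from means, with the exclusion count
#' reported.
#'
#' @param matrix A [screen_matrix()] (the `untreated` column is
#'   ignored in the ranking).
#' @param sensitivity_threshold Percent reduction defining
#'   sensitivity (default 80).
#' @return A list: `ranking` tibble (`regimen`, `mean_reduction`,
#'   `n_models`, `n_excluded`, `rank`), `calls` tibble (`model_id`,
#'   `regimen`, `value`, `sensitive`).
#' @export
cohort_summary <- function(matrix, sensitivity_threshold = 80) {
  stopifnot(inherits(matrix, "screen_matrix"))
  m <- as_tibble(matrix) |> filter(.data$regimen != "untreated")
  if (nrow(m) == 0L) abort("screen matrix is empty")
  ranking <- m |>
    group_by(.data$regimen) |>
    summarise(mean_reduction = mean(100 - .data$value, na.rm = TRUE),
              n_models = sum(!is.na(.data$value)),
              n_excluded = sum(is.na(.data$value)),
              .groups = "drop") |>
    arrange(desc(.data$mean_reduction)) |>
    mutate(rank = dplyr::row_number())
  calls <- m |>
    mutate(sensitive = !is.na(.data$value) &
             (100 - .data$value) > sensitivity_threshold) |>
    select("model_id", "regimen", "value", "sensitive")
  list(ranking = ranking, calls = calls)
}

#' Pearson correlation between two per-model sensitivity vectors
#'
#' Pairwise-complete Pearson correlation with a two-tailed p-value.
#' Models with an undetermined (missing) value in either vector are
#' excluded when `exclude_undetermined = TRUE` (the convention for
#' GI panels with not-determined entries). The dichotomous
#' `correlated` flag applies the operational `r >= r_threshold`
#' reading (default 0.5); both `r` and the flag are returned so users
#' can re-threshold.
#'
#' @param data Data frame with one row per model.
#' @param x,y Columns of `data` (tidy-eval) holding the two
#'   sensitivity measures (e.g. GI50 doses, normalized AUCs).
#' @param exclude_undetermined Drop rows with `NA` in either column
#'   (default `TRUE`).
#' @param r_threshold Threshold for the `correlated` flag
#'   (default 0.5).
#' @return A one-row tibble: `r`, `p_value`, `n`, `correlated`.
#' @export
#' @examples
#' d <- tibble::tibble(gi_a = c(1, 2, 3, 4, NA), gi_b = c(2, 5, 5, 9, 1))
#' correlate_sensitivity(d, gi_a, gi_b)
correlate_sensitivity <- function(data, x, y,
                                  exclude_undetermined = TRUE,
                                  r_threshold = 0.5) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  stopifnot(length(xv) == length(yv))
  if (exclude_undetermined) {
    keep <- !is.na(xv) & !is.na(yv)
    xv <- xv[keep]; yv <- yv[keep]
  }
  if (length(xv) < 3L) abort("insufficient models (n < 3 after exclusion)")
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = length(xv),
         correlated = unname(ct$estimate) >= r_threshold)
}
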