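#' Load and validate cohort metadata
#'
#' Reads a cohort metadata table (one row per patient-derived model)
#' and validates the contract: required columns present, unique model
#' ids (patients may repeat - several models can derive from one
#' patient), positive seeding densities.
#'
#' The packaged example `cohort_synthetic.csv` is a synthetic
#' stand-in for a real cohort table: invented per-model values
#' constructed to match the documented cohort structure (16 models
#' from 14 patients, two patients contributing two models each,
#' three chemotherapy-naive patients).
#'
#' @param path Path to a CSV file with columns `ocm_id`,
#'   `patient_id`, `site`, `histology`, `figo_stage`,
#'   `germline_brca`, `lines_of_chemo`, `seeding_density_96well`.
#' @return A `cohort_metadata` tibble; `glance()` reports model and
#'   patient counts.
#' @export
#' @examples
#' path <- system.file("extdata", "cohort_synthetic.csv",
#'                     package = "mldprofiler")
#' cohort <- load_cohort(path)
#' glance(cohort)
load_cohort <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(paste("cannot read cohort file:",
                                    conditionMessage(e))))
  if (nrow(df) == 0L) abort("cohort file is empty")
  required <- c("ocm_id", "patient_id", "site", "histology",
                "figo_stage", "germline_brca", "lines_of_chemo",
                "seeding_density_96well")
  check_columns(df, required, "cohort metadata")
  if (anyDuplicated(df$ocm_id)) abort("duplicate ocm_id in cohort metadata")
  if (any(!is.finite(df$seeding_density_96well)) ||
      any(df$seeding_density_96well <= 0)) {
    abort("seeding_density_96well must be positive")
  }
  out <- as_tibble(df)
  structure(out, class = c("cohort_metadata", class(out)))
}

#' @describeIn load_cohort Model and patient counts.
#' @param x A `cohort_metadata` tibble.
#' @param ... Unused.
#' @export
glance.cohort_metadata <- function(x, ...) {
  tibble(n_models = nrow(x),
         n_patients = dplyr::n_distinct(x$patient_id),
         n_chemo_naive = sum(x$lines_of_chemo == 0))
}
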