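# Single-cell fate profiling from time-lapse annotations. Each
# record is one lineage path (after a division, one daughter is
# followed), so no branching structure is needed.

#' Event alphabet for cell-fate records
#'
#' `normal_mitosis`, `abnormal_mitosis` (tripolar divisions, division
#' of binucleated cells), `mitotic_exit` (slippage: entering mitosis
#' but exiting without division), `cytokinesis_failure` (furrow
#' regression merging daughters into one binucleated cell),
#' `interphase_death`, `mitotic_death`, and the explicit
#' `end_of_observation` terminal that makes survivorship unambiguous.
#'
#' @format Character vectors.
#' @export
fate_classes <- c("normal_mitosis", "abnormal_mitosis", "mitotic_exit",
                  "cytokinesis_failure", "interphase_death",
                  "mitotic_death", "end_of_observation")

#' @rdname fate_classes
#' @export
mitotic_event_classes <- c("normal_mitosis", "abnormal_mitosis",
                           "mitotic_exit", "cytokinesis_failure")

#' @rdname fate_classes
#' @export
death_classes <- c("interphase_death", "mitotic_death")

#' Validate a table of cell-fate records
#'
#' Checks the long-format contract: known event classes, per-cell
#' non-decreasing times, and at most one terminal event (a death or
#' `end_of_observation`) which must come last.
#'
#' @param records Tibble with columns `cell_id`, `treatment`,
#'   `event_time_h`, `event_class`.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_fate_records <- function(records) {
  check_columns(records,
                c("cell_id", "treatment", "event_time_h", "event_class"),
                "fate records")
  bad <- setdiff(unique(records$event_class), fate_classes)
  if (length(bad)) {
    abort(paste("unknown event class(es):", paste(bad, collapse = ", ")))
  }
  terminal <- c(death_classes, "end_of_observation")
  chk <- records |>
    group_by(.data$cell_id, .data$treatment) |>
    summarise(
      ordered = !is.unsorted(.data$event_time_h),
      n_terminal = sum(.data$event_class %in% terminal),
      terminal_last = !any(.data$event_class %in% terminal) ||
        (dplyr::last(.data$event_class) %in% terminal &&
           sum(.data$event_class %in% terminal) == 1L),
      .groups = "drop")
  if (any(!chk$ordered)) abort("event times must be non-decreasing within a cell")
  if (any(chk$n_terminal > 1L) || any(!chk$terminal_last)) {
    abort("each cell may have at most one terminal event, and it must be last")
  }
  as_tibble(records)
}

# per-cell digest used by all summaries
fate_digest <- function(records) {
  validate_fate_records(records) |>
    group_by(.data$treatment, .data$cell_id) |>
    arrange(.data$event_time_h, .by_group = TRUE) |>
    summarise(
      first_class = dplyr::first(.data$event_class),
      died = any(.data$event_class %in% death_classes),
      death_after_mitotic = {
        d <- which(.data$event_class %in% death_classes)
        length(d) > 0 &&
          any(.data$event_class[seq_len(d[1] - 1)] %in% mitotic_event_classes)
      },
      n_mitotic = sum(.data$event_class %in% mitotic_event_classes),
      t_mitotic1 = .data$event_time_h[
        which(.data$event_class %in% mitotic_event_classes)[1]],
      t_mitotic2 = .data$event_time_h[
        which(.data$event_class %in% mitotic_event_classes)[2]],
      .groups = "drop")
}

#' Distribution of first cell fates per treatment
#'
#' Fraction of cells whose first recorded event falls in each class.
#' Completed-mitosis tallies are reported both ways round the
#' abnormal-mitosis ambiguity: `completed_mitosis_strict` counts
#' first fates that are normal mitoses only, `completed_mitosis_any`
#' also counts abnormal mitoses.
#'
#' @param records Fate-record tibble (see [validate_fate_records()]).
#' @return A list: `fractions` tibble (`treatment`, `event_class`,
#'   `n`, `fraction`) and `completed_mitosis` tibble per treatment.
#' @export
first_fate_distribution <- function(records) {
  if (nrow(records) == 0L) abort("empty fate cohort")
  digest <- fate_digest(records)
  fractions <- digest |>
    group_by(.data$treatment,
             event_class = factor(.data$first_class,
                                  levels = fate_classes)) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    tidyr::complete(event_class = factor(fate_classes,
                                         levels = fate_classes),
                    fill = list(n = 0L)) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  completed <- digest |>
    group_by(.data$treatment) |>
    summarise(
      completed_mitosis_strict = mean(.data$first_class == "normal_mitosis"),
      completed_mitosis_any = mean(.data$first_class %in%
                                     c("normal_mitosis", "abnormal_mitosis")),
      .groups = "drop")
  list(fractions = fractions, completed_mitosis = completed)
}

#' Classify deaths as pre-mitotic/mitotic vs post-mitotic
#'
#' A death preceded by any mitotic event (normal or abnormal mitosis,
#' mitotic exit/slippage, cytokinesis failure) in the lineage is
#' post-mitotic; deaths with no prior mitotic event (first-interphase
#' death, death in the first mitosis) are pre-mitotic/mitotic.
#' Fractions are over all cells, so pre + post + survivors = 1.
#'
#' @param records Fate-record tibble.
#' @return A tibble per treatment: `pre_mitotic_fraction`,
#'   `post_mitotic_fraction`, `survivor_fraction`, `n_cells`.
#' @export
death_timing_classification <- function(records) {
  fate_digest(records) |>
    group_by(.data$treatment) |>
    summarise(
      pre_mitotic_fraction = mean(.data$died & !.data$death_after_mitotic),
      post_mitotic_fraction = mean(.data$died & .data$death_after_mitotic),
      survivor_fraction = mean(!.data$died),
      n_cells = dplyr::n(), .groups = "drop")
}

#' Mitotic-event counts among surviving cells
#'
#' Per surviving cell (no death event), the number of mitotic events
#' (normal/abnormal mitosis, mitotic exit, cytokinesis failure);
#' cells that died during the observation are excluded. Returned as
#' a histogram over 0..max events.
#'
#' @param records Fate-record tibble.
#' @return A tibble (`treatment`, `n_events`, `n_cells`, `fraction`),
#'   fractions over survivors within treatment.
#' @export
mitotic_event_counts <- function(records) {
  survivors <- fate_digest(records) |> filter(!.data$died)
  if (nrow(survivors) == 0L) {
    return(tibble(treatment = character(), n_events = integer(),
                  n_cells = integer(), fraction = numeric()))
  }
  survivors |>
    group_by(.data$treatment, n_events = .data$n_mitotic) |>
    summarise(n_cells = dplyr::n(), .groups = "drop_last") |>
    tidyr::complete(n_events = 0:max(survivors$n_mitotic),
                    fill = list(n_cells = 0L)) |>
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}

#' First and second interphase durations of surviving cells
#'
#' First interphase: observation start to the first mitotic event
#' (generally shorter than a full cycle, since observation starts
#' part-way through it). Second interphase: between the first and
#' second mitotic events; undefined (excluded) for cells with a
#' single mitotic event. Durations above `long_arrest_h` are flagged
#' as long-arrest candidates. Survivors only.
#'
#' @param records Fate-record tibble.
#' @param long_arrest_h Flagging threshold in hours (default 70).
#' @return A tibble (`treatment`, `cell_id`, `interphase`
#'   ("first"/"second"), `duration_h`, `long_arrest`).
#' @export
interphase_durations <- function(records, long_arrest_h = 70) {
  survivors <- fate_digest(records) |>
    filter(!.data$died, .data$n_mitotic >= 1L)
  out <- bind_rows(
    survivors |>
      transmute(.data$treatment, .data$cell_id, interphase = "first",
                duration_h = .data$t_mitotic1),
    survivors |>
      filter(.data$n_mitotic >= 2L) |>
      transmute(.data$treatment, .data$cell_id, interphase = "second",
                duration_h = .data$t_mitotic2 - .data$t_mitotic1))
  out |> mutate(long_arrest = .data$duration_h > long_arrest_h) |>
    arrange(.data$treatment, .data$cell_id, .data$interphase)
}
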