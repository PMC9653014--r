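# Stochastic cell-fate state machine emulating manually annotated
# time-lapse lineage paths.

#' Specify a cell-fate simulation
#'
#' Each simulated cell is one lineage path. The first event class is
#' drawn from `first_fate_probs`; its time is a uniform fraction of a
#' cycle length (observation starts part-way through the first
#' interphase, so first interphases are shorter than full cycles).
#' Cells surviving an event continue: each subsequent cycle they die
#' in interphase with probability `death_hazards["interphase"]`, die
#' in mitosis with `death_hazards["mitotic"]`, or undergo a further
#' mitotic event drawn from the mitotic classes of
#' `first_fate_probs` (renormalized). Cycle lengths are Normal
#' (`interphase_mean_h`, `interphase_sd_h`), truncated at 1 h.
#' Anything beyond `horizon_h` becomes `end_of_observation`.
#'
#' @param first_fate_probs Named probabilities over the six
#'   non-censoring classes (see [fate_classes]); must sum to 1
#'   (tolerance 1e-9).
#' @param death_hazards Named per-cycle probabilities
#'   `c(interphase = , mitotic = )` after the first event.
#' @param interphase_mean_h,interphase_sd_h Cycle-length Normal
#'   parameters in hours.
#' @param n_cells Number of cells (>= 1).
#' @param horizon_h Observation window in hours (default 96).
#' @param treatment Treatment label carried into the records.
#' @param seed Integer seed.
#' @return A validated `fate_profile_spec` list.
#' @export
fate_profile_spec <- function(first_fate_probs = c(
                                normal_mitosis = 0.85,
                                abnormal_mitosis = 0.05,
                                mitotic_exit = 0.04,
                                cytokinesis_failure = 0.02,
                                interphase_death = 0.02,
                                mitotic_death = 0.02),
                              death_hazards = c(interphase = 0.03,
                                                mitotic = 0.02),
                              interphase_mean_h = 24,
                              interphase_sd_h = 6,
                              n_cells = 50, horizon_h = 96,
                              treatment = "untreated", seed = 1) {
  allowed <- setdiff(fate_classes, "end_of_observation")
  if (!all(names(first_fate_probs) %in% allowed)) {
    abort("first_fate_probs names must be non-censoring fate classes")
  }
  if (any(first_fate_probs < 0) || any(first_fate_probs > 1) ||
      abs(sum(first_fate_probs) - 1) > 1e-9) {
    abort("first_fate_probs must lie in [0, 1] and sum to 1 (tolerance 1e-9)")
  }
  stopifnot(all(death_hazards >= 0), sum(death_hazards) <= 1,
            all(c("interphase", "mitotic") %in% names(death_hazards)))
  check_number(interphase_mean_h, "interphase_mean_h", lower = 1e-9)
  check_number(interphase_sd_h, "interphase_sd_h", lower = 0)
  stopifnot(n_cells >= 1)
  structure(list(first_fate_probs = first_fate_probs,
                 death_hazards = death_hazards,
                 interphase_mean_h = interphase_mean_h,
                 interphase_sd_h = interphase_sd_h,
                 n_cells = as.integer(n_cells), horizon_h = horizon_h,
                 treatment = treatment, seed = as.integer(seed)),
            class = "fate_profile_spec")
}

#' Simulate a cohort of cell-fate records
#'
#' @param spec A [fate_profile_spec()]. The spec's seed fixes the
#'   cohort bit-for-bit.
#' @return A long fate-record tibble (`cell_id`, `treatment`,
#'   `event_time_h`, `event_class`) satisfying
#'   [validate_fate_records()].
#' @export
#' @examples
#' records <- simulate_fate_cohort(fate_profile_spec(n_cells = 20))
#' first_fate_distribution(records)$fractions
simulate_fate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fate_profile_spec"))
  set.seed(spec$seed)
  p <- spec$first_fate_probs
  mit_p <- p[names(p) %in% mitotic_event_classes]
  cycle <- function() {
    max(rnorm(1, spec$interphase_mean_h, spec$interphase_sd_h), 1)
  }
  hz <- spec$horizon_h
  one_cell <- function(id) {
    times <- numeric(); classes <- character()
    t1 <- runif(1) * cycle()
    c1 <- sample(names(p), 1, prob = p)
    if (t1 > hz) {
      return(tibble(cell_id = id, treatment = spec$treatment,
                    event_time_h = hz,
                    event_class = "end_of_observation"))
    }
    times <- t1; classes <- c1
    t <- t1
    alive <- !(c1 %in% death_classes)
    while (alive) {
      u <- runif(1)
      L <- cycle()
      if (u < spec$death_hazards[["interphase"]]) {
        ev_t <- t + runif(1) * L; ev_c <- "interphase_death"
      } else if (u < sum(spec$death_hazards)) {
        ev_t <- t + L; ev_c <- "mitotic_death"
      } else {
        ev_t <- t + L
        ev_c <- if (length(mit_p) && sum(mit_p) > 0) {
          sample(names(mit_p), 1, prob = mit_p)
        } else "normal_mitosis"
      }
      if (ev_t > hz) {
        times <- c(times, hz); classes <- c(classes, "end_of_observation")
        break
      }
      times <- c(times, ev_t); classes <- c(classes, ev_c)
      t <- ev_t
      alive <- !(ev_c %in% death_classes)
    }
    if (alive && classes[length(classes)] != "end_of_observation") {
      times <- c(times, hz); classes <- c(classes, "end_of_observation")
    }
    tibble(cell_id = id, treatment = spec$treatment,
           event_time_h = times, event_class = classes)
  }
  map(sprintf("cell%05d", seq_len(spec$n_cells)), one_cell) |>
    list_rbind()
}
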