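# Independent oracles used across the suite. These deliberately do
# not share code with the package internals they check.

# closed-form integral of 2^(t/td) over [0, t_end]
exp_auc_closed_form <- function(td, t_end) {
  (2^(t_end / td) - 1) * td / log(2)
}

# exhaustive log-phase window search using lm(), the brute-force
# counterpart of the package's scan
brute_force_doubling_time <- function(time_h, value, min_span_h) {
  y <- log2(value)
  n <- length(time_h)
  best <- NULL
  for (i in 1:(n - 3)) {
    for (j in (i + 3):n) {
      if (time_h[j] - time_h[i] < min_span_h) next
      m <- stats::lm(y[i:j] ~ time_h[i:j])
      r2 <- summary(m)$r.squared
      if (is.null(best) || r2 > best$r2 + 1e-9) {
        best <- list(r2 = r2, slope = unname(stats::coef(m)[2]),
                     i = i, j = j)
      }
    }
  }
  1 / best$slope
}

# exact-4PL dose-response tibble
make_4pl_data <- function(doses, bottom = 0, top = 100, ec50 = 450,
                          hill = 1) {
  tibble::tibble(dose_nM = doses,
                 response = four_pl(doses, bottom, top, ec50, hill))
}

# pure-exponential normalized time course
make_exp_series <- function(td, times, model_id = "m", well = "A1") {
  tibble::tibble(model_id = model_id, well = well,
                 treatment = "untreated", time_h = times,
                 count = 500 * 2^(times / td))
}

# random but legal fate cohort built directly from the record grammar
random_fate_cohort <- function(n_cells, seed, treatment = "t") {
  set.seed(seed)
  nonterminal <- c("normal_mitosis", "abnormal_mitosis", "mitotic_exit",
                   "cytokinesis_failure")
  terminal <- c("interphase_death", "mitotic_death", "end_of_observation")
  purrr::map(seq_len(n_cells), function(i) {
    k <- sample(0:4, 1)
    classes <- c(sample(nonterminal, k, replace = TRUE),
                 sample(terminal, 1))
    times <- sort(runif(k + 1, 0, 96))
    tibble::tibble(cell_id = sprintf("c%04d", i), treatment = treatment,
                   event_time_h = times, event_class = classes)
  }) |> purrr::list_rbind()
}

# independent per-record scanner for death-timing classification
scan_death_timing <- function(records) {
  mitotic <- c("normal_mitosis", "abnormal_mitosis", "mitotic_exit",
               "cytokinesis_failure")
  deaths <- c("interphase_death", "mitotic_death")
  split(records, records$cell_id) |>
    lapply(function(rec) {
      rec <- rec[order(rec$event_time_h), ]
      idx <- which(rec$event_class %in% deaths)
      if (length(idx) == 0) return("survivor")
      if (any(rec$event_class[seq_len(idx[1] - 1)] %in% mitotic)) {
        "post"
      } else {
        "pre"
      }
    }) |> unlist()
}
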