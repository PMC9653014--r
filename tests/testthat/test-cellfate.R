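cell <- function(id, classes, times, treatment = "combo") {
  tibble::tibble(cell_id = id, treatment = treatment,
                 event_time_h = times, event_class = classes)
}

test_that("record validation enforces the grammar", {
  good <- cell("c1", c("normal_mitosis", "end_of_observation"), c(10, 96))
  expect_identical(validate_fate_records(good), good)

  expect_error(validate_fate_records(
    cell("c1", c("apoptosis"), 5)), "unknown event class")
  expect_error(validate_fate_records(
    cell("c1", c("normal_mitosis", "normal_mitosis"), c(20, 10))),
    "non-decreasing")
  expect_error(validate_fate_records(
    cell("c1", c("interphase_death", "normal_mitosis"), c(10, 20))),
    "terminal")
  expect_error(validate_fate_records(
    cell("c1", c("interphase_death", "mitotic_death"), c(10, 20))),
    "terminal")
  expect_error(validate_fate_records(
    tibble::tibble(cell_id = "c1", event_time_h = 1,
                   event_class = "normal_mitosis")),
    "treatment")
})

test_that("first-fate fractions count first events and sum to one", {
  rec <- dplyr::bind_rows(
    cell("c1", c("normal_mitosis", "end_of_observation"), c(10, 96)),
    cell("c2", c("normal_mitosis", "mitotic_exit", "end_of_observation"),
         c(12, 40, 96)),
    cell("c3", c("mitotic_exit", "end_of_observation"), c(30, 96)),
    cell("c4", c("abnormal_mitosis", "end_of_observation"), c(25, 96)),
    cell("c5", c("interphase_death"), 8))
  dist <- first_fate_distribution(rec)
  fr <- dist$fractions
  get <- function(cls) fr$fraction[fr$event_class == cls]
  expect_equal(get("normal_mitosis"), 2 / 5)
  expect_equal(get("mitotic_exit"), 1 / 5)
  expect_equal(get("abnormal_mitosis"), 1 / 5)
  expect_equal(get("interphase_death"), 1 / 5)
  expect_equal(get("cytokinesis_failure"), 0)
  expect_equal(sum(fr$fraction), 1)
  cm <- dist$completed_mitosis
  expect_equal(cm$completed_mitosis_strict, 0.4)
  expect_equal(cm$completed_mitosis_any, 0.6)
})

test_that("fractions are computed within treatment, not pooled", {
  rec <- dplyr::bind_rows(
    cell("c1", c("normal_mitosis", "end_of_observation"), c(10, 96),
         treatment = "untreated"),
    cell("c2", c("normal_mitosis", "end_of_observation"), c(11, 96),
         treatment = "untreated"),
    cell("c1", c("mitotic_exit", "end_of_observation"), c(30, 96),
         treatment = "combo"))
  fr <- first_fate_distribution(rec)$fractions
  expect_equal(
    fr$fraction[fr$treatment == "untreated" &
                  fr$event_class == "normal_mitosis"], 1)
  expect_equal(
    fr$fraction[fr$treatment == "combo" &
                  fr$event_class == "mitotic_exit"], 1)
})

test_that("a death after mitotic exit is post-mitotic; fractions partition the cohort", {
  rec <- dplyr::bind_rows(
    cell("c1", c("mitotic_exit", "interphase_death"), c(20, 50)),
    cell("c2", "mitotic_death", 15),
    cell("c3", "interphase_death", 5),
    cell("c4", c("normal_mitosis", "mitotic_death"), c(18, 44)),
    cell("c5", c("normal_mitosis", "end_of_observation"), c(18, 96)))
  dt <- death_timing_classification(rec)
  expect_equal(dt$post_mitotic_fraction, 2 / 5)
  expect_equal(dt$pre_mitotic_fraction, 2 / 5)
  expect_equal(dt$survivor_fraction, 1 / 5)
  expect_equal(dt$pre_mitotic_fraction + dt$post_mitotic_fraction +
                 dt$survivor_fraction, 1)
  expect_equal(dt$n_cells, 5L)
})

test_that("death-timing classification matches an independent scanner on random cohorts", {
  for (seed in c(3, 17, 101)) {
    rec <- random_fate_cohort(200, seed)
    dt <- death_timing_classification(rec)
    oracle <- scan_death_timing(rec)
    expect_equal(dt$pre_mitotic_fraction, mean(oracle == "pre"))
    expect_equal(dt$post_mitotic_fraction, mean(oracle == "post"))
    expect_equal(dt$survivor_fraction, mean(oracle == "survivor"))
  }
})

test_that("mitotic-event histograms exclude dead cells and match a recount", {
  rec <- dplyr::bind_rows(
    cell("c1", c("normal_mitosis", "normal_mitosis",
                 "end_of_observation"), c(10, 40, 96)),
    cell("c2", c("mitotic_exit", "end_of_observation"), c(30, 96)),
    cell("c3", "end_of_observation", 96),
    cell("c4", c("normal_mitosis", "mitotic_death"), c(12, 30)))
  hist <- mitotic_event_counts(rec)
  expect_equal(hist$n_events, 0:2)
  expect_equal(hist$n_cells, c(1L, 1L, 1L))
  expect_equal(sum(hist$fraction), 1)

  rec2 <- random_fate_cohort(300, seed = 9)
  hist2 <- mitotic_event_counts(rec2)
  # recount oracle with base R only
  mitotic <- c("normal_mitosis", "abnormal_mitosis", "mitotic_exit",
               "cytokinesis_failure")
  per_cell <- tapply(rec2$event_class, rec2$cell_id, function(cls) {
    if (any(cls %in% c("interphase_death", "mitotic_death"))) NA_integer_
    else sum(cls %in% mitotic)
  })
  per_cell <- per_cell[!is.na(per_cell)]
  for (k in hist2$n_events) {
    expect_equal(hist2$n_cells[hist2$n_events == k],
                 sum(per_cell == k))
  }
  expect_equal(sum(hist2$n_cells), length(per_cell))
})

test_that("interphase durations difference consecutive mitotic events", {
  rec <- dplyr::bind_rows(
    cell("c1", c("normal_mitosis", "normal_mitosis",
                 "end_of_observation"), c(10, 40, 96)),
    cell("c2", c("mitotic_exit", "end_of_observation"), c(75, 96)),
    cell("c3", "end_of_observation", 96),
    cell("c4", c("normal_mitosis", "mitotic_death"), c(12, 30)))
  dur <- interphase_durations(rec, long_arrest_h = 70)
  c1 <- dur[dur$cell_id == "c1", ]
  expect_equal(c1$duration_h[c1$interphase == "first"], 10)
  expect_equal(c1$duration_h[c1$interphase == "second"], 30)
  # single mitotic event: only a first interphase
  c2 <- dur[dur$cell_id == "c2", ]
  expect_equal(c2$interphase, "first")
  expect_true(c2$long_arrest)   # 75 h > 70 h threshold
  expect_false(any(c1$long_arrest))
  # no mitotic events or dead: absent entirely
  expect_false(any(dur$cell_id %in% c("c3", "c4")))
})
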