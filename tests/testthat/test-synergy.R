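# inverse of the 0-100 hill curve, written independently for the oracle
invert_effect_oracle <- function(E, ec50, hill) {
  ec50 * ((100 - E) / E)^(1 / hill)
}

fit_from_curve <- function(ec50, hill = 1, bottom = 0, top = 100) {
  fit_four_pl(make_4pl_data(c(0, ec50 * 3^(-3:3)), bottom = bottom,
                            top = top, ec50 = ec50, hill = hill))
}

test_that("Loewe expectation reduces to the monotherapy curves on the margins", {
  fa <- fit_from_curve(500, hill = 1.2)
  fb <- fit_from_curve(80, hill = 0.9)
  expect_equal(loewe_expected(0, 0, fa, fb), 100)
  d <- c(10, 100, 1000)
  expect_equal(loewe_expected(d, 0, fa, fb), predict(fa, d))
  expect_equal(loewe_expected(0, d, fa, fb), predict(fb, d))
})

test_that("sham combinations obey dose additivity", {
  f <- fit_from_curve(450, hill = 1)
  for (pair in list(c(50, 100), c(225, 225), c(900, 1350))) {
    got <- loewe_expected(pair[1], pair[2], f, f)
    # dense grid-search oracle for the effect of the pooled dose
    grid <- seq(0.01, 99.99, by = 0.001)
    idx <- which.min(abs(invert_effect_oracle(grid, 450, 1) -
                           sum(pair)))
    expect_equal(got, predict(f, sum(pair)), tolerance = 1e-4)
    expect_equal(got, grid[idx], tolerance = 0.01)
  }
  # steeper sham
  f2 <- fit_from_curve(200, hill = 2)
  expect_equal(loewe_expected(100, 150, f2, f2), predict(f2, 250),
               tolerance = 1e-4)
})

test_that("asymmetric Loewe solutions satisfy the isobole equation", {
  fa <- fit_from_curve(500, hill = 1)
  fb <- fit_from_curve(120, hill = 2)
  cells <- tidyr::expand_grid(d1 = c(100, 500, 2000),
                              d2 = c(30, 120, 480))
  E <- loewe_expected(cells$d1, cells$d2, fa, fb)
  resid <- cells$d1 / invert_effect_oracle(E, 500, 1) +
    cells$d2 / invert_effect_oracle(E, 120, 2) - 1
  expect_lt(max(abs(resid)), 1e-6)
  # brute-force scan over a million effect values agrees
  grid <- seq(1e-4, 100 - 1e-4, length.out = 1e6)
  for (k in c(1, 5, 9)) {
    g <- cells$d1[k] / invert_effect_oracle(grid, 500, 1) +
      cells$d2[k] / invert_effect_oracle(grid, 120, 2) - 1
    expect_equal(E[k], grid[which.min(abs(g))], tolerance = 1e-3)
  }
})

test_that("expected surfaces are monotone non-increasing in each dose", {
  fa <- fit_from_curve(300, hill = 1.4, bottom = 10)
  fb <- fit_from_curve(90, hill = 0.8)
  d1 <- c(0, 50, 150, 450, 1350)
  d2 <- c(0, 30, 90, 270, 810)
  surf <- outer(d1, d2, function(x, y) loewe_expected(x, y, fa, fb))
  expect_true(all(apply(surf, 1, function(r) all(diff(r) <= 1e-6))))
  expect_true(all(apply(surf, 2, function(cc) all(diff(cc) <= 1e-6))))
})

test_that("additive surfaces score zero; constructed offsets are recovered", {
  da <- drug_response_spec("A", ec50 = 500)
  db <- drug_response_spec("B", ec50 = 100)
  grids <- list(a = c(0, 500 * 2^(-2:2)), b = c(0, 100 * 2^(-2:2)))
  add <- simulate_combination_matrix(
    combination_surface_spec(da, db, grids$a, grids$b,
                             synergy_offset = 0, noise_sd = 0))
  s_add <- synergy_matrix(add, fit_a = da, fit_b = db)
  expect_lt(max(abs(s_add$score)), 1e-6)

  off <- simulate_combination_matrix(
    combination_surface_spec(da, db, grids$a, grids$b,
                             synergy_offset = 10, noise_sd = 0))
  s_off <- synergy_matrix(off, fit_a = da, fit_b = db)
  interior <- dplyr::filter(tidy(s_off), dose_a_nM > 0, dose_b_nM > 0)
  expect_equal(interior$score, rep(10, nrow(interior)), tolerance = 1e-6)
  margins <- dplyr::filter(tidy(s_off), dose_a_nM == 0 | dose_b_nM == 0)
  expect_true(all(margins$score == 0))

  # margins fitted from the matrix itself recover almost the same scores
  s_self <- synergy_matrix(off)
  interior_self <- dplyr::filter(tidy(s_self), dose_a_nM > 0,
                                 dose_b_nM > 0)
  expect_equal(interior_self$score, rep(10, nrow(interior_self)),
               tolerance = 1e-3)
})

test_that("mean interior score over noisy replicates recovers the planted offset", {
  da <- drug_response_spec("A", ec50 = 400, hill = 1.1)
  db <- drug_response_spec("B", ec50 = 90, hill = 0.9)
  spec <- combination_surface_spec(da, db, c(0, 400 * 2^(-2:2)),
                                   c(0, 90 * 2^(-2:2)),
                                   synergy_offset = 10, noise_sd = 2)
  means <- vapply(1:100, function(s) {
    m <- simulate_combination_matrix(spec, seed = s)
    surf <- synergy_matrix(m, fit_a = da, fit_b = db)
    mean(dplyr::filter(tidy(surf), dose_a_nM > 0, dose_b_nM > 0)$score)
  }, numeric(1))
  expect_lt(abs(mean(means) - 10), 1)
})

test_that("injected antagonism lowers scores symmetrically", {
  da <- drug_response_spec("A", ec50 = 400)
  db <- drug_response_spec("B", ec50 = 90)
  antag <- simulate_combination_matrix(
    combination_surface_spec(da, db, c(0, 400 * 2^(-2:2)),
                             c(0, 90 * 2^(-2:2)),
                             synergy_offset = -8, noise_sd = 0))
  s <- synergy_matrix(antag, fit_a = da, fit_b = db)
  interior <- dplyr::filter(tidy(s), dose_a_nM > 0, dose_b_nM > 0)
  expect_equal(interior$score, rep(-8, nrow(interior)), tolerance = 1e-6)
  expect_lt(integrated_synergy(s)$integrated, 0)
})

test_that("drug-average vectors localise synergy and match recomputed means", {
  da <- drug_response_spec("A", ec50 = 400)
  db <- drug_response_spec("B", ec50 = 90)
  m <- simulate_combination_matrix(
    combination_surface_spec(da, db, c(0, 100, 200, 400, 800, 1600),
                             c(0, 22.5, 45, 90, 180, 360),
                             synergy_offset = 0, noise_sd = 0))
  # plant synergy on a single row of drug A
  m$observed[m$dose_a_nM == 400 & m$dose_b_nM > 0] <-
    m$observed[m$dose_a_nM == 400 & m$dose_b_nM > 0] - 12
  s <- synergy_matrix(m, fit_a = da, fit_b = db)
  avg <- drug_average_synergy(s)
  a_vec <- dplyr::filter(avg, drug == "A")
  expect_equal(a_vec$mean_score[a_vec$dose_nM == 400], 12,
               tolerance = 1e-6)
  expect_true(all(abs(a_vec$mean_score[a_vec$dose_nM != 400]) < 1e-6))
  # recomputation oracle on the raw interior cells
  interior <- dplyr::filter(tidy(s), dose_a_nM > 0, dose_b_nM > 0)
  oracle <- tapply(interior$score, interior$dose_b_nM, mean)
  b_vec <- dplyr::filter(avg, drug == "B") |> dplyr::arrange(dose_nM)
  expect_equal(b_vec$mean_score, as.numeric(oracle))
})

test_that("integrated synergy is a normalized, refinement-invariant summary", {
  da <- drug_response_spec("A", ec50 = 400)
  db <- drug_response_spec("B", ec50 = 90)
  zero <- synergy_matrix(simulate_combination_matrix(
    combination_surface_spec(da, db, c(0, 400 * 2^(-2:2)),
                             c(0, 90 * 2^(-2:2)))),
    fit_a = da, fit_b = db)
  expect_equal(integrated_synergy(zero)$integrated, 0, tolerance = 1e-9)

  uniform <- function(grid_a, grid_b) {
    m <- simulate_combination_matrix(
      combination_surface_spec(da, db, grid_a, grid_b,
                               synergy_offset = 7, noise_sd = 0))
    integrated_synergy(synergy_matrix(m, fit_a = da, fit_b = db))
  }
  coarse <- uniform(c(0, 400 * 2^(-2:2)), c(0, 90 * 2^(-2:2)))
  fine <- uniform(c(0, 400 * 2^(seq(-2, 2, 0.5))),
                  c(0, 90 * 2^(seq(-2, 2, 0.5))))
  expect_equal(coarse$integrated, 7, tolerance = 1e-6)
  expect_equal(fine$integrated, coarse$integrated, tolerance = 1e-9)
  expect_gt(fine$n_interior, coarse$n_interior)
})

test_that("margin disagreement triggers a recorded warning, not an error", {
  da <- drug_response_spec("A", ec50 = 400)
  db <- drug_response_spec("B", ec50 = 90)
  m <- simulate_combination_matrix(
    combination_surface_spec(da, db, c(0, 400 * 2^(-2:2)),
                             c(0, 90 * 2^(-2:2))))
  m$observed[m$dose_a_nM == 0 & m$dose_b_nM == 90] <-
    m$observed[m$dose_a_nM == 0 & m$dose_b_nM == 90] + 15
  expect_warning(s <- synergy_matrix(m, fit_a = da, fit_b = db),
                 "margins")
  expect_false(is.null(attr(s, "margin_warning")))
})
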