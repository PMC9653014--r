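# Loewe-additivity synergy scoring for two-drug dose matrices.
# Sign convention: score = expected - observed, so positive = observed
# inhibition exceeds the Loewe expectation = synergy.

#' Construct a two-drug dose matrix of observed effects
#'
#' @param dose_a_nM,dose_b_nM Dose coordinates (nM) per cell; the
#'   full grid including the zero-dose margins must be present.
#' @param observed Observed effect per cell, percent of untreated.
#' @param drug_a,drug_b Drug labels.
#' @return A `dose_matrix` tibble (long format) with attributes
#'   `drug_a`, `drug_b`.
#' @export
dose_matrix <- function(dose_a_nM, dose_b_nM, observed,
                        drug_a = "drug_a", drug_b = "drug_b") {
  stopifnot(length(dose_a_nM) == length(dose_b_nM),
            length(observed) == length(dose_a_nM),
            all(is.finite(observed)))
  out <- tibble(dose_a_nM = dose_a_nM, dose_b_nM = dose_b_nM,
                observed = observed) |>
    arrange(.data$dose_a_nM, .data$dose_b_nM)
  if (!any(out$dose_a_nM == 0) || !any(out$dose_b_nM == 0)) {
    abort("dose matrix must include zero-dose margins")
  }
  structure(out, class = c("dose_matrix", class(out)),
            drug_a = drug_a, drug_b = drug_b)
}

#' Loewe-expected combined effect of two drugs
#'
#' Solves the Loewe additivity (isobole) equation
#' \deqn{d_1 / D_1(E) + d_2 / D_2(E) = 1}
#' for the expected effect `E` (percent of untreated) by bisection,
#' where `D_i(E)` is the dose of drug i alone producing effect `E`
#' (the 4PL inverse). At a zero dose the expression reduces to the
#' other drug's monotherapy curve, which is returned exactly. When
#' `E` lies below a drug's achievable floor its term is 0 (the
#' required dose is unbounded); when neither drug can reach the
#' bracketed effect, the expected effect is the lower of the two
#' floors.
#'
#' @param d1,d2 Dose vectors (nM, recycled to a common length).
#' @param fit1,fit2 Converged `fourpl_fit`s (or
#'   [drug_response_spec()]s coerced internally) for the two
#'   monotherapies; curves must be monotone decreasing.
#' @param tol Bisection tolerance on `E` in percent units
#'   (default 1e-6).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return Numeric vector of expected effects (percent of untreated).
#' @export
#' @examples
#' f <- fit_four_pl(tibble::tibble(
#'   dose_nM = c(0, 50, 150, 450, 1350, 4050),
#'   response = four_pl(c(0, 50, 150, 450, 1350, 4050), 0, 100, 450, 1)))
#' loewe_expected(100, 100, f, f)  # sham: equals the curve at 200 nM
#' four_pl(200, 0, 100, 450, 1)
loewe_expected <- function(d1, d2, fit1, fit2, tol = 1e-6,
                           max_iter = 200) {
  if (inherits(fit1, "drug_response_spec")) fit1 <- spec_as_fit(fit1)
  if (inherits(fit2, "drug_response_spec")) fit2 <- spec_as_fit(fit2)
  stopifnot(inherits(fit1, "fourpl_fit"), inherits(fit2, "fourpl_fit"))
  if (!fit1$converged || !fit2$converged) abort("fit not converged")
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n); d2 <- rep_len(d2, n)
  stopifnot(all(d1 >= 0), all(d2 >= 0))
  out <- numeric(n)
  both0 <- d1 == 0 & d2 == 0
  only1 <- d1 > 0 & d2 == 0
  only2 <- d1 == 0 & d2 > 0
  inner <- d1 > 0 & d2 > 0
  out[both0] <- 100
  out[only1] <- predict(fit1, d1[only1])
  out[only2] <- predict(fit2, d2[only2])
  if (any(inner)) {
    # interaction index at effect E; increasing in E
    g <- function(E, a, b) {
      D1 <- invert_effect(fit1, E)
      D2 <- invert_effect(fit2, E)
      a / D1 + b / D2 - 1   # d/Inf = 0 below a drug's floor
    }
    lo0 <- min(fit1$bottom, fit2$bottom)
    hi0 <- min(fit1$top, fit2$top)
    a <- d1[inner]; b <- d2[inner]
    lo <- rep(lo0 + 1e-12, length(a))
    hi <- rep(hi0 - 1e-12, length(a))
    g_lo <- g(lo, a, b); g_hi <- g(hi, a, b)
    res <- numeric(length(a))
    floor_hit <- g_lo >= 0    # doses exceed what the floor requires
    top_hit <- g_hi <= 0      # doses too small for any bracketed effect
    res[floor_hit] <- lo0
    res[top_hit] <- hi0
    open <- !floor_hit & !top_hit
    if (any(open)) {
      lo_o <- lo[open]; hi_o <- hi[open]
      a_o <- a[open]; b_o <- b[open]
      for (it in seq_len(max_iter)) {
        mid <- (lo_o + hi_o) / 2
        gm <- g(mid, a_o, b_o)
        up <- gm < 0          # root above mid
        lo_o[up] <- mid[up]
        hi_o[!up] <- mid[!up]
        if (max(hi_o - lo_o) < tol) break
      }
      res[open] <- (lo_o + hi_o) / 2
    }
    out[inner] <- res
  }
  out
}

#' Score a dose matrix against Loewe additivity
#'
#' Computes the Loewe-expected effect for every cell and the per-cell
#' synergy score `expected - observed` (positive = synergy). Margins
#' score 0 by construction. Monotherapy curves are fitted from the
#' matrix margins by default (self-contained); external fits or true
#' generating curves can be supplied instead. If the fitted margins
#' disagree with the observed margins beyond `margin_tol` a warning
#' is recorded (attribute `margin_warning`), not an error.
#'
#' @param matrix A [dose_matrix()].
#' @param fit_a,fit_b Optional `fourpl_fit` / `drug_response_spec`
#'   for the two monotherapies; fitted from the margins when `NULL`.
#' @param margin_tol Percent points of tolerated margin disagreement
#'   (default 2).
#' @return A `synergy_surface` tibble: `dose_a_nM`, `dose_b_nM`,
#'   `observed`, `expected`, `score`, with fits and sign convention in
#'   attributes.
#' @export
synergy_matrix <- function(matrix, fit_a = NULL, fit_b = NULL,
                           margin_tol = 2) {
  stopifnot(inherits(matrix, "dose_matrix"))
  if (is.null(fit_a)) {
    fit_a <- fit_four_pl(matrix |>
      filter(.data$dose_b_nM == 0) |>
      transmute(dose_nM = .data$dose_a_nM, response = .data$observed))
  }
  if (is.null(fit_b)) {
    fit_b <- fit_four_pl(matrix |>
      filter(.data$dose_a_nM == 0) |>
      transmute(dose_nM = .data$dose_b_nM, response = .data$observed))
  }
  if (inherits(fit_a, "drug_response_spec")) fit_a <- spec_as_fit(fit_a)
  if (inherits(fit_b, "drug_response_spec")) fit_b <- spec_as_fit(fit_b)
  if (!fit_a$converged || !fit_b$converged) {
    abort("monotherapy fit not converged; cannot compute Loewe expectation")
  }
  expected <- loewe_expected(matrix$dose_a_nM, matrix$dose_b_nM,
                             fit_a, fit_b)
  margin <- matrix$dose_a_nM == 0 | matrix$dose_b_nM == 0
  score <- expected - matrix$observed
  score[margin] <- 0   # margins define the monotherapies; scored 0
  margin_err <- max(abs(expected[margin] - matrix$observed[margin]))
  margin_warning <- NULL
  if (margin_err > margin_tol) {
    margin_warning <- sprintf(
      "fitted margins deviate from observed margins by up to %.2f points",
      margin_err)
    warn(margin_warning)
  }
  out <- as_tibble(matrix)
  out$expected <- expected
  out$score <- score
  structure(out, class = c("synergy_surface", class(as_tibble(out))),
            drug_a = attr(matrix, "drug_a"),
            drug_b = attr(matrix, "drug_b"),
            fit_a = fit_a, fit_b = fit_b,
            sign_convention = "positive = synergy (expected - observed)",
            margin_error = margin_err, margin_warning = margin_warning)
}

#' Drug-average synergy vectors
#'
#' For each nonzero concentration of one drug, the mean per-cell
#' score across the other drug's nonzero concentrations - the
#' standard display for localising where on the dose range synergy
#' concentrates.
#'
#' @param surface A `synergy_surface` from [synergy_matrix()].
#' @return A tibble (`drug`, `dose_nM`, `mean_score`), one row per
#'   nonzero concentration of each drug.
#' @export
drug_average_synergy <- function(surface) {
  stopifnot(inherits(surface, "synergy_surface"))
  interior <- surface |>
    filter(.data$dose_a_nM > 0, .data$dose_b_nM > 0)
  bind_rows(
    interior |>
      group_by(dose_nM = .data$dose_a_nM) |>
      summarise(mean_score = mean(.data$score), .groups = "drop") |>
      mutate(drug = attr(surface, "drug_a") %||% "drug_a", .before = 1),
    interior |>
      group_by(dose_nM = .data$dose_b_nM) |>
      summarise(mean_score = mean(.data$score), .groups = "drop") |>
      mutate(drug = attr(surface, "drug_b") %||% "drug_b", .before = 1))
}

# trapezoid weights over log-doses; length-1 grids get weight 1
log_dose_weights <- function(unique_doses) {
  u <- log(unique_doses)
  m <- length(u)
  if (m == 1L) return(1)
  w <- numeric(m)
  w[1] <- (u[2] - u[1]) / 2
  w[m] <- (u[m] - u[m - 1]) / 2
  if (m > 2L) w[2:(m - 1)] <- (u[3:m] - u[1:(m - 2)]) / 2
  w
}

#' Integrated synergy of a surface
#'
#' A single number summarising net synergy/antagonism across the
#' matrix: the weighted sum of interior cell scores, each cell
#' weighted by its share of log-dose area (trapezoid weights in log
#' dose along both axes, normalized to total 1). The normalization
#' makes the statistic invariant to refining the dose grid over a
#' fixed range: a uniform +s surface integrates to +s at any grid
#' density. The plain unweighted cell sum is also reported for
#' comparability with tools that sum raw cells.
#'
#' @param surface A `synergy_surface`.
#' @return A one-row tibble: `integrated` (percent points, positive =
#'   net synergy), `unweighted_sum`, `n_interior`.
#' @export
integrated_synergy <- function(surface) {
  stopifnot(inherits(surface, "synergy_surface"))
  interior <- surface |>
    filter(.data$dose_a_nM > 0, .data$dose_b_nM > 0)
  if (nrow(interior) == 0L) abort("surface has no interior cells")
  ua <- sort(unique(interior$dose_a_nM))
  ub <- sort(unique(interior$dose_b_nM))
  wa <- log_dose_weights(ua)
  wb <- log_dose_weights(ub)
  w <- wa[match(interior$dose_a_nM, ua)] * wb[match(interior$dose_b_nM, ub)]
  w <- w / sum(w)
  tibble(integrated = sum(w * interior$score),
         unweighted_sum = sum(interior$score),
         n_interior = nrow(interior))
}

#' @describeIn synergy_matrix Per-cell scores as a plain tibble.
#' @param x A `synergy_surface`.
#' @param ... Unused.
#' @export
tidy.synergy_surface <- function(x, ...) {
  as_tibble(x)[c("dose_a_nM", "dose_b_nM", "observed", "expected",
                 "score")]
}

#' @describeIn synergy_matrix One-row summary: integrated synergy,
#'   unweighted sum, interior cell count, worst margin error.
#' @export
glance.synergy_surface <- function(x, ...) {
  integrated_synergy(x) |>
    mutate(margin_error = attr(x, "margin_error"))
}
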