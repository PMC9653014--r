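#' Evaluate a four-parameter logistic inhibition curve
#'
#' The 4PL used throughout is
#' \deqn{y(d) = bottom + \frac{top - bottom}{1 + (d / ec50)^{hill}}}
#' with `y` in percent of untreated and `d` in nM. With `hill > 0` the
#' curve decreases from `top` (at dose 0) towards `bottom`.
#'
#' @param dose_nM Numeric vector of doses (nM, >= 0).
#' @param bottom,top Asymptotes in percent of untreated, `bottom < top`.
#' @param ec50_nM Dose of half-maximal effect (nM, > 0).
#' @param hill Hill slope (> 0).
#' @return Numeric vector of responses (percent of untreated).
#' @export
#' @examples
#' four_pl(c(0, 135.3, 1e6), bottom = 0, top = 100, ec50_nM = 135.3, hill = 1)
four_pl <- function(dose_nM, bottom, top, ec50_nM, hill) {
  stopifnot(all(dose_nM >= 0), ec50_nM > 0, hill > 0, bottom < top)
  bottom + (top - bottom) / (1 + (dose_nM / ec50_nM)^hill)
}

new_fourpl_fit <- function(bottom, top, ec50_nM, hill, converged,
                           residual_sse, n, max_dose_nM, data = NULL) {
  structure(
    list(bottom = bottom, top = top, ec50_nM = ec50_nM, hill = hill,
         converged = converged, residual_sse = residual_sse, n = n,
         max_dose_nM = max_dose_nM, data = data),
    class = "fourpl_fit")
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares (via
#' [minpack.lm::nlsLM()]) of [four_pl()] to replicate-averaged
#' responses. Bounds follow the assay's conventions: `bottom` in
#' \[0, 100\], `top` in \[80, 120\] (softly anchored at the untreated
#' level rather than pinned), `hill` in (0, 10\]. Starting values are
#' `top = 100`, `bottom = min(response)`, `ec50` the geometric mean of
#' the nonzero doses, `hill = 1`.
#'
#' Flat response profiles (range below `flat_range`) are
#' unidentifiable - resistant models in practice - and are returned
#' with `converged = FALSE` rather than an arbitrary curve.
#'
#' @param data Data frame with columns `dose_nM` (incl. 0) and
#'   `response` (percent of untreated), e.g. from
#'   [summarize_titration()].
#' @param flat_range Minimum response range (percent points) below
#'   which the profile is flagged flat. Default 5.
#' @return A `fourpl_fit` object; see [tidy.fourpl_fit()] and
#'   [glance.fourpl_fit()].
#' @export
#' @examples
#' d <- tibble::tibble(dose_nM = c(0, 30, 100, 300, 1000, 3000),
#'                     response = four_pl(c(0, 30, 100, 300, 1000, 3000),
#'                                        0, 100, 300, 1))
#' fit <- fit_four_pl(d)
#' tidy(fit)
fit_four_pl <- function(data, flat_range = 5) {
  check_columns(data, c("dose_nM", "response"), "dose-response data")
  data <- dplyr::arrange(as_tibble(data), .data$dose_nM)
  nz <- unique(data$dose_nM[data$dose_nM > 0])
  if (length(nz) < 4L) {
    abort("need at least 4 distinct nonzero doses to fit a 4PL")
  }
  max_dose <- max(data$dose_nM)
  if (diff(range(data$response)) < flat_range) {
    return(new_fourpl_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                          converged = FALSE,
                          residual_sse = NA_real_, n = nrow(data),
                          max_dose_nM = max_dose, data = data))
  }
  # fitted on log(ec50) for conditioning via minpack.lm's raw
  # Levenberg-Marquardt optimizer; dose 0 is mapped to a large finite
  # negative log-dose so the Hill term underflows to exactly 0 and the
  # untreated level anchors `top` without log(0) in the residuals
  ldose <- ifelse(data$dose_nM == 0, min(log(nz)) - 1e4,
                  log(data$dose_nM))
  response <- data$response
  residual_fn <- function(p) {
    response - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
                  (1 + exp(p[["hill"]] * (ldose - p[["lec50"]]))))
  }
  starts <- list(
    c(bottom = max(min(response), 0), top = 100,
      lec50 = mean(log(nz)), hill = 1),
    c(bottom = 0, top = 100, lec50 = mean(log(nz)), hill = 1),
    c(bottom = 0, top = 100, lec50 = mean(log(nz)), hill = 2))
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, fn = residual_fn,
        lower = c(bottom = 0, top = 80, lec50 = log(max_dose * 1e-9),
                  hill = 1e-3),
        upper = c(bottom = 100, top = 120, lec50 = log(max_dose * 1e6),
                  hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4
    if (ok && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    return(new_fourpl_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                          converged = FALSE, residual_sse = NA_real_,
                          n = nrow(data), max_dose_nM = max_dose,
                          data = data))
  }
  p <- best$par
  new_fourpl_fit(unname(p[["bottom"]]), unname(p[["top"]]),
                 exp(unname(p[["lec50"]])), unname(p[["hill"]]),
                 converged = TRUE,
                 residual_sse = best$deviance,
                 n = nrow(data), max_dose_nM = max_dose, data = data)
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> not converged (flat or unidentifiable profile), n =",
        x$n, "\n")
  } else {
    cat(sprintf(
      "<fourpl_fit> bottom %.2f, top %.2f, EC50 %.4g nM, hill %.3f (SSE %.3g, n %d)\n",
      x$bottom, x$top, x$ec50_nM, x$hill, x$residual_sse, x$n))
  }
  invisible(x)
}

#' Predicted response of a fitted 4PL
#'
#' @param object A `fourpl_fit`.
#' @param dose_nM Doses (nM) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of responses (percent of untreated).
#' @export
predict.fourpl_fit <- function(object, dose_nM, ...) {
  if (!object$converged) abort("fit not converged")
  four_pl(dose_nM, object$bottom, object$top, object$ec50_nM, object$hill)
}

# dose of drug alone producing effect E (% of untreated); Inf when E is
# below the curve's floor, 0 when E is at/above the top
invert_effect <- function(fit, effect) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) abort("fit not converged")
  out <- numeric(length(effect))
  lo <- effect <= fit$bottom
  hi <- effect >= fit$top
  mid <- !lo & !hi
  out[lo] <- Inf
  out[hi] <- 0
  out[mid] <- fit$ec50_nM *
    ((fit$top - effect[mid]) / (effect[mid] - fit$bottom))^(1 / fit$hill)
  out
}

#' Invert a fitted dose-response curve to a GI_x dose
#'
#' Solves `y(d) = 100 - level` analytically for the 4PL. The estimate
#' is *undetermined* when the fitted curve cannot reach that
#' inhibition (`100 - bottom < level`, e.g. resistant models), when
#' the required inhibition is already exceeded at dose 0
#' (`100 - top > level`), or when the solution lies beyond the highest
#' tested dose (no extrapolation). Undetermined is a value (`NA` dose
#' with `determined = FALSE`), not an error, so screen tables can
#' carry it.
#'
#' @param fit A converged `fourpl_fit`.
#' @param level Growth-inhibition level(s) in percent (e.g. 10, 50).
#' @param max_tested_dose_nM Highest dose actually tested; defaults to
#'   the maximum dose in the fitted data.
#' @return A tibble with one row per level: `level`, `dose_nM`,
#'   `determined`, `within_tested_range`.
#' @export
#' @examples
#' fit <- fit_four_pl(tibble::tibble(
#'   dose_nM = c(0, 50, 150, 450, 1350, 4050),
#'   response = four_pl(c(0, 50, 150, 450, 1350, 4050), 0, 100, 450, 1)))
#' invert_gi(fit, c(10, 50))
invert_gi <- function(fit, level, max_tested_dose_nM = fit$max_dose_nM) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) abort("fit not converged")
  stopifnot(all(level > 0), all(level < 100))
  target <- 100 - level
  reachable <- target > fit$bottom & target < fit$top
  dose <- rep(NA_real_, length(level))
  dose[reachable] <- invert_effect(fit, target[reachable])
  in_range <- ifelse(reachable, dose <= max_tested_dose_nM, NA)
  determined <- reachable & !is.na(in_range) & in_range
  tibble(level = level,
         dose_nM = ifelse(determined, dose, NA_real_),
         determined = determined,
         within_tested_range = in_range)
}

#' Check that GI doses are ordered consistently with their levels
#'
#' For a decreasing curve, the dose producing x% inhibition must
#' strictly increase with x. Violations indicate an internal
#' inconsistency (they cannot arise from a valid 4PL inversion) and
#' raise an error.
#'
#' @inheritParams invert_gi
#' @param levels Inhibition levels in percent; all must be determined.
#' @return The [invert_gi()] tibble sorted by level.
#' @export
gi_ordering_check <- function(fit, levels,
                              max_tested_dose_nM = fit$max_dose_nM) {
  gi <- invert_gi(fit, sort(levels), max_tested_dose_nM)
  if (!all(gi$determined)) {
    abort("all levels must be determined for an ordering check")
  }
  if (any(diff(gi$dose_nM) <= 0)) {
    abort("internal-consistency error: GI doses not strictly increasing with level")
  }
  gi
}

#' @describeIn fit_four_pl Broom-style one-row-per-parameter summary.
#' @param x A `fourpl_fit`.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "ec50_nM", "hill"),
         estimate = c(x$bottom, x$top, x$ec50_nM, x$hill))
}

#' @describeIn fit_four_pl One-row model summary.
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_sse = x$residual_sse,
         n = x$n, max_dose_nM = x$max_dose_nM)
}
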