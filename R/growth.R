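# Proliferation kinetics: t = 0 normalization, log-phase doubling
# time, and area under the proliferation curve.

#' Normalize object counts to t = 0
#'
#' Divides each well's counts by its count at t = 0, the standard
#' proliferation-curve normalization for time-lapse object counts.
#' Adds a `value` column (1 at t = 0 by construction). Idempotent:
#' input that already carries `value` is returned unchanged.
#'
#' @param series Long time-course tibble with `time_h` and `count`
#'   (plus any label columns - `model_id`, `drug_id`, `dose_nM`,
#'   `treatment`, `well` - identifying individual wells).
#' @return The input with a `value` column of normalized counts.
#' @export
#' @examples
#' tc <- tibble::tibble(well = "A1", time_h = c(0, 24, 48),
#'                      count = c(200, 400, 800))
#' normalize_to_t0(tc)
normalize_to_t0 <- function(series) {
  if ("value" %in% names(series)) return(series)  # idempotent
  check_columns(series, c("time_h", "count"), "time course")
  keys <- tc_keys(series)
  out <- series |>
    group_by(across(all_of(keys))) |>
    mutate(.n0 = .data$count[.data$time_h == 0][1]) |>
    ungroup()
  if (any(is.na(out$.n0))) abort("every well needs a t = 0 observation")
  if (any(out$.n0 <= 0)) abort("cannot normalize: count at t = 0 is not positive")
  out |> mutate(value = .data$count / .data$.n0) |> select(-".n0")
}

# slope, intercept, r2 of y ~ x via closed-form least squares
ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  ss_res <- syy - slope * sxy
  # a zero-variance window carries no information; score it 0 so any
  # real trend outranks it (slope 0 then fails the growth check)
  r2 <- if (syy > 0) 1 - ss_res / syy else 0
  c(slope = slope, r2 = r2)
}

estimate_td_one <- function(time_h, value, min_span_h) {
  if (length(time_h) < 4L) abort("need at least 4 timepoints")
  if (any(value <= 0)) {
    # half-count floor so the log transform is defined; only here,
    # never in AUC computation
    floor_val <- min(value[value > 0]) / 2
    value <- pmax(value, floor_val)
  }
  y <- log2(value)
  n <- length(time_h)
  best <- NULL
  for (i in seq_len(n - 3L)) {
    for (j in seq(i + 3L, n)) {
      if (time_h[j] - time_h[i] < min_span_h) next
      f <- ls_line(time_h[i:j], y[i:j])
      cand <- c(f, start = i, end = j, span = time_h[j] - time_h[i])
      if (is.null(best)) { best <- cand; next }
      dr2 <- cand["r2"] - best["r2"]
      better <- dr2 > 1e-9 ||
        (abs(dr2) <= 1e-9 && (cand["span"] > best["span"] + 1e-12 ||
           (abs(cand["span"] - best["span"]) <= 1e-12 &&
              cand["start"] < best["start"])))
      if (better) best <- cand
    }
  }
  if (is.null(best)) abort("no contiguous window reaches the minimum span")
  if (best[["slope"]] <= 0) abort("no growth detected (non-positive log-phase slope)")
  tibble(doubling_time_h = 1 / best[["slope"]],
         window_start_h = time_h[best[["start"]]],
         window_end_h = time_h[best[["end"]]],
         fit_r2 = best[["r2"]],
         n_points = best[["end"]] - best[["start"]] + 1)
}

#' Estimate culture doubling time from the log phase
#'
#' Transforms normalized counts to log2 and fits a least-squares line
#' over the contiguous time window (span >= `min_span_h`) that
#' maximizes r-squared - the automatic reading of "the log-phase
#' portion of the graph". Doubling time is the inverse gradient.
#' Ties in r-squared (e.g. a noiseless exponential, where every
#' window is perfectly linear) go to the longest window, then the
#' earliest start, so exact exponentials are estimated over the full
#' range and exactly.
#'
#' @param series Normalized time-course tibble (see
#'   [normalize_to_t0()]); one or more wells.
#' @param min_span_h Minimum window span in hours (default 24,
#'   matching daily culture dynamics).
#' @return A tibble with one row per well: `doubling_time_h`, the
#'   window (`window_start_h`, `window_end_h`), `fit_r2`, `n_points`.
#' @export
#' @examples
#' tc <- simulate_growth_curve(growth_model_spec(28), noise_sd = 0)
#' estimate_doubling_time(normalize_to_t0(tc))
estimate_doubling_time <- function(series, min_span_h = 24) {
  check_columns(series, c("time_h", "value"),
                "normalized time course (run normalize_to_t0 first?)")
  keys <- tc_keys(series)
  series |>
    group_by(across(all_of(keys))) |>
    arrange(.data$time_h, .by_group = TRUE) |>
    group_modify(~ estimate_td_one(.x$time_h, .x$value, min_span_h)) |>
    ungroup()
}

#' Area under the normalized proliferation curve
#'
#' Trapezoidal integral of the normalized value over \[0, `t_end_h`\]
#' on the observed grid (no smoothing; a `t_end_h` between grid points
#' is handled by linear interpolation of the final segment). No
#' extrapolation: `t_end_h` beyond the last timepoint is an error.
#'
#' @param series Normalized time-course tibble; one or more wells.
#' @param t_end_h Upper limit of integration in hours (default 96).
#' @return A tibble with one row per well and an `auc` column
#'   (unitless x hours).
#' @export
#' @examples
#' tc <- tibble::tibble(well = "A1", time_h = c(0, 48, 96),
#'                      count = c(1, 1.5, 2), value = c(1, 1.5, 2))
#' area_under_curve(tc)  # linear 1 -> 2 over 96 h: 144
area_under_curve <- function(series, t_end_h = 96) {
  check_columns(series, c("time_h", "value"),
                "normalized time course (run normalize_to_t0 first?)")
  keys <- tc_keys(series)
  auc_one <- function(t, v) {
    if (t_end_h > max(t) + 1e-9) {
      abort("t_end_h beyond the last timepoint; no extrapolation")
    }
    keep <- t <= t_end_h + 1e-9
    t2 <- t[keep]; v2 <- v[keep]
    if (max(t2) < t_end_h - 1e-9) {
      v_end <- stats::approx(t, v, xout = t_end_h)$y
      t2 <- c(t2, t_end_h); v2 <- c(v2, v_end)
    }
    tibble(auc = trapz(t2, v2))
  }
  series |>
    group_by(across(all_of(keys))) |>
    arrange(.data$time_h, .by_group = TRUE) |>
    group_modify(~ auc_one(.x$time_h, .x$value)) |>
    ungroup()
}
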