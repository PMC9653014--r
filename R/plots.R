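# ggplot2 displays for the main result types.

#' Plot proliferation curves
#'
#' Normalized object count over time, one line per well, coloured by
#' treatment (or dose when present).
#'
#' @param series Normalized long time-course tibble.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(series) {
  check_columns(series, c("time_h", "value"), "normalized time course")
  colour_var <- if ("dose_nM" %in% names(series)) "dose_nM" else "treatment"
  keys <- tc_keys(series)
  series <- series |>
    mutate(.well_key = interaction(!!!rlang::syms(keys), drop = TRUE))
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               group = .data$.well_key,
                               colour = factor(.data[[colour_var]]))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "normalized object count",
                  colour = colour_var) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_four_pl Dose-response curve with the fitted 4PL;
#'   zero doses are drawn at a pseudo-log position.
#' @param object A `fourpl_fit`.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  if (is.null(object$data)) abort("fit carries no data to plot")
  d <- object$data
  nz <- d$dose_nM[d$dose_nM > 0]
  pseudo0 <- min(nz) / 10
  d$dose_plot <- ifelse(d$dose_nM == 0, pseudo0, d$dose_nM)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_plot,
                                       y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM, log scale)",
                  y = "response (% of untreated AUC)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(dose_plot = exp(seq(log(pseudo0), log(max(nz)),
                                       length.out = 200)))
    grid$response <- predict(object, grid$dose_plot)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' @describeIn synergy_matrix Heatmap of per-cell synergy scores
#'   (blue = antagonism, red = synergy), margins omitted.
#' @param object A `synergy_surface`.
#' @export
autoplot.synergy_surface <- function(object, ...) {
  interior <- as_tibble(object) |>
    filter(.data$dose_a_nM > 0, .data$dose_b_nM > 0)
  ggplot2::ggplot(interior,
                  ggplot2::aes(x = factor(round(.data$dose_a_nM, 1)),
                               y = factor(round(.data$dose_b_nM, 1)),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$score, 1)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = paste(attr(object, "drug_a"), "(nM)"),
                  y = paste(attr(object, "drug_b"), "(nM)"),
                  fill = "synergy\n(% points)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a model x regimen screen matrix
#'
#' @param matrix A [screen_matrix()].
#' @return A ggplot.
#' @export
plot_screen_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "screen_matrix"))
  ggplot2::ggplot(as_tibble(matrix),
                  ggplot2::aes(x = .data$regimen, y = .data$model_id,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkblue", high = "white",
                                 limits = c(0, 100), oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "% of\nuntreated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# minimal squish so we avoid a scales dependency
scales_squish <- function(x, range = c(0, 100)) {
  pmin(pmax(x, range[1]), range[2])
}
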