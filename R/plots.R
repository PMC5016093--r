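#' Plot log-unit gaps of a verdict table
#'
#' Horizontal bars of the signed log-unit gap for each (scenario, quantity)
#' pair; bars to the right of zero are shortfalls. Infinite gaps (zero
#' drive) are dropped.
#'
#' @param object an `mg_verdicts` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mg_verdicts
#' @export
autoplot.mg_verdicts <- function(object, ...) {
  df <- as_tibble(as.data.frame(object)) |>
    filter(is.finite(.data$log_unit_gap))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log_unit_gap,
    y = stats::reorder(.data$quantity, .data$log_unit_gap),
    fill = .data$headline
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$scenario),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(
      x = "log-unit gap to threshold (positive = shortfall)",
      y = NULL, fill = "headline"
    ) +
    ggplot2::theme_minimal()
}

#' Plot computed versus published values of the reproduction table
#'
#' Log-log scatter of recomputed (displayed-precision) values against the
#' published numbers; points on the diagonal reproduce the publication.
#' Flagged points mark published values inconsistent with their own stated
#' formulas.
#'
#' @param object an `mg_reproduction` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mg_reproduction
#' @export
autoplot.mg_reproduction <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$printed, y = .data$displayed,
    colour = .data$flagged, shape = .data$tier
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "published value", y = "recomputed value (displayed precision)",
      colour = "flagged", shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.mg_verdicts <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.mg_reproduction <- function(x, ...) print(autoplot(x, ...))
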