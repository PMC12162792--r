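#' Plot a TSS-anchored methylation metaplot
#'
#' @param x A [metaplot()] tibble.
#' @param smooth Draw the smoothed curve (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_metaplot <- function(x, smooth = TRUE) {
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$bin_mid, y = .data$meth_pct)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "methylation (%)") +
    ggplot2::theme_minimal()
  if (smooth && "meth_pct_smooth" %in% names(x)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$meth_pct_smooth),
                                colour = "steelblue", linewidth = 0.9)
  }
  p
}

#' Plot positional profiles of significant windows
#'
#' Stacked-area rendering of [positional_dmr_profile()] tables, optionally
#' faceted over comparisons if the input carries a `comparison` column.
#'
#' @param x A positional profile tibble (optionally row-bound across
#'   comparisons with a `comparison` column).
#' @return A ggplot object.
#' @export
plot_positional_profile <- function(x) {
  d <- tidyr::pivot_longer(
    x, c("n_hypo", "n_hyper"),
    names_to = "direction", values_to = "count"
  ) |>
    mutate(direction = sub("^n_", "", .data$direction))
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$rel_start, y = .data$count, fill = .data$direction
  )) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "window start relative to TSS (bp)",
                  y = "significant windows") +
    ggplot2::theme_minimal()
  if ("comparison" %in% names(x)) {
    p <- p + ggplot2::facet_wrap(~comparison)
  }
  p
}

#' @describeIn static_association ggplot of the binned gene density with
#'   the fitted regression line.
#' @param object A `meth_expr_fit` object.
#' @param ... Unused.
#' @export
autoplot.meth_expr_fit <- function(object, ...) {
  d <- object$data
  co <- coef(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[object$meth_col]], y = .data[[object$expr_col]]
  )) +
    ggplot2::geom_bin2d(bins = 40) +
    ggplot2::geom_abline(intercept = co[1], slope = co[2],
                         colour = "white", linewidth = 0.9) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "promoter methylation (%)", y = "log2 CPM") +
    ggplot2::theme_minimal()
}

#' Plot window-wise association significance
#'
#' Tile plot of [delta_association()] results: window position against
#' comparison, coloured by direction, alpha by significance tier.
#'
#' @param x A [delta_association()] tibble, optionally row-bound across
#'   comparisons with a `comparison` column.
#' @return A ggplot object.
#' @export
plot_window_associations <- function(x) {
  if (!"comparison" %in% names(x)) x$comparison <- "comparison"
  d <- filter(x, .data$tier != "ns")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$rel_start, y = .data$comparison,
    fill = .data$direction, alpha = .data$tier
  )) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_alpha_manual(
      values = c("p<0.001" = 1, "p<0.01" = 0.7, "p<0.05" = 0.4)
    ) +
    ggplot2::labs(x = "window start relative to TSS (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
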