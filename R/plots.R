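# Optional ggplot2 renderings of the standard result surfaces.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("plotting requires the ggplot2 package")
  }
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceac_table a [ceac()] table.
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  need_ggplot()
  ggplot2::ggplot(
    ceac_table,
    ggplot2::aes(x = threshold, y = probability,
                 colour = strategy)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD per effect unit)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram from a one-way sensitivity analysis
#'
#' @param owsa an [run_owsa()] result.
#' @param top show only the `top` largest swings (default all).
#' @return a ggplot object.
#' @export
plot_tornado <- function(owsa, top = nrow(owsa)) {
  need_ggplot()
  df <- utils::head(owsa[order(-owsa$swing), ], top)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = outcome_low, xend = outcome_high,
                   y = label, yend = label),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(
      ggplot2::aes(xintercept = outcome_base), linetype = 2
    ) +
    ggplot2::labs(x = "Outcome at range ends", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane
#'
#' @param plane a [ce_plane()] table.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(plane) {
  need_ggplot()
  ggplot2::ggplot(
    plane, ggplot2::aes(x = inc_effect, y = inc_cost,
                        colour = strategy)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Incremental effect vs anchor",
                  y = "Incremental cost vs anchor (USD)", colour = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("threshold", "probability", "strategy",
  "outcome_low", "outcome_high", "label", "outcome_base", "inc_effect",
  "inc_cost"))
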