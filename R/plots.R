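# Quick-look plotting helpers for traces and populations.

#' Plot fluorescence traces
#'
#' One line per cell; optionally restricted to a few cells.
#'
#' @param traces Long trace tibble.
#' @param cells Optional character vector of cell ids to show.
#' @param max_cells Cap on the number of cells drawn.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, cells = NULL, max_cells = 12) {
  if (!is.null(cells)) {
    traces <- filter(traces, .data$cell_id %in% cells)
  } else {
    keep <- utils::head(unique(traces$cell_id), max_cells)
    traces <- filter(traces, .data$cell_id %in% keep)
  }
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s,
                                       y = .data$fluorescence,
                                       colour = .data$cell_id)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell chloride estimates
#'
#' Marks the population mean and, when a context is given, the critical
#' concentration for efflux.
#'
#' @param estimates Tibble from [estimate_cl()] (or any tibble with a
#'   `cl_i_mM` column).
#' @param ctx Optional [equilibrium_context()] whose critical concentration
#'   is drawn as a dashed line.
#' @param binwidth Histogram bin width (mM).
#' @return A ggplot object.
#' @export
plot_population <- function(estimates, ctx = NULL, binwidth = 5) {
  p <- ggplot2::ggplot(estimates, ggplot2::aes(x = .data$cl_i_mM)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = base::mean(estimates$cl_i_mM),
                        colour = "steelblue") +
    ggplot2::labs(x = "[Cl-]i (mM)", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.null(ctx)) {
    p <- p + ggplot2::geom_vline(xintercept = critical_cli(ctx),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
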