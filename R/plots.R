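#' Plot evoked sweeps of one cell
#'
#' Overlays a cell's evoked sweeps, one panel per temperature.
#'
#' @param sweeps sweep tibble.
#' @param cell cell id to plot (default: first).
#' @param max_sweeps sweeps per temperature to draw.
#' @return a ggplot.
#' @export
plot_sweeps <- function(sweeps, cell = NULL, max_sweeps = 3) {
  ev <- dplyr::filter(sweeps, .data$protocol == "evoked")
  if (is.null(cell)) cell <- ev$cell_id[1]
  ev <- dplyr::filter(ev, .data$cell_id == cell,
                      .data$sweep_index <= max_sweeps)
  long <- ev |>
    dplyr::mutate(trace = purrr::map2(.data$vm, .data$sampling_rate, function(v, fs)
      tibble::tibble(time_ms = (seq_along(v) - 1) / fs * 1000, vm = v))) |>
    dplyr::select("temperature", "sweep_index", "trace") |>
    tidyr::unnest("trace")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$vm,
                                     group = .data$sweep_index)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::facet_wrap(~temperature, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ms)", y = "Vm (mV)", title = cell) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.unit_classification <- function(object, ...) {
  ggplot2::ggplot(object$units, ggplot2::aes(.data$duration_ms,
                                             fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$boundary_ms, linetype = 2) +
    ggplot2::labs(x = "trough-to-peak duration (ms)", y = "units",
                  subtitle = sprintf("dip = %.3f, p = %.3g; boundary %.2f ms",
                                     object$dip$statistic, object$dip$p_value,
                                     object$boundary_ms)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fate_table <- function(object, ...) {
  ggplot2::ggplot(object$cohort,
                  ggplot2::aes(.data$fate, .data$percent)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of cells",
                  subtitle = sprintf("n = %d cells", object$n_cells)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tb_series <- function(object, fever_threshold = 38, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s / 3600, .data$tb_c)) +
    ggplot2::geom_hline(yintercept = fever_threshold, linetype = 2,
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "body temperature (°C)") +
    ggplot2::theme_minimal()
}
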