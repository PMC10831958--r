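#' QC plots
#'
#' Each pipeline stage can emit a diagnostic figure: signal traces with
#' detected triggers, the trigger raster in space-time, per-wave delay maps
#' with flow arrows, and the final measure distributions. All plots are
#' ggplot objects and can be restyled downstream.
#'
#' @name qc_plots
NULL

#' @describeIn qc_plots signal traces for a subset of channels, with
#'   triggers overlaid if supplied.
#' @param rec a [grid_recording()].
#' @param ts optional trigger tibble.
#' @param channels channel indices to draw.
#' @export
plot_traces <- function(rec, ts = NULL, channels = NULL) {
  if (is.null(channels)) {
    channels <- utils::head(which(rec$channel_mask), 6)
  }
  df <- as_tibble.grid_recording(rec) |>
    dplyr::filter(.data$channel %in% channels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = rec$units)
  if (!is.null(ts) && nrow(ts)) {
    tr <- dplyr::filter(ts, .data$channel %in% channels, .data$state == "up")
    p <- p + ggplot2::geom_vline(data = tr,
                                 ggplot2::aes(xintercept = .data$time),
                                 color = "red", linewidth = 0.25)
  }
  p
}

#' @describeIn qc_plots trigger raster: trigger times per channel, colored
#'   by wave when the input is a clustered wave tibble.
#' @export
plot_trigger_raster <- function(ts) {
  aes <- if ("wave" %in% names(ts)) {
    ggplot2::aes(.data$time, .data$channel,
                 color = factor(.data$wave))
  } else {
    ggplot2::aes(.data$time, .data$channel)
  }
  ggplot2::ggplot(dplyr::filter(ts, .data$state == "up"), aes) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "time (s)", y = "channel", color = "wave")
}

#' @describeIn qc_plots delay-map heatmap of one wave, with optional
#'   optical-flow arrows at the trigger sites.
#' @param dm a `wave_delay_map`.
#' @param ws_flow optional wave tibble carrying `flow_u`, `flow_v`.
#' @export
plot_delay_map <- function(dm, ws_flow = NULL) {
  df <- tidy.wave_delay_map(dm)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$delay)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "delay (s)", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("wave", dm$wave_id))
  if (!is.null(ws_flow) && all(c("flow_u", "flow_v") %in% names(ws_flow))) {
    arr <- dplyr::filter(ws_flow, .data$wave == dm$wave_id)
    sc <- 0.4 / max(arr$flow_mag, na.rm = TRUE)
    p <- p + ggplot2::geom_segment(
      data = arr, inherit.aes = FALSE,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + .data$flow_u * sc,
                   yend = .data$y + .data$flow_v * sc),
      arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
      linewidth = 0.2
    )
  }
  p
}

#' @describeIn qc_plots measure distributions of a characterization table.
#' @param tab a `characterization_table`.
#' @export
plot_measures <- function(tab) {
  keep <- intersect(c("velocity", "direction", "planarity",
                      "interwave_interval"), names(tab))
  df <- tidyr::pivot_longer(tibble::as_tibble(tab)[keep],
                            dplyr::all_of(keep),
                            names_to = "measure", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free") +
    ggplot2::labs(x = NULL, y = "density")
}

#' @exportS3Method ggplot2::autoplot
autoplot.grid_recording <- function(object, ...) plot_traces(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.trigger_set <- function(object, ...) plot_trigger_raster(object)

#' @exportS3Method ggplot2::autoplot
autoplot.wave_set <- function(object, ...) plot_trigger_raster(object)

#' @exportS3Method ggplot2::autoplot
autoplot.wave_delay_map <- function(object, ...) plot_delay_map(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.characterization_table <- function(object, ...) plot_measures(object)
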