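# ggplot2 views of the main result types.

#' Plot per-class detection metrics
#'
#' Bar chart of precision, recall and F1 per scored class, with the macro
#' average as a dashed reference line on the F1 facet.
#'
#' @param metrics A `metrics_tbl` from [compute_metrics()] (or a `box_eval`).
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  if (inherits(metrics, "box_eval")) metrics <- metrics$metrics
  per <- dplyr::filter(as_tibble(metrics), .data$class != "macro")
  macro <- dplyr::filter(as_tibble(metrics), .data$class == "macro")
  long <- tidyr::pivot_longer(per, c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ref <- tidyr::pivot_longer(macro, c("precision", "recall", "f1"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-class detection metrics (dashed: macro average)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Autoplot method for detection evaluations
#'
#' @param object A `box_eval`.
#' @param ... Unused.
#' @return A ggplot object (see [plot_metrics()]).
#' @importFrom ggplot2 autoplot
#' @method autoplot box_eval
#' @export
autoplot.box_eval <- function(object, ...) plot_metrics(object)

#' Plot per-individual SNR distributions
#'
#' Boxplots (quartiles, whiskers at 1.5 IQR) of per-call SNR grouped by
#' individual.
#'
#' @param records SNR tibble from [estimate_snr()] with `individual_id`.
#' @return A ggplot object.
#' @export
plot_snr_distribution <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$individual_id, y = .data$snr_db)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = "individual", y = "SNR (dB)",
                  title = "Per-call signal-to-noise ratio by individual") +
    ggplot2::theme_minimal()
}

#' Plot normalized amplitude density curves
#'
#' @param density_tbl Tibble from [amplitude_density()].
#' @return A ggplot object.
#' @export
plot_amplitude_density <- function(density_tbl) {
  ggplot2::ggplot(density_tbl,
                  ggplot2::aes(x = .data$level_dbfs, y = .data$density,
                               colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "call level (dBFS)", y = "density", colour = NULL,
                  title = "Call amplitude distributions (area-normalized)") +
    ggplot2::theme_minimal()
}

#' Plot an acceleration decomposition
#'
#' Raw, static and dynamic z-acceleration over time, with detected banking
#' peaks marked when a `dive_test` is supplied.
#'
#' @param accel An [accel_table()].
#' @param cfg A [motion_config()].
#' @param dive_test Optional `dive_test` whose peaks to overlay.
#' @return A ggplot object.
#' @export
plot_accel_decomposition <- function(accel, cfg = motion_config(),
                                     dive_test = NULL) {
  parts <- decompose_static_dynamic(accel, cfg)
  long <- dplyr::bind_rows(
    tibble(t = accel$t, value = accel$az, component = "raw"),
    tibble(t = accel$t, value = parts$static$az, component = "static"),
    tibble(t = accel$t, value = parts$dynamic$az, component = "dynamic")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "z-acceleration (g)",
                  title = "Static/dynamic decomposition (zero-delay 3 Hz high-pass)") +
    ggplot2::theme_minimal()
  if (!is.null(dive_test)) {
    pk <- tibble(t = unlist(dive_test$segments$peak_times_s),
                 component = "static")
    if (nrow(pk) > 0) {
      p <- p + ggplot2::geom_vline(data = pk,
                                   ggplot2::aes(xintercept = .data$t),
                                   colour = "red", linetype = "dotted")
    }
  }
  p
}

#' Plot an acceleration spectrogram
#'
#' @param spec Result of [accel_spectrogram()].
#' @return A ggplot object.
#' @export
plot_accel_spectrogram <- function(spec) {
  df <- expand.grid(freq_hz = spec$freq_hz, time_s = spec$time_s)
  df$magnitude <- as.vector(spec$magnitude)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = log10(.data$magnitude + 1e-9))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 |STFT|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = "z-acceleration spectrogram") +
    ggplot2::theme_minimal()
}
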