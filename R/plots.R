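#' Plot a hypnogram
#'
#' Classic stage-by-time staircase with arousal and artifact annotations as
#' rug marks.
#'
#' @param hypnogram A [hypnogram()].
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(hypnogram) {
  h <- as_tibble(hypnogram) |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("N3", "N2", "N1", "R", "W")))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$onset_s / 60,
                                       y = .data$stage, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (min)", y = NULL)
  if (nrow(hypnogram$arousals) > 0) {
    p <- p + ggplot2::geom_rug(
      data = hypnogram$arousals,
      ggplot2::aes(x = .data$onset_s / 60), inherit.aes = FALSE,
      sides = "t", colour = "red")
  }
  if (nrow(hypnogram$artifacts) > 0) {
    p <- p + ggplot2::geom_rug(
      data = hypnogram$artifacts,
      ggplot2::aes(x = .data$onset_s / 60), inherit.aes = FALSE,
      sides = "b", colour = "grey40")
  }
  p
}

#' @export
autoplot.remstim_erp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean_uv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Time from click (s)", y = "Amplitude (µV)")
}

#' @export
autoplot.remstim_ersp <- function(object, channel = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channel)) {
    df <- dplyr::filter(df, .data$channel %in% !!channel)
  } else {
    df <- df |>
      dplyr::group_by(.data$freq_hz, .data$time_s) |>
      dplyr::summarise(db = mean(.data$db), .groups = "drop") |>
      dplyr::mutate(channel = "all channels")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Time from click (s)", y = "Frequency (Hz)",
                  fill = "dB")
}

#' Scalp map of electrode-wise regression results
#'
#' Top-view electrode positions with FDR-surviving electrodes highlighted.
#'
#' @param x An `electrode_regressions` object.
#' @param montage Montage tibble (see [montage_1020()]).
#' @return A ggplot object.
#' @export
plot_electrode_map <- function(x, montage = montage_1020()) {
  df <- dplyr::left_join(x$by_electrode, montage,
                         by = c(channel = "label"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$slope,
                                     shape = .data$p_fdr_significant),
                        size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), vjust = -1.2,
                       size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80",
                                    high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "slope (%/dB)", shape = "FDR significant")
}
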