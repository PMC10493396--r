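# ggplot2 views of the main result types.

#' Plot an ISKNA series with detected bursts and event markers
#'
#' @param iskna Tibble from [integrate_skna()].
#' @param bursts Optional burst tibble from [detect_bursts()].
#' @param markers Optional vector of CRD marker times (s).
#' @return A ggplot object.
#' @export
plot_iskna <- function(iskna, bursts = NULL, markers = NULL) {
  p <- ggplot2::ggplot(iskna, ggplot2::aes(.data$t, .data$iskna)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "ISKNA (µV·s)")
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts, inherit.aes = FALSE, alpha = 0.2, fill = "firebrick",
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf))
  }
  if (!is.null(markers) && length(markers)) {
    p <- p + ggplot2::geom_vline(xintercept = markers, linetype = "dashed")
  }
  p
}

#' Plot a power spectrum with the VLF/LF/HF band edges
#'
#' @param psd Tibble `freq`/`power` from [lomb_psd()].
#' @param bands A [rat_bands()] definition drawn as shaded regions.
#' @return A ggplot object.
#' @export
plot_psd <- function(psd, bands = rat_bands()) {
  shade <- tibble(
    band = factor(c("VLF", "LF", "HF"), levels = c("VLF", "LF", "HF")),
    xmin = c(bands$vlf[1], bands$lf[1], bands$hf[1]),
    xmax = c(bands$vlf[2], bands$lf[2], bands$hf[2]))
  ggplot2::ggplot(psd, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_rect(data = shade, inherit.aes = FALSE, alpha = 0.15,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power", fill = NULL)
}

#' Plot a spectrogram
#'
#' @param spec A `spectrogram_result` from [fft_spectrogram()].
#' @param log_power Show `log10` power (default TRUE).
#' @return A ggplot object.
#' @export
plot_spectrogram <- function(spec, log_power = TRUE) {
  d <- as_tibble(spec)
  if (log_power) d$power <- log10(d$power + .Machine$double.eps)
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$freq, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (log_power) "log10 power" else "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Plot per-feature onset delays for the detected events
#'
#' @param analysis An `ad_analysis` (or a tidied delay tibble).
#' @return A ggplot object.
#' @export
plot_delays <- function(analysis) {
  d <- if (inherits(analysis, "ad_analysis")) tidy(analysis) else analysis
  ggplot2::ggplot(d[is.finite(d$delay), ],
                  ggplot2::aes(.data$feature, .data$delay)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~event, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "onset delay after CRD (s)")
}
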