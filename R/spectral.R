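# Frequency-domain analysis: classic Lomb-Scargle periodogram of the NN
# tachogram (valid for the unevenly spaced beat times), VLF/LF/HF band
# powers in the rat-specific bands, Welch-style FFT spectrograms, and
# dominant-frequency extraction.

#' Rat VLF/LF/HF band definition
#'
#' The rat HRV bands: VLF 0-0.2 Hz, LF 0.2-0.75 Hz, HF 0.75-2.5 Hz —
#' contiguous, non-overlapping and increasing. (Human bands differ: LF
#' 0.04-0.15 Hz, HF 0.15-0.40 Hz.)
#'
#' @param vlf,lf,hf Two-element Hz vectors.
#' @param species_label Free-text label.
#' @return A list of class `band_definition`.
#' @export
rat_bands <- function(vlf = c(0, 0.2), lf = c(0.2, 0.75), hf = c(0.75, 2.5),
                      species_label = "rat") {
  edges <- c(vlf, lf, hf)
  if (is.unsorted(c(vlf[2], lf[1])) || vlf[2] != lf[1] || lf[2] != hf[1] ||
      any(diff(edges[c(1, 2, 4, 6)]) <= 0)) {
    abort("bands must be contiguous, non-overlapping and increasing")
  }
  structure(list(vlf = vlf, lf = lf, hf = hf, species_label = species_label),
            class = "band_definition")
}

#' Lomb-Scargle periodogram of an NN series
#'
#' Classic least-squares Lomb periodogram evaluated on a frequency grid,
#' after linear detrending against the beat times and (by default) a Hann
#' data window. For uniformly sampled data the result matches the standard
#' FFT periodogram `|X(f)|^2 / N`.
#'
#' @param nn Tibble with `t` (s) and `nn` (ms) — e.g. from
#'   [rr_intervals()]; rejected (`valid == FALSE`) intervals are dropped.
#' @param freq_grid Evaluation frequencies, Hz; default 0.002-2.5 Hz in
#'   0.002 Hz steps (resolves the 0-0.2 Hz VLF band).
#' @param detrend Remove a least-squares linear trend first (default TRUE).
#' @param window `"hann"` or `"none"`.
#' @return Tibble `freq` (Hz) and `power` (ms^2 per grid bin scale).
#' @export
lomb_psd <- function(nn, freq_grid = seq(0.002, 2.5, by = 0.002),
                     detrend = TRUE, window = c("hann", "none")) {
  window <- match.arg(window)
  if ("valid" %in% names(nn)) nn <- nn[nn$valid, ]
  t <- nn$t
  x <- nn$nn
  if (length(x) < 8) abort("need at least 8 intervals for a periodogram")
  if (detrend) x <- stats::resid(stats::lm(x ~ t))
  if (window == "hann") {
    u <- (t - min(t)) / (max(t) - min(t))
    w <- 0.5 - 0.5 * cos(2 * pi * u)
    x <- x * w / sqrt(mean(w^2)) # preserve total power on average
  }
  if (var(x) < .Machine$double.eps) {
    abort("series has zero variance after detrending")
  }
  x <- x - mean(x)
  n <- length(x)
  power <- vapply(freq_grid, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  tibble(freq = freq_grid, power = power)
}

#' VLF/LF/HF band powers from a power spectrum
#'
#' Absolute band powers are trapezoidal integrals of the PSD over each
#' band; percentages are taken over the VLF+LF+HF total, so they sum to
#' 100 exactly; `lf_hf_ratio` is the ratio of the absolute LF and HF
#' powers (reported `NA` when HF power is zero).
#'
#' @param psd Tibble `freq`/`power` (e.g. from [lomb_psd()]).
#' @param bands A [rat_bands()] definition.
#' @param segment Optional `c(start, end)` seconds, echoed in the output.
#' @param condition_label Optional label (e.g. `"baseline"`, `"AD"`).
#' @return One-row tibble: `vlf_pct`, `lf_pct`, `hf_pct`, `lf_hf_ratio`,
#'   `vlf_abs`, `lf_abs`, `hf_abs`, `total_power`, `condition`.
#' @export
band_powers <- function(psd, bands = rat_bands(), segment = NULL,
                        condition_label = NA_character_) {
  if (max(psd$freq) < bands$hf[2] - 1e-9) {
    abort("PSD does not cover the HF band")
  }
  bp <- function(b) {
    keep <- psd$freq >= b[1] - 1e-12 & psd$freq <= b[2] + 1e-12
    if (sum(keep) < 2) return(0)
    pracma::trapz(psd$freq[keep], psd$power[keep])
  }
  vlf <- bp(bands$vlf); lf <- bp(bands$lf); hf <- bp(bands$hf)
  tot <- vlf + lf + hf
  if (tot <= 0) abort("zero total band power")
  tibble(
    vlf_pct = 100 * vlf / tot, lf_pct = 100 * lf / tot,
    hf_pct = 100 * hf / tot,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
    vlf_abs = vlf, lf_abs = lf, hf_abs = hf, total_power = tot,
    segment_start = if (is.null(segment)) NA_real_ else segment[1],
    segment_end = if (is.null(segment)) NA_real_ else segment[2],
    condition = condition_label
  )
}

#' Welch-style FFT spectrogram
#'
#' Hann-windowed overlapping FFT segments (defaults: 128000-point FFT with
#' 93.75% overlap, i.e. a hop of nfft/16), one-sided power, restricted to
#' the requested frequency range (default 0-10 Hz, the range of interest
#' for SKNA-envelope and ISKNA rhythms).
#'
#' @param sig Tibble `t`/`value` or numeric vector.
#' @param fs Sampling rate, Hz.
#' @param nfft Segment/FFT length, samples.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param range Two-element Hz vector to retain.
#' @param demean Subtract each segment's mean before windowing (default
#'   TRUE); without it the DC pedestal of non-negative signals such as
#'   ISKNA leaks into the lowest bins and masks slow rhythms.
#' @return A list of class `spectrogram_result`: `times` (segment centers,
#'   s), `freqs` (Hz), `power` (freq x time matrix), `nfft`, `overlap`.
#' @export
fft_spectrogram <- function(sig, fs = NULL, nfft = 128000, overlap = 0.9375,
                            range = c(0, 10), demean = TRUE) {
  x <- as_signal(sig, fs)
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  if (length(x$values) < nfft) {
    abort(sprintf(paste("signal (%d samples) is shorter than nfft (%d);",
                        "zero-pad the signal or choose a smaller nfft"),
                  length(x$values), nfft))
  }
  if (x$fs < 2 * range[2]) abort("fs must be at least twice the range maximum")
  hop <- round(nfft * (1 - overlap))
  if (hop < 1) abort("overlap leaves an empty hop")
  v <- x$values
  starts <- seq(1L, length(v) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft) # periodic Hann
  freqs <- (0:(nfft %/% 2)) * x$fs / nfft
  keep <- freqs >= range[1] & freqs <= range[2]
  scale <- x$fs * sum(w^2) # one-sided PSD normalization
  power <- vapply(starts, function(s) {
    seg <- v[s:(s + nfft - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)
    p <- Mod(X[1:(nfft %/% 2 + 1L)])^2 / scale
    p[-c(1L, length(p))] <- 2 * p[-c(1L, length(p))]
    p[keep]
  }, numeric(sum(keep)))
  structure(list(times = (starts - 1L + nfft / 2) / x$fs, freqs = freqs[keep],
                 power = matrix(power, nrow = sum(keep)),
                 nfft = nfft, overlap = overlap, fs = x$fs),
            class = "spectrogram_result")
}

#' @export
print.spectrogram_result <- function(x, ...) {
  cat(sprintf("<spectrogram_result> %d freqs x %d segments, nfft=%d, overlap=%.4f\n",
              length(x$freqs), length(x$times), x$nfft, x$overlap))
  invisible(x)
}

#' Tidy a spectrogram into a long tibble
#'
#' @param x A `spectrogram_result`.
#' @param ... Unused.
#' @return Tibble `t`, `freq`, `power`.
#' @export
as_tibble.spectrogram_result <- function(x, ...) {
  tidyr::expand_grid(ti = seq_along(x$times), fi = seq_along(x$freqs)) %>%
    mutate(t = x$times[.data$ti], freq = x$freqs[.data$fi],
           power = x$power[cbind(.data$fi, .data$ti)]) %>%
    select("t", "freq", "power")
}

#' Dominant frequency of a spectrum or spectrogram
#'
#' Frequency of maximum power. For a spectrogram the powers are first
#' averaged over segments. With `exclude_dc`, bins below one frequency
#' resolution step are ignored. Ties resolve to the lowest frequency.
#'
#' @param spec A tibble `freq`/`power` or a `spectrogram_result`.
#' @param exclude_dc Drop the near-zero-frequency bins first.
#' @return One-row tibble `freq` (Hz) and `power`.
#' @export
dominant_frequency <- function(spec, exclude_dc = FALSE) {
  if (inherits(spec, "spectrogram_result")) {
    freqs <- spec$freqs
    power <- rowMeans(spec$power)
  } else {
    freqs <- spec$freq
    power <- spec$power
  }
  if (!length(freqs) || all(power == 0)) abort("spectrum is empty or all zero")
  if (exclude_dc) {
    res <- if (length(freqs) > 1) min(diff(freqs)) else 0
    keep <- freqs >= res
    freqs <- freqs[keep]
    power <- power[keep]
  }
  i <- which(power == max(power))[1] # ties -> lowest frequency
  tibble(freq = freqs[i], power = power[i])
}
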