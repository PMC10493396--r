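# Dual-threshold SKNA burst detection: band-limit to 500-995 Hz, take the
# analytic-signal amplitude, normalize by the series mean, then walk a high
# onset threshold / low termination threshold over the envelope.

# analytic signal via the frequency-domain construction; returns |analytic|
analytic_amplitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Mean-normalized SKNA amplitude envelope
#'
#' Band-passes the signal to the SKNA carrier band (default 500-995 Hz),
#' computes the instantaneous amplitude as the magnitude of the analytic
#' signal, smooths it with a short moving average, and divides by the mean
#' of the whole series so the output has mean exactly 1. Normalizing by the
#' series mean makes burst detection invariant to uniform amplitude scaling
#' of the raw signal.
#'
#' @param sig Tibble `t`/`value` or numeric vector (SKNA-rate signal).
#' @param fs Sampling rate, Hz.
#' @param band Two-element Hz vector inside (0, fs/2); when the signal has
#'   already been band-limited (e.g. by [highpass_skna()] at 2 kHz, whose
#'   effective band is 500-995 Hz) the band-pass is a near no-op.
#' @param smooth Moving-average length, seconds (default 10 ms).
#' @return Tibble with columns `t` and `env` (dimensionless, mean 1).
#' @export
amplitude_envelope <- function(sig, fs = 2000, band = c(500, 995), smooth = 0.01) {
  x <- as_signal(sig, fs)
  if (band[1] <= 0 || band[2] >= x$fs / 2 || band[2] <= band[1]) {
    abort("`band` must lie within (0, fs/2) and increase")
  }
  bp <- signal::butter(4, band / (x$fs / 2), type = "pass")
  v <- zero_phase(bp, x$values)
  env <- analytic_amplitude(v)
  k <- max(1L, round(smooth * x$fs))
  if (k > 1L) env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env <- as.numeric(env)
  env[is.na(env)] <- mean(env, na.rm = TRUE) # moving-average edge fill
  m <- mean(env)
  if (m <= 0 || !is.finite(m)) abort("cannot normalize an all-zero envelope")
  env <- env / mean(env) # exact mean-1 contract
  env <- env / mean(env)
  tibble(t = (seq_along(env) - 1L) / x$fs, env = env)
}

#' Detect bursts with a dual-threshold crossing rule
#'
#' A burst begins when the normalized envelope crosses `thresh_hi` and
#' extends backward and forward to the surrounding crossings of
#' `thresh_lo`, so each reported burst contains at least one sample above
#' the high threshold. Bursts separated by less than `merge_gap` are fused
#' and bursts shorter than `min_duration` are discarded.
#'
#' @param env Tibble from [amplitude_envelope()] (`t`, `env`).
#' @param thresh_hi,thresh_lo Onset / termination thresholds in
#'   mean-normalized units; `thresh_hi >= thresh_lo > 0`.
#' @param min_duration Minimum burst length, seconds.
#' @param merge_gap Gaps shorter than this between consecutive bursts are
#'   merged, seconds.
#' @return Tibble of bursts: `onset`, `offset`, `duration` (s) and
#'   `peak_norm_amp`.
#' @export
detect_bursts <- function(env, thresh_hi = 2.0, thresh_lo = 1.0,
                          min_duration = 0.02, merge_gap = 0.01) {
  if (thresh_hi < thresh_lo) abort("`thresh_hi` must be >= `thresh_lo`")
  if (thresh_lo <= 0) abort("`thresh_lo` must be > 0")
  t <- env$t
  e <- env$env
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  above_lo <- e >= thresh_lo
  # contiguous runs above the low threshold
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs)) {
    hit_hi <- purrr::map_lgl(seq_len(nrow(runs)), function(i)
      any(e[runs$start[i]:runs$end[i]] >= thresh_hi))
    runs <- runs[hit_hi, ]
  }
  if (!nrow(runs)) {
    return(tibble(onset = numeric(), offset = numeric(),
                  duration = numeric(), peak_norm_amp = numeric()))
  }
  # merge runs separated by less than merge_gap
  if (nrow(runs) > 1 && merge_gap > 0) {
    keep_start <- c(TRUE, t[runs$start[-1]] - t[runs$end[-nrow(runs)]] > merge_gap)
    grp <- cumsum(keep_start)
    runs <- runs %>%
      mutate(grp = grp) %>%
      group_by(.data$grp) %>%
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  }
  out <- tibble(
    onset = t[runs$start],
    offset = t[runs$end] + dt,
    peak_norm_amp = purrr::map_dbl(seq_len(nrow(runs)), function(i)
      max(e[runs$start[i]:runs$end[i]]))
  ) %>%
    mutate(duration = .data$offset - .data$onset) %>%
    filter(.data$duration >= min_duration) %>%
    select("onset", "offset", "duration", "peak_norm_amp") %>%
    arrange(.data$onset)
  out
}

#' Summarize burst activity over an interval
#'
#' Counts bursts whose onset lies inside the interval (a burst straddling
#' the interval edge belongs to the interval containing its onset) and
#' reports the rate and mean duration.
#'
#' @param events Burst tibble from [detect_bursts()].
#' @param interval Two-element `c(start, end)`, seconds; must have positive
#'   length.
#' @return One-row tibble: `n_bursts`, `bursts_per_second`, `mean_duration`,
#'   `interval_start`, `interval_end`.
#' @export
burst_stats <- function(events, interval) {
  len <- interval[2] - interval[1]
  if (!is.finite(len) || len <= 0) abort("`interval` must have positive length")
  inside <- events$onset >= interval[1] & events$onset < interval[2]
  n <- sum(inside)
  tibble(
    n_bursts = n,
    bursts_per_second = n / len,
    mean_duration = if (n) mean(events$duration[inside]) else 0,
    interval_start = interval[1],
    interval_end = interval[2]
  )
}

#' Sliding burst-rate series
#'
#' Burst rate in consecutive windows, for use as a feature series in the
#' onset-delay analysis.
#'
#' @param events Burst tibble from [detect_bursts()].
#' @param span Two-element `c(start, end)` covering the analysis range, s.
#' @param window,step Window length and hop, seconds.
#' @return Tibble `t` (window end) and `value` (bursts/s).
#' @export
burst_rate_series <- function(events, span, window = 10, step = 1) {
  starts <- seq(span[1], span[2] - window, by = step)
  # causal stamp (window end) so rises are never reported before they occur
  tibble(
    t = starts + window,
    value = purrr::map_dbl(starts, function(s)
      sum(events$onset >= s & events$onset < s + window) / window)
  )
}
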