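# Time-domain HRV: R-peak detection (Pan-Tompkins-style), NN intervals with
# a physiological artifact rule, RMSSD, median NN, and sliding-window
# feature series for the onset-delay analysis. Defaults target rat ECG
# (resting HR ~400 beats/min, RR floor 60 ms).

#' Detect R peaks in an ECG signal
#'
#' Band-pass (8-50 Hz), differentiate, square, integrate over a 30 ms
#' moving window, then threshold at a fixed fraction of a high quantile of
#' the integrated energy — making the detector invariant to amplitude
#' scaling — and keep one peak per supra-threshold region, enforcing a
#' refractory period.
#'
#' @param ecg Tibble `t`/`value` or numeric vector.
#' @param fs Sampling rate, Hz; must be at least 250.
#' @param refractory Minimum peak spacing, seconds (default 60 ms, the rat
#'   physiological RR floor).
#' @return Tibble with column `t`: strictly increasing peak times, seconds.
#'   A flat-line input yields zero rows with a warning.
#' @export
detect_r_peaks <- function(ecg, fs = NULL, refractory = 0.06) {
  x <- as_signal(ecg, fs)
  if (x$fs < 250) abort("R-peak detection needs fs >= 250 Hz")
  v <- x$values
  if (all(abs(v - v[1]) < 1e-12)) {
    warn("flat-line ECG: no R peaks detected")
    return(tibble(t = numeric()))
  }
  bp <- signal::butter(3, c(8, 50) / (x$fs / 2), type = "pass")
  f <- zero_phase(bp, v)
  energy <- c(0, diff(f))^2
  k <- max(1L, round(0.03 * x$fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / k, k), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * quantile(integ, 0.99)
  above <- integ > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (!nrow(seg)) return(tibble(t = numeric()))
  peaks <- vapply(seq_len(nrow(seg)), function(i) {
    idx <- seg[i, 1]:seg[i, 2]
    idx[which.max(abs(f[idx]))]
  }, numeric(1))
  times <- (peaks - 1L) / x$fs
  # refractory: keep the stronger of any pair closer than the floor
  keep <- rep(TRUE, length(times))
  last <- 1L
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[last] < refractory) {
      if (integ[peaks[i]] > integ[peaks[last]]) {
        keep[last] <- FALSE
        last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  tibble(t = times[keep])
}

#' NN intervals from R-peak times
#'
#' Successive differences of the peak times in milliseconds, stamped at the
#' time of the interval's end. Intervals outside the physiological window
#' are rejected as artifacts, and a successive-difference pair spanning a
#' rejected interval is excluded downstream (the `valid` flag marks
#' survivors).
#'
#' @param peaks Tibble with column `t` from [detect_r_peaks()], or a
#'   numeric vector of peak times (s).
#' @param floor_ms,ceiling_ms Physiological NN window in ms (rat defaults
#'   60-400 ms).
#' @return Tibble with `t` (s, interval end), `nn` (ms) and `valid`.
#' @export
rr_intervals <- function(peaks, floor_ms = 60, ceiling_ms = 400) {
  pt <- if (is.data.frame(peaks)) peaks$t else as.numeric(peaks)
  if (length(pt) < 2) abort("need at least 2 peaks to form intervals")
  nn <- diff(pt) * 1000
  tibble(t = pt[-1], nn = nn,
         valid = nn >= floor_ms & nn <= ceiling_ms)
}

# valid intervals only, erroring when fewer than `min_n` remain
nn_valid <- function(nn, min_n) {
  v <- if ("valid" %in% names(nn)) nn[nn$valid, ] else nn
  if (nrow(v) < min_n) abort(sprintf("need at least %d valid NN intervals", min_n))
  v
}

#' Root mean square of successive NN differences (RMSSD)
#'
#' `sqrt(mean(diff(nn)^2))` over valid intervals; successive-difference
#' pairs spanning a rejected artifact interval are excluded.
#'
#' @param nn Tibble from [rr_intervals()] or numeric NN vector (ms).
#' @return RMSSD in ms.
#' @export
rmssd <- function(nn) {
  if (!is.data.frame(nn)) nn <- tibble(t = seq_along(nn), nn = nn, valid = TRUE)
  v <- nn_valid(nn, 2)
  d <- diff(v$nn)
  if ("t" %in% names(nn) && "valid" %in% names(nn)) {
    # a pair is contiguous only if no rejected interval sits between them
    idx <- which(nn$valid)
    contiguous <- diff(idx) == 1
    d <- diff(nn$nn[idx])[contiguous]
  }
  if (!length(d)) abort("no contiguous NN pairs for RMSSD")
  sqrt(mean(d^2))
}

#' Median NN interval
#'
#' Sample median of the valid NN intervals; an even count returns the mean
#' of the two central values. (Reported alongside RMSSD as a time-domain
#' HRV feature; despite naming variations in the literature this is the
#' plain median of the NN intervals in ms.)
#'
#' @param nn Tibble from [rr_intervals()] or numeric NN vector (ms).
#' @return Median NN in ms.
#' @export
median_nn <- function(nn) {
  if (!is.data.frame(nn)) nn <- tibble(nn = nn, valid = TRUE)
  v <- nn_valid(nn, 1)
  median(v$nn)
}

#' Instantaneous heart-rate series
#'
#' Converts each NN interval to beats/min (`60000 / NN_ms`) at its
#' timestamp.
#'
#' @param nn Tibble from [rr_intervals()].
#' @return Tibble `t` (s) and `value` (beats/min).
#' @export
heart_rate_series <- function(nn) {
  v <- nn_valid(nn, 1)
  tibble(t = v$t, value = 60000 / v$nn)
}

#' Sliding-window HRV feature series
#'
#' RMSSD, median NN and mean HR in sliding windows, producing the regular
#' feature series consumed by the onset-delay analysis.
#'
#' @param nn Tibble from [rr_intervals()].
#' @param window,step Window length and hop, seconds.
#' @return Tibble `t` (window end), `rmssd_ms`, `median_nn_ms`, `hr_bpm`;
#'   windows with fewer than 3 valid intervals carry `NA`.
#' @export
hrv_sliding_features <- function(nn, window = 10, step = 1) {
  v <- nn[nn$valid, ]
  t0 <- min(nn$t)
  starts <- seq(t0, max(nn$t) - window, by = step)
  # causal stamp (window end) so feature rises never precede their cause
  purrr::map_dfr(starts, function(s) {
    w <- v[v$t >= s & v$t < s + window, ]
    if (nrow(w) < 3) {
      return(tibble(t = s + window, rmssd_ms = NA_real_,
                    median_nn_ms = NA_real_, hr_bpm = NA_real_))
    }
    tibble(t = s + window,
           rmssd_ms = sqrt(mean(diff(w$nn)^2)),
           median_nn_ms = median(w$nn),
           hr_bpm = mean(60000 / w$nn))
  })
}
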