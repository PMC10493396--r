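# Marker-anchored AD event detection (SBP rise > 15 mmHg followed by
# bradycardia) and per-feature onset-delay estimation relative to the CRD
# stimulus marker.

#' Detect autonomic dysreflexia events around stimulus markers
#'
#' For each marker pulse, the pre-marker SBP baseline (mean over
#' `baseline_window` seconds) is compared with the post-marker search
#' window: an AD event is accepted iff SBP exceeds the baseline by more
#' than `rise_threshold` mmHg AND heart rate subsequently falls below its
#' pre-marker mean by `brady_frac` for at least `brady_sustain` seconds. A
#' rise without bradycardia is reported as a flagged non-AD trial. The SBP
#' rise onset is the last sample within one baseline SD of the baseline
#' mean before the threshold exceedance.
#'
#' @param sbp Tibble `t`/`value`, systolic pressure in mmHg.
#' @param hr Tibble `t`/`value`, heart rate in beats/min (may be
#'   irregularly sampled, e.g. from [heart_rate_series()]).
#' @param marker Numeric vector of marker pulse times, seconds.
#' @param rise_threshold SBP rise criterion, mmHg (default 15, the rat AD
#'   criterion; the clinical human criterion is 20).
#' @param baseline_window Pre-marker baseline length, seconds.
#' @param search_window Post-marker window searched for the response, s.
#' @param brady_frac Fractional HR drop defining bradycardia (default 10%).
#' @param brady_sustain Minimum sustained bradycardia, seconds.
#' @return Tibble with one row per marker: `crd_onset`, `sbp_rise_onset`,
#'   `sbp_rise` (mmHg), `bradycardia_confirmed`, `accepted`,
#'   `window_start`, `window_end`.
#' @export
detect_ad_events <- function(sbp, hr, marker, rise_threshold = 15,
                             baseline_window = 60, search_window = 120,
                             brady_frac = 0.10, brady_sustain = 2) {
  purrr::map_dfr(marker, function(m) {
    if (m < min(sbp$t) || m > max(sbp$t)) {
      abort(sprintf("marker at %.1f s lies outside the SBP signal span", m))
    }
    base_idx <- sbp$t >= m - baseline_window & sbp$t < m
    post_idx <- sbp$t >= m & sbp$t <= m + search_window
    base_sbp <- mean(sbp$value[base_idx])
    post <- sbp[post_idx, ]
    rise <- max(post$value) - base_sbp
    rise_ok <- rise > rise_threshold
    base_sd <- stats::sd(sbp$value[base_idx])
    onset <- NA_real_
    if (rise_ok) {
      i_exceed <- which(post$value > base_sbp + rise_threshold)[1]
      # walk back to the last sample within one baseline-SD of the mean, so
      # slow pressure wander does not drag the onset earlier than the ramp
      below <- which(post$value[seq_len(i_exceed)] <= base_sbp + base_sd)
      onset <- if (length(below)) post$t[max(below)] else post$t[1]
    }
    # bradycardia: sustained HR below (1 - brady_frac) x pre-marker mean
    hr_base <- mean(hr$value[hr$t >= m - baseline_window & hr$t < m])
    hpost <- hr[hr$t >= m & hr$t <= m + search_window, ]
    brady <- FALSE
    if (nrow(hpost) > 1 && is.finite(hr_base)) {
      low <- hpost$value < hr_base * (1 - brady_frac)
      r <- rle(low)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        if (hpost$t[ends[k]] - hpost$t[starts[k]] >= brady_sustain) {
          brady <- TRUE
          break
        }
      }
    }
    tibble(crd_onset = m, sbp_rise_onset = onset, sbp_rise = rise,
           bradycardia_confirmed = brady, accepted = rise_ok && brady,
           window_start = m - baseline_window, window_end = m + search_window)
  })
}

#' Find significant rises in a feature series
#'
#' The baseline is the mean of the series over the leading
#' `baseline_window` seconds. Local maxima exceeding
#' `baseline * (1 + peak_frac)` are significant; for each, the rise time is
#' the last sample preceding the peak that sits within one baseline SD of
#' the baseline mean (for a noise-free baseline this is exactly the
#' baseline-mean crossing).
#'
#' @param feature Tibble `t`/`value`.
#' @param baseline_window Baseline length, seconds (default 180); the
#'   series must be longer than this.
#' @param peak_frac Significance margin over baseline (default 0.20, the
#'   20% rule).
#' @param direction `"rise"` or `"fall"` (the fall rule mirrors the rise
#'   rule below `baseline * (1 - peak_frac)`, used for the bradycardic HR
#'   response).
#' @return Tibble `peak_time`, `peak_value`, `rise_time`; zero rows if no
#'   significant excursion.
#' @export
detect_feature_rise <- function(feature, baseline_window = 180,
                                peak_frac = 0.20,
                                direction = c("rise", "fall")) {
  direction <- match.arg(direction)
  feature <- feature[is.finite(feature$value), ]
  t <- feature$t
  v <- feature$value
  if (length(t) < 3 || max(t) - min(t) <= baseline_window) {
    abort("feature series must be longer than the baseline window")
  }
  base_idx <- t <= min(t) + baseline_window
  base_mean <- mean(v[base_idx])
  base_sd <- stats::sd(v[base_idx])
  if (!is.finite(base_sd)) base_sd <- 0
  if (direction == "fall") {
    v <- 2 * base_mean - v # mirror, so a fall becomes a rise
  }
  thr <- base_mean * (1 + peak_frac)
  # local maxima: strictly greater than both neighbours (plateaus: first)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  sig <- which(is_max & v > thr)
  if (!length(sig)) {
    return(tibble(peak_time = numeric(), peak_value = numeric(),
                  rise_time = numeric()))
  }
  purrr::map_dfr(sig, function(i) {
    # walk back to the last sample within one baseline SD of the baseline
    # mean: ordinary baseline fluctuation should not pull the onset earlier
    below <- which(v[seq_len(i)] <= base_mean + base_sd)
    rise <- if (length(below)) t[max(below)] else t[1]
    tibble(peak_time = t[i],
           peak_value = if (direction == "fall") 2 * base_mean - v[i] else v[i],
           rise_time = rise)
  })
}

#' Per-feature onset delays for one AD event
#'
#' For each feature series, finds the largest significant rise (HR: fall)
#' inside the post-marker window — the episode response dominates any
#' chance resting fluctuation — and reports the latency of its
#' baseline-crossing rise time relative to the CRD marker. The SBP delay
#' uses the event's `sbp_rise_onset`. Features with no significant
#' excursion get a missing (`NA`) delay, never zero.
#'
#' @param event One row of the tibble from [detect_ad_events()].
#' @param features Named list of tibbles `t`/`value` (e.g. `iskna`,
#'   `bursts_per_s`, `rmssd`, `hr`). Each should cover the event window.
#' @param baseline_window,peak_frac Passed to [detect_feature_rise()];
#'   `baseline_window` defaults to the event's own pre-marker window.
#' @return Tibble `feature`, `delay` (s from `crd_onset`), `peak_time`.
#' @export
feature_delays <- function(event, features, baseline_window = NULL,
                           peak_frac = 0.20) {
  m <- event$crd_onset
  if (is.null(baseline_window)) baseline_window <- m - event$window_start
  rows <- purrr::imap(features, function(f, nm) {
    w <- f[f$t >= event$window_start & f$t <= event$window_end, ]
    dirn <- if (nm == "hr") "fall" else "rise"
    res <- tryCatch(
      detect_feature_rise(w, baseline_window = baseline_window,
                          peak_frac = peak_frac, direction = dirn),
      error = function(e) tibble(peak_time = numeric(), rise_time = numeric(),
                                 peak_value = numeric())
    )
    res <- res[res$peak_time >= m, ]
    if (!nrow(res)) {
      return(tibble(feature = nm, delay = NA_real_, peak_time = NA_real_))
    }
    best <- res[which.max(res$peak_value), ]
    tibble(feature = nm, delay = max(best$rise_time - m, 0),
           peak_time = best$peak_time)
  })
  out <- bind_rows(rows)
  bind_rows(out, tibble(feature = "sbp",
                        delay = event$sbp_rise_onset - m,
                        peak_time = NA_real_))
}

#' SKNA lead time over the blood-pressure rise
#'
#' How much earlier the SKNA response (ISKNA or burst rate, whichever rises
#' first) begins compared to the systolic blood-pressure rise:
#' `sbp_delay - min(iskna_delay, bursts_delay)`.
#'
#' @param delays Tibble from [feature_delays()] (columns `feature`,
#'   `delay`), or any tibble with rows named `iskna`/`bursts_per_s` and
#'   `sbp`.
#' @return Lead time in seconds.
#' @export
lead_time <- function(delays) {
  skna <- delays$delay[delays$feature %in% c("iskna", "bursts_per_s")]
  skna <- skna[is.finite(skna)]
  sbp <- delays$delay[delays$feature == "sbp"]
  sbp <- sbp[is.finite(sbp)]
  if (!length(skna)) abort("no SKNA-family delay available")
  if (!length(sbp)) abort("no SBP delay available")
  sbp[1] - min(skna)
}
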