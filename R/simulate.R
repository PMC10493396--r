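# Synthetic multichannel physiology: rat-like ECG carrying SKNA burst trains,
# a systolic blood-pressure envelope, and a stimulus-marker channel, with the
# statistical structure the downstream analysis assumes (known burst times,
# known per-feature onset delays).

#' Describe one autonomic dysreflexia episode for the simulator
#'
#' An `ad_scenario` plants a colorectal-distension (CRD) stimulus at
#' `crd_onset` and schedules the physiological responses around it: the SKNA
#' burst train starts `skna_delay` seconds later, systolic blood pressure
#' ramps up by `sbp_rise` mmHg after `sbp_delay`, beat-to-beat RR jitter (the
#' RMSSD response) rises after `rmssd_delay`, and heart rate falls by
#' `hr_drop` beats/min after `hr_drop_delay`. Default delays follow the mean
#' latencies observed in conscious rat CRD experiments (SKNA ~5.6 s,
#' SBP ~23.4 s, RMSSD ~9.4 s, HR ~35.8 s after stimulus onset).
#'
#' @param crd_onset Stimulus onset, seconds from the start of the recording.
#' @param skna_delay,sbp_delay,rmssd_delay,hr_drop_delay Response latencies in
#'   seconds relative to `crd_onset`; all must be >= 0.
#' @param sbp_rise Systolic pressure elevation in mmHg (> 0).
#' @param hr_drop Bradycardic heart-rate drop in beats/min.
#' @param event_duration Length of the episode in seconds, measured from
#'   `crd_onset`.
#' @param rmssd_jitter_sd_ms Beat-to-beat RR jitter SD (ms) applied from
#'   `crd_onset + rmssd_delay` to the end of the episode; drives the RMSSD
#'   elevation during the event.
#' @return A list of class `ad_scenario`.
#' @export
ad_scenario <- function(crd_onset,
                        skna_delay = 5.6,
                        sbp_delay = 23.4,
                        sbp_rise = 30,
                        rmssd_delay = 9.4,
                        hr_drop_delay = 35.8,
                        hr_drop = 60,
                        event_duration = 60,
                        rmssd_jitter_sd_ms = 10) {
  delays <- c(skna_delay = skna_delay, sbp_delay = sbp_delay,
              rmssd_delay = rmssd_delay, hr_drop_delay = hr_drop_delay)
  if (any(delays < 0)) abort("all scenario delays must be >= 0")
  if (sbp_rise <= 0) abort("`sbp_rise` must be > 0")
  stopifnot_scalar(event_duration, "event_duration")
  structure(list(crd_onset = crd_onset, skna_delay = skna_delay,
                 sbp_delay = sbp_delay, sbp_rise = sbp_rise,
                 rmssd_delay = rmssd_delay, hr_drop_delay = hr_drop_delay,
                 hr_drop = hr_drop, event_duration = event_duration,
                 rmssd_jitter_sd_ms = rmssd_jitter_sd_ms),
            class = "ad_scenario")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic recording. Defaults emulate the
#' acquisition used for rat SKNA work: ECG at 10 kHz, telemetry blood
#' pressure at 500 Hz, resting heart rate ~400 beats/min, resting systolic
#' pressure ~120 mmHg, and SKNA bursts as 500-995 Hz band-limited noise.
#'
#' @param duration Recording length, seconds.
#' @param ecg_fs,bp_fs Sampling rates (Hz) of the ECG/marker and blood
#'   pressure channels.
#' @param baseline_hr Resting heart rate, beats/min.
#' @param hr_noise_sd Per-beat heart-rate noise SD, beats/min.
#' @param baseline_sbp Resting systolic pressure, mmHg.
#' @param sbp_noise_sd Marginal SD (mmHg) of the slow SBP noise process.
#' @param ad_events List of [ad_scenario()] objects, sorted by onset and
#'   non-overlapping.
#' @param baseline_burst_rate Resting SKNA burst rate, bursts/s.
#' @param ad_burst_rate Burst rate during an episode's SKNA window, bursts/s.
#' @param burst_amplitude Burst RMS amplitude, microvolts.
#' @param burst_duration_mean Mean burst duration, seconds.
#' @param burst_carrier_band Two-element Hz vector; must lie inside
#'   (0, ecg_fs/2).
#' @param ecg_noise_sd Broadband ECG noise SD, microvolts.
#' @param rr_jitter_sd_ms Baseline beat-to-beat RR jitter SD, ms.
#' @param seed Integer seed; identical configurations give bit-identical
#'   recordings.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration,
                       ecg_fs = 10000,
                       bp_fs = 500,
                       baseline_hr = 400,
                       hr_noise_sd = 5,
                       baseline_sbp = 120,
                       sbp_noise_sd = 2,
                       ad_events = list(),
                       baseline_burst_rate = 0.2,
                       ad_burst_rate = 2,
                       burst_amplitude = 10,
                       burst_duration_mean = 0.3,
                       burst_carrier_band = c(500, 995),
                       ecg_noise_sd = 2,
                       rr_jitter_sd_ms = 2,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot_scalar(config$duration, "duration")
  stopifnot_scalar(config$ecg_fs, "ecg_fs")
  stopifnot_scalar(config$bp_fs, "bp_fs")
  band <- config$burst_carrier_band
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= config$ecg_fs / 2) {
    abort("`burst_carrier_band` must lie within (0, ecg_fs/2) and increase")
  }
  evs <- config$ad_events
  if (length(evs)) {
    if (!all(vapply(evs, inherits, logical(1), "ad_scenario"))) {
      abort("`ad_events` must be a list of ad_scenario objects")
    }
    on <- vapply(evs, `[[`, numeric(1), "crd_onset")
    end <- on + vapply(evs, `[[`, numeric(1), "event_duration")
    if (is.unsorted(on, strictly = TRUE)) abort("`ad_events` must be sorted by onset")
    if (any(head(end, -1) > tail(on, -1))) abort("`ad_events` must not overlap")
    reach <- vapply(evs, function(e) {
      e$crd_onset + max(e$event_duration, e$sbp_delay + 5,
                        e$hr_drop_delay + 2, e$skna_delay + 1)
    }, numeric(1))
    if (any(reach > config$duration)) {
      abort("event window exceeds recording duration")
    }
  }
  invisible(config)
}

# smoothstep ramp: 0 before t0, 1 after t0 + width
smoothstep <- function(t, t0, width) {
  u <- pmin(pmax((t - t0) / width, 0), 1)
  u * u * (3 - 2 * u)
}

# cosine-tapered (Tukey) window, taper fraction `a` at each end combined
tukey_win <- function(n, a = 0.2) {
  if (n == 1) return(1)
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- u < a / 2
  w[edge] <- 0.5 * (1 + cos(pi * (2 * u[edge] / a - 1)))
  edge <- u > 1 - a / 2
  w[edge] <- 0.5 * (1 + cos(pi * (2 * (1 - u[edge]) / a - 1)))
  w
}

# draw a non-overlapping burst train on [t0, t1) at `rate` bursts/s
draw_bursts <- function(t0, t1, rate, dur_mean) {
  if (rate <= 0 || t1 <= t0) return(tibble(onset = numeric(), offset = numeric()))
  onsets <- offsets <- numeric()
  t <- t0
  repeat {
    gap <- stats::rexp(1, rate)
    dur <- max(0.05, stats::rgamma(1, shape = 4, scale = dur_mean / 4))
    t <- t + gap
    if (t + dur > t1) break
    onsets <- c(onsets, t)
    offsets <- c(offsets, t + dur)
    t <- t + dur + 0.05 # refractory gap keeps planted bursts disjoint
  }
  tibble(onset = onsets, offset = offsets)
}

#' Generate a synthetic multichannel recording
#'
#' Produces an `ecg` channel (QRS-like beats as sums of Gaussian bumps, plus
#' band-limited SKNA burst trains gated by cosine-tapered envelopes, plus
#' white noise), a `bp` channel (systolic-pressure envelope: baseline plus a
#' slow noise process plus a smooth ramp of `sbp_rise` mmHg during each
#' episode), and a `marker` channel that is zero except for a single-sample
#' pulse at each CRD onset. Heart rate follows the configured baseline,
#' drops by `hr_drop` beats/min from `crd_onset + hr_drop_delay` to the end
#' of each episode, and carries elevated RR jitter from
#' `crd_onset + rmssd_delay`. The planted ground truth (scenario table and
#' burst onset/offset times) is attached for test harnesses.
#'
#' @param config A [sim_config()] object.
#' @return A `physio_recording`: list with `channels` (each a list holding
#'   `values` and `fs`), `meta` (subject/day labels, duration, seed) and
#'   `truth` (tibbles `ad_events` and `bursts`).
#' @param subject,day Metadata labels stored with the recording.
#' @export
simulate_recording <- function(config, subject = "S1", day = "day1") {
  validate_sim_config(config)
  set.seed(config$seed)
  dur <- config$duration
  fs <- config$ecg_fs

  # ---- beat times ----------------------------------------------------
  evs <- config$ad_events
  hr_at <- function(t) {
    hr <- config$baseline_hr
    for (e in evs) {
      t0 <- e$crd_onset + e$hr_drop_delay
      t1 <- max(t0 + 10, e$crd_onset + e$event_duration)
      hr <- hr - e$hr_drop * smoothstep(t, t0, 2) * (1 - smoothstep(t, t1, 5))
    }
    hr
  }
  jitter_at <- function(t) {
    j <- config$rr_jitter_sd_ms
    for (e in evs) {
      if (t >= e$crd_onset + e$rmssd_delay && t <= e$crd_onset + e$event_duration) {
        j <- e$rmssd_jitter_sd_ms
      }
    }
    j
  }
  beats <- numeric(ceiling(dur * config$baseline_hr / 60) + 16)
  nb <- 0L
  t <- stats::runif(1, 0, 60 / config$baseline_hr)
  while (t < dur) {
    nb <- nb + 1L
    beats[nb] <- t
    hr <- hr_at(t) + stats::rnorm(1, 0, config$hr_noise_sd)
    rr <- 60 / max(hr, 30) + stats::rnorm(1, 0, jitter_at(t) / 1000)
    t <- t + max(rr, 0.06) # physiological RR floor
  }
  beats <- beats[seq_len(nb)]

  # ---- ECG waveform --------------------------------------------------
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  ecg <- numeric(n)
  add_bump <- function(center, amp, width) {
    lo <- max(1L, floor((center - 4 * width) * fs) + 1L)
    hi <- min(n, ceiling((center + 4 * width) * fs) + 1L)
    if (hi < lo) return(invisible())
    idx <- lo:hi
    ecg[idx] <<- ecg[idx] + amp * exp(-0.5 * ((tt[idx] - center) / width)^2)
  }
  for (b in beats) {
    add_bump(b - 0.040, 50, 0.010)  # P
    add_bump(b - 0.008, -80, 0.003) # Q
    add_bump(b, 500, 0.003)         # R
    add_bump(b + 0.008, -100, 0.003) # S
    add_bump(b + 0.060, 80, 0.020)  # T
  }

  # ---- SKNA bursts ---------------------------------------------------
  truth_bursts <- draw_bursts(0, dur, config$baseline_burst_rate,
                              config$burst_duration_mean)
  truth_bursts$during_ad <- rep(FALSE, nrow(truth_bursts))
  for (e in evs) {
    bt <- draw_bursts(e$crd_onset + e$skna_delay,
                      e$crd_onset + e$event_duration,
                      config$ad_burst_rate, config$burst_duration_mean)
    bt$during_ad <- rep(TRUE, nrow(bt))
    truth_bursts <- bind_rows(truth_bursts, bt)
  }
  truth_bursts <- arrange(truth_bursts, .data$onset)
  if (nrow(truth_bursts) > 1) { # baseline bursts may straddle AD trains
    keep <- c(TRUE, truth_bursts$onset[-1] >= cummax(truth_bursts$offset)[-nrow(truth_bursts)])
    truth_bursts <- truth_bursts[keep, ]
  }
  if (nrow(truth_bursts)) {
    bf <- signal::butter(4, config$burst_carrier_band / (fs / 2), type = "pass")
    for (k in seq_len(nrow(truth_bursts))) {
      i0 <- floor(truth_bursts$onset[k] * fs) + 1L
      i1 <- min(n, ceiling(truth_bursts$offset[k] * fs))
      ns <- i1 - i0 + 1L
      if (ns < 16) next
      w <- signal::filter(bf, stats::rnorm(ns + 200))[-(1:200)] # discard transient
      w <- w / sqrt(mean(w^2))
      ecg[i0:i1] <- ecg[i0:i1] + config$burst_amplitude * w * tukey_win(ns, 0.25)
    }
  }
  if (config$ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, config$ecg_noise_sd)

  # ---- blood pressure (SBP envelope) ---------------------------------
  nbp <- round(dur * config$bp_fs)
  tbp <- (seq_len(nbp) - 1L) / config$bp_fs
  bp <- rep(config$baseline_sbp, nbp)
  if (config$sbp_noise_sd > 0) {
    kt <- seq(-5, dur + 5, by = 5) # slow vasomotor SBP wander
    kv <- stats::rnorm(length(kt), 0, config$sbp_noise_sd)
    bp <- bp + stats::spline(kt, kv, xout = tbp)$y
  }
  for (e in evs) {
    t0 <- e$crd_onset + e$sbp_delay
    t1 <- e$crd_onset + e$event_duration
    ramp <- smoothstep(tbp, t0, 5) * (1 - smoothstep(tbp, max(t1, t0 + 5), 20))
    bp <- bp + e$sbp_rise * ramp
  }

  # ---- marker --------------------------------------------------------
  marker <- numeric(n)
  for (e in evs) marker[round(e$crd_onset * fs) + 1L] <- 1

  structure(list(
    channels = list(
      ecg = list(values = ecg, fs = fs),
      bp = list(values = bp, fs = config$bp_fs),
      marker = list(values = marker, fs = fs)
    ),
    meta = list(subject = subject, day = day, duration = dur,
                seed = config$seed),
    truth = list(
      ad_events = if (length(evs)) bind_rows(lapply(evs, function(e)
        as_tibble(unclass(e)))) else tibble(),
      bursts = truth_bursts,
      beats = beats
    )
  ), class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat("<physio_recording>", x$meta$subject, x$meta$day,
      sprintf("(%.1f s)\n", x$meta$duration))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-7s %d samples @ %g Hz\n", nm, length(ch$values), ch$fs))
  }
  invisible(x)
}

#' Long-format view of a recording's channels
#'
#' @param x A `physio_recording`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `t`, `value`.
#' @export
as_tibble.physio_recording <- function(x, ...) {
  purrr::imap(x$channels, function(ch, nm) {
    tibble(channel = nm,
           t = (seq_along(ch$values) - 1L) / ch$fs,
           value = ch$values)
  }) %>% bind_rows()
}

#' Extract one channel as a time/value tibble
#'
#' @param rec A `physio_recording`.
#' @param channel Channel name (`"ecg"`, `"bp"` or `"marker"`).
#' @return Tibble with columns `t` (s) and `value`.
#' @export
channel_tbl <- function(rec, channel) {
  ch <- rec$channels[[channel]]
  if (is.null(ch)) abort(sprintf("channel '%s' not present in recording", channel))
  ts_tibble((seq_along(ch$values) - 1L) / ch$fs, ch$values)
}

#' Marker pulse times
#'
#' @param rec A `physio_recording`.
#' @return Numeric vector of CRD onset times in seconds.
#' @export
marker_times <- function(rec) {
  ch <- rec$channels$marker
  if (is.null(ch)) abort("channel 'marker' not present in recording")
  (which(ch$values != 0) - 1L) / ch$fs
}

# draw from a normal truncated below at `lower` (inverse-CDF method)
rtruncnorm_low <- function(n, mean, sd, lower = 0) {
  p0 <- stats::pnorm(lower, mean, sd)
  qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate a cohort of subjects with randomly drawn response delays
#'
#' Each subject gets one AD episode whose SKNA and SBP latencies are drawn
#' from normal distributions truncated at zero (defaults: SKNA
#' Normal(5.6, 4.5) s, SBP Normal(23.4, 18.0) s, matching the latency spread
#' reported for conscious rat CRD experiments). Returns the recordings along
#' with the configured (planted) delays for parameter-recovery studies.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed for the cohort-level draws; subject recordings use
#'   derived seeds.
#' @param skna_delay_mean,skna_delay_sd,sbp_delay_mean,sbp_delay_sd Delay
#'   distribution parameters in seconds.
#' @param crd_onset Stimulus onset within each recording, seconds.
#' @param ... Further arguments passed to [sim_config()] overriding defaults.
#' @return A list with `recordings` (list of `physio_recording`) and
#'   `configured` (tibble of planted delays per subject).
#' @export
simulate_cohort <- function(n_subjects = 9, seed = 1L,
                            skna_delay_mean = 5.6, skna_delay_sd = 4.5,
                            sbp_delay_mean = 23.4, sbp_delay_sd = 18.0,
                            crd_onset = 70, ...) {
  set.seed(seed)
  skna_d <- rtruncnorm_low(n_subjects, skna_delay_mean, skna_delay_sd)
  sbp_d <- rtruncnorm_low(n_subjects, sbp_delay_mean, sbp_delay_sd)
  sub_seeds <- sample.int(2^30, n_subjects)
  recs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    dur <- crd_onset + max(90, sbp_d[i] + 40)
    sc <- ad_scenario(crd_onset, skna_delay = skna_d[i], sbp_delay = sbp_d[i],
                      event_duration = max(60, sbp_d[i] + 20))
    cfg <- sim_config(duration = dur, ad_events = list(sc),
                      seed = sub_seeds[i], ...)
    recs[[i]] <- simulate_recording(cfg, subject = sprintf("S%d", i))
  }
  list(recordings = recs,
       configured = tibble(subject = sprintf("S%d", seq_len(n_subjects)),
                           skna_delay = skna_d, sbp_delay = sbp_d))
}
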