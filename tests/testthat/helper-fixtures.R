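# Shared fixtures, generated once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one AD episode with round planted delays
std_ad_recording <- function() memo("std_ad", {
  sc <- ad_scenario(70, skna_delay = 5, sbp_delay = 23, hr_drop_delay = 35,
                    sbp_rise = 30)
  simulate_recording(sim_config(duration = 180, ad_events = list(sc), seed = 42))
})

std_analysis <- function() memo("std_analysis", analyze_recording(std_ad_recording()))

# short baseline-only recording for burst work (SNR ~3.6 in the SKNA band)
burst_recording <- function() memo("burst_rec", {
  simulate_recording(sim_config(duration = 120, ad_events = list(),
                                baseline_burst_rate = 0.3, burst_amplitude = 10,
                                ecg_noise_sd = 10, seed = 7))
})

burst_skna <- function() memo("burst_skna",
  highpass_skna(downsample_ecg(channel_tbl(burst_recording(), "ecg"))))

# fraction of truth bursts overlapped by a detection, and vice versa
burst_match <- function(truth, detected) {
  ov <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  sens <- mean(vapply(seq_len(nrow(truth)), function(i)
    any(ov(truth$onset[i], truth$offset[i], detected$onset, detected$offset) > 0),
    logical(1)))
  prec <- mean(vapply(seq_len(nrow(detected)), function(i)
    any(ov(detected$onset[i], detected$offset[i], truth$onset, truth$offset) > 0),
    logical(1)))
  c(sensitivity = sens, precision = prec)
}

# brute-force dual-threshold state machine over samples (oracle)
brute_force_bursts <- function(t, e, hi, lo) {
  onsets <- offsets <- numeric()
  i <- 1L
  n <- length(e)
  dt <- t[2] - t[1]
  while (i <= n) {
    if (e[i] >= hi) {
      j <- i
      while (j > 1L && e[j - 1L] >= lo) j <- j - 1L
      k <- i
      while (k < n && e[k + 1L] >= lo) k <- k + 1L
      onsets <- c(onsets, t[j])
      offsets <- c(offsets, t[k] + dt)
      i <- k + 1L
    }
    i <- i + 1L
  }
  tibble::tibble(onset = onsets, offset = offsets)
}

# brute-force RMSSD via an explicit loop (oracle)
brute_force_rmssd <- function(nn) {
  s <- 0
  for (i in seq_len(length(nn) - 1)) s <- s + (nn[i + 1] - nn[i])^2
  sqrt(s / (length(nn) - 1))
}

# synthetic NN tachogram: mean_ms plus a sinusoidal modulation, with real
# beat times accumulated from the intervals themselves
modulated_nn <- function(duration = 300, mean_ms = 200, amp_ms = 10, f_mod = 0.5) {
  t <- 0
  ts <- nn <- numeric()
  while (t < duration) {
    v <- mean_ms + amp_ms * sin(2 * pi * f_mod * t)
    t <- t + v / 1000
    ts <- c(ts, t)
    nn <- c(nn, v)
  }
  tibble::tibble(t = ts, nn = nn, valid = TRUE)
}
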