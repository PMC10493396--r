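test_that("the amplitude envelope honours the mean-1 normalization contract", {
  skna <- burst_skna()
  env <- amplitude_envelope(skna)
  expect_equal(mean(env$env), 1, tolerance = 1e-9)
  expect_true(all(env$env >= 0))
  expect_identical(nrow(env), nrow(skna))
  expect_error(amplitude_envelope(numeric(2000), fs = 2000), "normalize")
})

test_that("a pure in-band tone has a flat envelope that scales linearly", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 700 * t)
  env <- amplitude_envelope(tone, fs = fs)
  core <- env$env[200:(length(t) - 200)]
  expect_lt(sd(core) / mean(core), 0.05)
  # doubled second half -> envelope ratio ~2
  tone2 <- tone * rep(c(1, 2), each = length(t) / 2)
  env2 <- amplitude_envelope(tone2, fs = fs)
  h1 <- mean(env2$env[200:(length(t) / 2 - 200)])
  h2 <- mean(env2$env[(length(t) / 2 + 200):(length(t) - 200)])
  expect_equal(h2 / h1, 2, tolerance = 0.05)
})

test_that("dual-threshold detection brackets rectangular envelope steps", {
  dt <- 1 / 100
  t <- seq(0, 10 - dt, by = dt)
  base <- rep(0.5, length(t))
  # sub-threshold envelope -> nothing
  expect_identical(nrow(detect_bursts(tibble::tibble(t = t, env = base), 2, 1)), 0L)
  # one rectangular step to 3 between 4 and 5 s
  e <- base
  e[t >= 4 & t < 5] <- 3
  out <- detect_bursts(tibble::tibble(t = t, env = e), 2, 1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$onset, 4, tolerance = dt + 1e-9)
  expect_equal(out$offset, 5, tolerance = dt + 1e-9)
  expect_equal(out$peak_norm_amp, 3)
  # two separated steps -> two bursts in time order
  e[t >= 7 & t < 7.5] <- 3
  out2 <- detect_bursts(tibble::tibble(t = t, env = e), 2, 1)
  expect_identical(nrow(out2), 2L)
  expect_true(!is.unsorted(out2$onset, strictly = TRUE))
  expect_error(detect_bursts(tibble::tibble(t = t, env = e), 1, 2), "thresh")
})

test_that("detection matches a brute-force state machine on random envelopes", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 400
    t <- seq(0, n / 100 - 1 / 100, by = 1 / 100)
    e <- abs(stats::filter(rnorm(n, 1, 0.8), rep(0.2, 5), circular = TRUE))
    env <- tibble::tibble(t = t, env = as.numeric(e))
    mine <- detect_bursts(env, 2, 1, min_duration = 0, merge_gap = 0)
    oracle <- brute_force_bursts(t, env$env, 2, 1)
    expect_equal(mine$onset, oracle$onset)
    expect_equal(mine$offset, oracle$offset)
  }
})

test_that("burst detection is invariant to uniform scaling of the raw signal", {
  skna <- burst_skna()
  a <- detect_bursts(amplitude_envelope(skna))
  scaled <- dplyr::mutate(skna, value = value * 37)
  b <- detect_bursts(amplitude_envelope(scaled))
  expect_equal(a$onset, b$onset, tolerance = 1e-9)
  expect_equal(a$offset, b$offset, tolerance = 1e-9)
})

test_that("planted bursts are recovered with sensitivity and precision >= 0.9", {
  rec <- burst_recording() # SNR ~3.6 in the SKNA band
  det <- detect_bursts(amplitude_envelope(burst_skna()))
  m <- burst_match(rec$truth$bursts, det)
  expect_gte(m[["sensitivity"]], 0.9)
  expect_gte(m[["precision"]], 0.9)
})

test_that("burst statistics count onset-attributed bursts over the interval", {
  ev <- tibble::tibble(onset = c(0.2, 0.7), offset = c(0.4, 1.3),
                       duration = c(0.2, 0.6), peak_norm_amp = c(3, 3))
  s <- burst_stats(ev, c(0, 1))
  expect_identical(s$n_bursts, 2L)
  expect_equal(s$bursts_per_second, 2)
  expect_equal(s$mean_duration, 0.4)
  empty <- burst_stats(ev[0, ], c(0, 1))
  expect_identical(empty$n_bursts, 0L)
  expect_equal(empty$bursts_per_second, 0)
  expect_error(burst_stats(ev, c(1, 1)), "positive")
})

test_that("planted burst rate is recovered on a clean envelope", {
  cfg <- sim_config(duration = 60, ad_events = list(), baseline_burst_rate = 1,
                    burst_duration_mean = 0.15, burst_amplitude = 10,
                    ecg_noise_sd = 2, seed = 12)
  rec <- simulate_recording(cfg)
  skna <- highpass_skna(downsample_ecg(channel_tbl(rec, "ecg")))
  det <- detect_bursts(amplitude_envelope(skna))
  truth_rate <- nrow(rec$truth$bursts) / 60
  got <- burst_stats(det, c(0, 60))$bursts_per_second
  expect_equal(got, truth_rate, tolerance = 0.15)
})
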