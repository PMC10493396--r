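test_that("Lomb periodogram locates a known RR modulation frequency", {
  nn <- modulated_nn(duration = 300, f_mod = 0.5)
  psd <- lomb_psd(nn)
  expect_equal(psd$freq[which.max(psd$power)], 0.5, tolerance = 0.002 + 1e-9)
})

test_that("linear detrending removes a pure trend", {
  t <- cumsum(rep(0.2, 100))
  nn <- tibble::tibble(t = t, nn = 200 + 0.5 * t, valid = TRUE)
  with_trend <- lomb_psd(nn, detrend = FALSE, window = "none")
  expect_error(lomb_psd(nn, detrend = TRUE, window = "none"), "zero variance")
  nn$nn <- nn$nn + rnorm(100, 0, 0.01)
  detr <- lomb_psd(nn, detrend = TRUE, window = "none")
  expect_lt(sum(detr$power), 0.01 * sum(with_trend$power))
})

test_that("Lomb equals the FFT periodogram on uniformly sampled data", {
  set.seed(5)
  n <- 256
  fs <- 4
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 0.5 * t) + 0.5 * cos(2 * pi * 1.25 * t) + rnorm(n, 0, 0.3)
  nn <- tibble::tibble(t = t, nn = x, valid = TRUE)
  grid <- (1:(n / 2 - 1)) * fs / n # Fourier frequencies, DC/Nyquist excluded
  mine <- lomb_psd(nn, freq_grid = grid, detrend = FALSE, window = "none")
  xc <- x - mean(x)
  ref <- (Mod(fft(xc))^2 / n)[2:(n / 2)]
  expect_equal(mine$power, ref, tolerance = 0.02)
  # Parseval-style: total periodogram power ~ series variance
  expect_equal(2 * sum(mine$power) / n, mean(xc^2), tolerance = 0.02)
})

test_that("Lomb power ignores a constant offset in the NN series", {
  nn <- modulated_nn(duration = 120, f_mod = 0.4)
  a <- lomb_psd(nn)
  b <- lomb_psd(dplyr::mutate(nn, nn = nn + 500))
  expect_equal(a$power, b$power, tolerance = 1e-6)
})

test_that("band powers are width-proportional for a flat PSD and sum to 100", {
  psd <- tibble::tibble(freq = seq(0, 2.5, by = 0.001), power = 1)
  bp <- band_powers(psd)
  expect_equal(bp$vlf_pct, 8, tolerance = 0.1)
  expect_equal(bp$lf_pct, 22, tolerance = 0.1)
  expect_equal(bp$hf_pct, 70, tolerance = 0.1)
  expect_equal(bp$vlf_pct + bp$lf_pct + bp$hf_pct, 100, tolerance = 1e-6)
})

test_that("power concentrated in one LF line dominates the LF percentage", {
  f <- seq(0, 2.5, by = 0.002)
  p <- 1e-9 + exp(-((f - 0.5) / 0.005)^2)
  bp <- band_powers(tibble::tibble(freq = f, power = p))
  expect_gt(bp$lf_pct, 99)
  expect_gt(bp$lf_hf_ratio, 100)
})

test_that("moving power from HF to LF raises the LF/HF ratio", {
  f <- seq(0, 2.5, by = 0.002)
  base <- tibble::tibble(freq = f, power = 1)
  shifted <- dplyr::mutate(base,
    power = power + ifelse(f > 0.2 & f <= 0.75, 0.5, 0) -
      ifelse(f > 0.75, 0.15, 0))
  expect_gt(band_powers(shifted)$lf_hf_ratio, band_powers(base)$lf_hf_ratio)
})

test_that("percentage normalization holds on seeded random spectra", {
  set.seed(7)
  for (i in 1:20) {
    psd <- tibble::tibble(freq = seq(0, 2.5, by = 0.01),
                          power = rexp(251))
    bp <- band_powers(psd)
    expect_equal(bp$vlf_pct + bp$lf_pct + bp$hf_pct, 100, tolerance = 1e-6)
  }
})

test_that("spectrogram segmentation and tone localization follow nfft/overlap", {
  fs <- 100
  nfft <- 4096
  x <- sin(2 * pi * 1 * (0:(2 * nfft - 1)) / fs)
  sp <- fft_spectrogram(x, fs = fs, nfft = nfft, overlap = 0.9375)
  hop <- nfft * (1 - 0.9375)
  expect_identical(length(sp$times),
                   as.integer(floor((2 * nfft - nfft) / hop) + 1))
  argmax <- sp$freqs[apply(sp$power, 2, which.max)]
  expect_true(all(abs(argmax - 1) <= fs / nfft + 1e-9))
  expect_error(fft_spectrogram(x[1:100], fs = fs, nfft = nfft), "smaller nfft")
})

test_that("white noise gives an approximately flat average spectrum", {
  set.seed(21)
  fs <- 100
  x <- rnorm(40 * 2048)
  sp <- fft_spectrogram(x, fs = fs, nfft = 2048, overlap = 0.5)
  avg <- rowMeans(sp$power)
  expect_lt(max(avg), 3 * median(avg))
})

test_that("dominant frequency takes the maximum with lowest-frequency ties", {
  spec <- tibble::tibble(freq = c(1, 2, 5, 7), power = c(0, 3, 3, 1))
  expect_equal(dominant_frequency(spec)$freq, 2)
  spec2 <- tibble::tibble(freq = c(0, 7), power = c(9, 2))
  expect_equal(dominant_frequency(spec2, exclude_dc = TRUE)$freq, 7)
  expect_error(dominant_frequency(tibble::tibble(freq = 1, power = 0)), "zero")
})

test_that("planted slow ISKNA rhythms are recovered at the planted frequencies", {
  # baseline-like 1.4 Hz and AD-like 0.08 Hz oscillations planted directly
  # in a synthetic 10 Hz ISKNA series
  fs <- 10
  t <- (0:(600 * fs - 1)) / fs
  for (f0 in c(1.4, 0.08)) {
    x <- 1 + 0.5 * sin(2 * pi * f0 * t)
    sp <- fft_spectrogram(x, fs = fs, nfft = 4096, overlap = 0.5,
                          range = c(0, 5))
    dom <- dominant_frequency(sp, exclude_dc = TRUE)
    expect_lt(abs(dom$freq - f0), fs / 4096 + 1e-9) # within one bin
  }
})
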