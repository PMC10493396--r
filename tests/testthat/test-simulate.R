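test_that("no-event, noise-free configuration gives a constant SBP trace", {
  cfg <- sim_config(duration = 10, ad_events = list(), sbp_noise_sd = 0,
                    baseline_sbp = 118, seed = 1)
  rec <- simulate_recording(cfg)
  expect_true(all(rec$channels$bp$values == 118))
})

test_that("identical configurations give bit-identical recordings", {
  cfg <- sim_config(duration = 12, ad_events = list(ad_scenario(5, event_duration = 4,
                                                                sbp_delay = 1,
                                                                hr_drop_delay = 1,
                                                                skna_delay = 0.5)),
                    seed = 99)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  for (nm in names(a$channels)) {
    expect_identical(a$channels[[nm]]$values, b$channels[[nm]]$values)
  }
  expect_identical(a$truth$bursts, b$truth$bursts)
})

test_that("planted SBP rise is visible at the configured magnitude", {
  sc <- ad_scenario(40, sbp_rise = 30, sbp_delay = 10, hr_drop_delay = 15,
                    event_duration = 40)
  cfg <- sim_config(duration = 100, ad_events = list(sc), sbp_noise_sd = 1,
                    seed = 11)
  rec <- simulate_recording(cfg)
  rise <- max(rec$channels$bp$values) - 120
  expect_gte(rise, 28)
  expect_lte(rise, 32)
})

test_that("marker channel carries exactly one pulse per scenario", {
  sc1 <- ad_scenario(20, event_duration = 10, sbp_delay = 2, hr_drop_delay = 3,
                     skna_delay = 1)
  sc2 <- ad_scenario(50, event_duration = 10, sbp_delay = 2, hr_drop_delay = 3,
                     skna_delay = 1)
  rec <- simulate_recording(sim_config(duration = 80, ad_events = list(sc1, sc2),
                                       seed = 2))
  expect_identical(sum(rec$channels$marker$values != 0), 2L)
  expect_equal(marker_times(rec), c(20, 50), tolerance = 1e-4)
})

test_that("configs whose event windows exceed the duration are rejected", {
  sc <- ad_scenario(50, event_duration = 60)
  expect_error(sim_config(duration = 60, ad_events = list(sc)), "exceeds")
  expect_error(sim_config(duration = 10, burst_carrier_band = c(500, 6000)),
               "burst_carrier_band")
})

test_that("a noise-free envelope threshold recovers every planted burst train", {
  cfg <- sim_config(duration = 60, ad_events = list(), baseline_burst_rate = 0.4,
                    burst_amplitude = 10, ecg_noise_sd = 0, seed = 3)
  rec <- simulate_recording(cfg)
  skna <- highpass_skna(downsample_ecg(channel_tbl(rec, "ecg")))
  sm <- as.numeric(stats::filter(abs(skna$value), rep(1 / 20, 20), sides = 2))
  sm[is.na(sm)] <- 0
  r <- rle(sm > 1) # 10% of the planted burst amplitude
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 1) { # bridge sub-refractory dips inside one train
    keep <- c(TRUE, seg[-1, 1] - seg[-nrow(seg), 2] > 100)
    g <- cumsum(keep)
    seg <- cbind(tapply(seg[, 1], g, min), tapply(seg[, 2], g, max))
  }
  seg <- seg[seg[, 2] - seg[, 1] > 20, , drop = FALSE]
  expect_identical(nrow(seg), nrow(rec$truth$bursts))
})

test_that("recordings round-trip through the CSV container", {
  rec <- simulate_recording(sim_config(duration = 10, seed = 5,
                                       ad_events = list()))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  for (nm in names(rec$channels)) {
    expect_identical(length(back$channels[[nm]]$values),
                     length(rec$channels[[nm]]$values))
    expect_equal(back$channels[[nm]]$values, rec$channels[[nm]]$values,
                 tolerance = 1e-6)
    expect_identical(back$channels[[nm]]$fs, rec$channels[[nm]]$fs)
  }
  expect_identical(back$meta$subject, rec$meta$subject)
})

test_that("a recording missing its marker channel is refused by name", {
  rec <- simulate_recording(sim_config(duration = 5, seed = 5,
                                       ad_events = list()))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta$channels$marker <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  file.remove(file.path(dir, "marker.csv"))
  expect_error(read_recording(dir), "marker")
})
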