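# End-to-end orchestration: simulate -> extract SKNA/ISKNA -> bursts ->
# HRV -> spectra -> AD events and onset delays -> report tables, with one
# parameter list carrying every stage's knobs.

#' Default analysis parameters
#'
#' One list holding every stage's tunables, with the standard values of the
#' SKNA processing chain as defaults (2 kHz working rate, 500 Hz high-pass,
#' 100 ms ISKNA integration, 500-995 Hz burst band, dual thresholds 2.0/1.0,
#' rat VLF/LF/HF bands, 128000-point FFT at 93.75% overlap, 15 mmHg AD rise
#' criterion, 60 s pre-marker baseline, 20% peak-significance rule).
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(
    target_fs = 2000, hp_cutoff = 500, iskna_window = 0.1,
    burst_band = c(500, 995), thresh_hi = 2.0, thresh_lo = 1.0,
    min_burst_duration = 0.02, merge_gap = 0.01,
    nn_floor_ms = 60, nn_ceiling_ms = 400,
    hrv_window = 10, hrv_step = 1,
    bands = rat_bands(),
    lomb_grid = seq(0.002, 2.5, by = 0.002),
    nfft = 128000, overlap = 0.9375,
    rise_threshold = 15, baseline_window = 60, search_window = 120,
    brady_frac = 0.10, brady_sustain = 2, peak_frac = 0.20
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    abort(paste("unknown parameter(s):", paste(unknown, collapse = ", ")))
  }
  p[names(over)] <- over
  structure(p, class = c("pipeline_params", "list"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Analyze one recording end to end
#'
#' Runs the full chain on a `physio_recording`: downsample the ECG to the
#' working rate, high-pass to SKNA, integrate to ISKNA, detect bursts on the
#' mean-normalized envelope, detect R peaks and build NN/HRV feature series,
#' detect AD events around the marker pulses, estimate per-feature onset
#' delays and SKNA lead time, and compute Lomb band powers for the
#' pre-marker baseline and each event window. Deterministic for a fixed
#' recording and parameter set.
#'
#' @param rec A `physio_recording` (or a path readable by
#'   [read_recording()]).
#' @param params A [pipeline_params()] list.
#' @return A list of class `ad_analysis` with elements `iskna`, `bursts`,
#'   `features` (sliding HRV), `events`, `delays`, `lead_times`,
#'   `band_powers`, `params`.
#' @export
analyze_recording <- function(rec, params = pipeline_params()) {
  if (is.character(rec)) rec <- read_recording(rec)

  skna <- with_stage("skna_extract", {
    ecg <- channel_tbl(rec, "ecg")
    ds <- downsample_ecg(ecg, target_fs = params$target_fs)
    highpass_skna(ds, cutoff = params$hp_cutoff)
  })
  iskna <- with_stage("skna_extract",
    integrate_skna(skna, window = params$iskna_window))

  env <- with_stage("burst_detect",
    amplitude_envelope(skna, band = params$burst_band))
  bursts <- with_stage("burst_detect",
    detect_bursts(env, params$thresh_hi, params$thresh_lo,
                  params$min_burst_duration, params$merge_gap))

  hrv <- with_stage("hrv_features", {
    ds <- downsample_ecg(channel_tbl(rec, "ecg"), target_fs = params$target_fs)
    peaks <- detect_r_peaks(ds)
    nn <- rr_intervals(peaks, params$nn_floor_ms, params$nn_ceiling_ms)
    list(nn = nn, hr = heart_rate_series(nn),
         sliding = hrv_sliding_features(nn, params$hrv_window, params$hrv_step))
  })

  events <- with_stage("event_timing", {
    sbp <- channel_tbl(rec, "bp")
    mk <- marker_times(rec)
    if (!length(mk)) {
      tibble()
    } else {
      detect_ad_events(sbp, hrv$hr, mk,
                       rise_threshold = params$rise_threshold,
                       baseline_window = params$baseline_window,
                       search_window = params$search_window,
                       brady_frac = params$brady_frac,
                       brady_sustain = params$brady_sustain)
    }
  })

  delays <- tibble()
  leads <- tibble()
  bandpow <- tibble()
  if (nrow(events)) {
    feats <- list(
      iskna = iskna_sliding_mean(iskna, params$hrv_window, params$hrv_step),
      bursts_per_s = burst_rate_series(
        bursts, c(min(iskna$t), max(iskna$t)),
        window = params$hrv_window, step = params$hrv_step),
      rmssd = select(mutate(hrv$sliding, value = .data$rmssd_ms), "t", "value"),
      hr = hrv$hr
    )
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      d <- with_stage("event_timing",
        feature_delays(ev, feats, peak_frac = params$peak_frac))
      d$event <- i
      delays <- bind_rows(delays, d)
      lt <- tryCatch(lead_time(d), error = function(e) NA_real_)
      leads <- bind_rows(leads, tibble(event = i, lead_time = lt))

      bandpow <- bind_rows(bandpow, with_stage("spectral", {
        base_seg <- c(ev$window_start, ev$crd_onset)
        ad_seg <- c(ev$crd_onset, ev$window_end)
        seg_bp <- function(seg, label) {
          nnw <- hrv$nn[hrv$nn$t >= seg[1] & hrv$nn$t <= seg[2], ]
          if (sum(nnw$valid) < 8) return(tibble())
          band_powers(lomb_psd(nnw, params$lomb_grid), params$bands,
                      segment = seg, condition_label = label) %>%
            mutate(event = i)
        }
        bind_rows(seg_bp(base_seg, "baseline"), seg_bp(ad_seg, "AD"))
      }))
    }
  }

  structure(list(iskna = iskna, bursts = bursts, features = hrv$sliding,
                 nn = hrv$nn, events = events, delays = delays,
                 lead_times = leads, band_powers = bandpow,
                 meta = rec$meta, params = params),
            class = "ad_analysis")
}

#' @export
print.ad_analysis <- function(x, ...) {
  cat("<ad_analysis>", x$meta$subject %||% "", "\n")
  cat(sprintf("  %d bursts, %d AD trial(s), %d accepted\n",
              nrow(x$bursts), nrow(x$events),
              if (nrow(x$events)) sum(x$events$accepted) else 0L))
  if (nrow(x$lead_times)) {
    cat(sprintf("  lead time(s): %s s\n",
                paste(round(x$lead_times$lead_time, 1), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-event onset delays of an analysis
#'
#' @param x An `ad_analysis`.
#' @param ... Unused.
#' @return Tibble `event`, `feature`, `delay`, `peak_time`.
#' @export
tidy.ad_analysis <- function(x, ...) {
  if (!nrow(x$delays)) return(tibble(event = integer(), feature = character(),
                                     delay = numeric(), peak_time = numeric()))
  select(x$delays, "event", "feature", "delay", "peak_time")
}

#' One-row summary of an analysis
#'
#' @param x An `ad_analysis`.
#' @param ... Unused.
#' @return Tibble with trial counts, mean delays and mean lead time.
#' @export
glance.ad_analysis <- function(x, ...) {
  d <- x$delays
  mean_of <- function(f) {
    v <- d$delay[d$feature == f]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  tibble(
    n_trials = nrow(x$events),
    n_accepted = if (nrow(x$events)) sum(x$events$accepted) else 0L,
    n_bursts = nrow(x$bursts),
    iskna_delay = mean_of("iskna"),
    bursts_delay = mean_of("bursts_per_s"),
    rmssd_delay = mean_of("rmssd"),
    hr_delay = mean_of("hr"),
    sbp_delay = mean_of("sbp"),
    lead_time = if (nrow(x$lead_times)) mean(x$lead_times$lead_time, na.rm = TRUE)
                else NA_real_
  )
}

#' Simulate recordings and write them with their ground truth
#'
#' @param config A [sim_config()]; per-subject seeds are derived from
#'   `config$seed` when `n_subjects > 1`.
#' @param out_dir Output directory; one subdirectory per subject, each with
#'   channel CSVs, `meta.json` (which carries the planted truth) and a
#'   `truth.json` convenience copy.
#' @param n_subjects Number of recordings.
#' @return Paths of the written recording directories, invisibly.
#' @export
run_simulate <- function(config, out_dir, n_subjects = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- if (n_subjects == 1) config$seed else {
    set.seed(config$seed)
    sample.int(2^30, n_subjects)
  }
  paths <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- seeds[i]
    rec <- simulate_recording(cfg, subject = sprintf("S%d", i))
    p <- file.path(out_dir, sprintf("S%d", i))
    write_recording(rec, p)
    jsonlite::write_json(rec$truth[c("ad_events", "bursts")],
                         file.path(p, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths[i] <- p
  }
  invisible(paths)
}

#' Analyze a recording and write the result tables
#'
#' @param rec A `physio_recording` or recording directory path.
#' @param params A [pipeline_params()] list.
#' @param out_dir Optional directory for CSV outputs (`iskna.csv`,
#'   `bursts.csv`, `hrv_features.csv`, `events.csv`, `delays.csv`,
#'   `band_powers.csv`) plus a `params.json` echo.
#' @return The `ad_analysis` object, invisibly when writing.
#' @export
run_analyze <- function(rec, params = pipeline_params(), out_dir = NULL) {
  res <- analyze_recording(rec, params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(setNames(res$iskna, c("t_start_s", "iskna_uVs")),
                     file.path(out_dir, "iskna.csv"))
    readr::write_csv(setNames(res$bursts,
                              c("onset_s", "offset_s", "duration_s",
                                "peak_norm_amp")),
                     file.path(out_dir, "bursts.csv"))
    readr::write_csv(res$features, file.path(out_dir, "hrv_features.csv"))
    readr::write_csv(res$events, file.path(out_dir, "events.csv"))
    readr::write_csv(tidy(res), file.path(out_dir, "delays.csv"))
    readr::write_csv(res$band_powers, file.path(out_dir, "band_powers.csv"))
    jsonlite::write_json(res$params[setdiff(names(res$params), "bands")],
                         file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Aggregate a per-subject band-power table into a report
#'
#' @param band_table Long tibble as produced by [band_power_fixture()] or a
#'   path to such a CSV.
#' @param out_file Optional CSV path for the aggregated table.
#' @return The aggregated tibble from [aggregate_band_table()].
#' @export
run_report <- function(band_table, out_file = NULL) {
  if (is.character(band_table)) {
    band_table <- readr::read_csv(band_table, show_col_types = FALSE)
  }
  out <- aggregate_band_table(band_table)
  if (!is.null(out_file)) readr::write_csv(out, out_file)
  out
}

#' Load pipeline parameters from a YAML config file
#'
#' @param path YAML file whose keys mirror [pipeline_params()] names.
#' @return A `pipeline_params` list.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_params, cfg)
}

#' Recover planted onset delays across a simulated cohort
#'
#' Runs the full analysis on each recording of a [simulate_cohort()] result
#' and pairs the recovered ISKNA/SBP delays and lead time with the
#' configured (planted) values.
#'
#' @param cohort A list from [simulate_cohort()].
#' @param params A [pipeline_params()] list.
#' @return Tibble with one row per subject: configured and recovered
#'   `skna_delay`/`sbp_delay` and the corresponding lead times.
#' @export
recover_cohort_delays <- function(cohort, params = pipeline_params()) {
  purrr::map_dfr(seq_along(cohort$recordings), function(i) {
    g <- glance(analyze_recording(cohort$recordings[[i]], params))
    cfg <- cohort$configured[i, ]
    tibble(subject = cfg$subject,
           skna_delay_true = cfg$skna_delay,
           sbp_delay_true = cfg$sbp_delay,
           lead_time_true = cfg$sbp_delay - cfg$skna_delay,
           skna_delay_est = min(g$iskna_delay, g$bursts_delay, na.rm = TRUE),
           sbp_delay_est = g$sbp_delay,
           lead_time_est = g$lead_time)
  })
}
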