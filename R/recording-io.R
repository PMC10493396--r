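# Plain-text container for multichannel recordings: one CSV per channel
# (`time_s,value`, '.' decimal, UTF-8) plus a JSON sidecar with sampling
# rates, metadata and any planted ground truth.

#' Write a recording to a directory
#'
#' Writes one `<channel>.csv` file per channel with columns `time_s,value`
#' and a `meta.json` sidecar holding per-channel sampling rates, subject/day
#' metadata and the simulation ground truth when present.
#'
#' @param rec A `physio_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "physio_recording")) abort("`rec` must be a physio_recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    readr::write_csv(
      tibble(time_s = (seq_along(ch$values) - 1L) / ch$fs, value = ch$values),
      file.path(path, paste0(nm, ".csv"))
    )
  }
  sidecar <- list(
    channels = purrr::map(rec$channels, function(ch)
      list(fs = ch$fs, n = length(ch$values))),
    meta = rec$meta,
    truth = if (!is.null(rec$truth)) {
      list(ad_events = rec$truth$ad_events, bursts = rec$truth$bursts,
           beats = rec$truth$beats)
    }
  )
  jsonlite::write_json(sidecar, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Directory containing `<channel>.csv` files and `meta.json`.
#' @param require_channels Channels that must be present; an error names any
#'   absent one.
#' @return A `physio_recording`.
#' @export
read_recording <- function(path, require_channels = c("ecg", "bp", "marker")) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) abort(sprintf("no meta.json found in '%s'", path))
  sidecar <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  missing <- setdiff(require_channels, names(sidecar$channels))
  if (length(missing)) {
    abort(sprintf("recording at '%s' is missing channel(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  channels <- purrr::imap(sidecar$channels, function(info, nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) abort(sprintf("channel file missing: %s", f))
    d <- readr::read_csv(f, col_types = readr::cols(
      time_s = readr::col_double(), value = readr::col_double()))
    if (nrow(d) != info$n) {
      abort(sprintf("channel '%s': %d samples on disk, %d in sidecar",
                    nm, nrow(d), info$n))
    }
    list(values = d$value, fs = as.numeric(info$fs))
  })
  truth <- NULL
  if (!is.null(sidecar$truth)) {
    truth <- list(ad_events = as_tibble(sidecar$truth$ad_events),
                  bursts = as_tibble(sidecar$truth$bursts),
                  beats = sidecar$truth$beats)
  }
  structure(list(channels = channels, meta = sidecar$meta, truth = truth),
            class = "physio_recording")
}
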