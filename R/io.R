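# Plain-text persistence for recordings, events and spike trains.
#
# A recording is stored as a directory:
#   lfp.csv      one column per channel, full-precision (%.17g) mV samples
#   channels.csv channel_id, region, depth_um
#   meta.json    fs_hz, t0_s, boundaries_s
# Doubles are written with 17 significant digits, so a write/read
# round-trip reproduces the samples exactly.

#' Write a recording to a directory
#'
#' @param rec An `lfp_recording`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- t(rec$samples)
  colnames(mat) <- rec$channels$channel_id
  df <- as_tibble(as.data.frame(mat, check.names = FALSE))
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::everything(), ~ sprintf("%.17g", .x)
  ))
  readr::write_csv(df, file.path(dir, "lfp.csv"))
  readr::write_csv(rec$channels, file.path(dir, "channels.csv"))
  jsonlite::write_json(
    list(fs_hz = rec$fs_hz, t0_s = rec$t0_s,
         boundaries_s = as.numeric(rec$boundaries_s)),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing `lfp.csv`, `channels.csv`, `meta.json`.
#' @return An `lfp_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  channels <- readr::read_csv(
    file.path(dir, "channels.csv"),
    col_types = readr::cols(
      channel_id = readr::col_character(),
      region = readr::col_character(),
      depth_um = readr::col_double()
    )
  )
  # base read.csv parses doubles with correctly rounded strtod, so the
  # %.17g round-trip is bit-exact
  df <- utils::read.csv(file.path(dir, "lfp.csv"), check.names = FALSE,
                        colClasses = "numeric")
  m <- t(as.matrix(df[, channels$channel_id, drop = FALSE]))
  dimnames(m) <- NULL
  new_recording(
    m,
    fs_hz = meta$fs_hz, channels = channels, t0_s = meta$t0_s,
    boundaries_s = as.numeric(meta$boundaries_s %||% numeric(0))
  )
}

#' Write / read an event table
#'
#' Events are stored as CSV with the columns `kind, channel_id, start_s,
#' end_s, peak_s, amplitude, inst_freq_hz, latency_pct` (missing columns
#' are filled with `NA`).
#'
#' @param events Tibble of events.
#' @param path CSV path.
#' @return `path` invisibly, or the events tibble.
#' @export
write_events <- function(events, path) {
  cols <- c("kind", "channel_id", "start_s", "end_s", "peak_s",
            "amplitude", "inst_freq_hz", "latency_pct")
  for (c_ in setdiff(cols, names(events))) events[[c_]] <- NA
  readr::write_csv(events[, cols], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    kind = readr::col_character(),
    channel_id = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Write / read a spike-timestamp table
#'
#' CSV with columns `unit_id, time_s` and optionally `state`.
#'
#' @param spikes Tibble with at least `unit_id` and `time_s`.
#' @param path CSV path.
#' @return `path` invisibly, or the spikes tibble.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(spikes, path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    unit_id = readr::col_character(),
    time_s = readr::col_double(),
    .default = readr::col_character()
  ))
}
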