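# Recording container and pre-processing primitives.

#' Construct an LFP recording
#'
#' Bundles a channels-by-time voltage matrix with its sampling rate and
#' per-channel metadata. Internal units are millivolts and seconds; sample
#' indices are 1-based in R code and all intervals are half-open
#' `[start, end)`.
#'
#' @param samples Numeric matrix, channels x time, in millivolts. A bare
#'   numeric vector is treated as a single channel.
#' @param fs_hz Sampling rate in samples per second.
#' @param channels Tibble with columns `channel_id`, `region` and
#'   optionally `depth_um`. Defaults to `ch1, ch2, ...` with region
#'   `"other"`. Regions follow the usual labels (`ACC`, `PrL`, `IL`, `DP`,
#'   `CA1`, `other`).
#' @param t0_s Start time of the recording in seconds.
#' @param boundaries_s Times (seconds, relative to `t0_s`) at which
#'   independently recorded segments were concatenated. No detected state
#'   or event may straddle a boundary.
#' @return An object of class `lfp_recording`.
#' @export
new_recording <- function(samples, fs_hz, channels = NULL, t0_s = 0,
                          boundaries_s = numeric(0)) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix.")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.")
  }
  if (any(!is.finite(samples))) {
    abort("`samples` contains non-finite values.")
  }
  if (is.null(channels)) {
    channels <- tibble(
      channel_id = paste0("ch", seq_len(nrow(samples))),
      region = "other",
      depth_um = NA_real_
    )
  }
  channels <- as_tibble(channels)
  if (!"depth_um" %in% names(channels)) channels$depth_um <- NA_real_
  if (nrow(channels) != nrow(samples)) {
    abort("`channels` must have one row per channel.")
  }
  if (anyDuplicated(channels$channel_id)) {
    abort("`channel_id` must be unique within a recording.")
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, channels = channels,
         t0_s = t0_s, boundaries_s = sort(boundaries_s)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %d channel(s), %.1f s @ %g Hz, %d boundary(ies)\n",
    nrow(x$samples), ncol(x$samples) / x$fs_hz, x$fs_hz,
    length(x$boundaries_s)
  ))
  print(x$channels, n = 6)
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `lfp_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs_hz

#' Extract one channel as a numeric vector
#' @param rec An `lfp_recording`.
#' @param channel_id Channel identifier (string) or index.
#' @return Numeric vector of samples (mV).
#' @export
channel_signal <- function(rec, channel_id) {
  i <- if (is.character(channel_id)) {
    match(channel_id, rec$channels$channel_id)
  } else {
    as.integer(channel_id)
  }
  if (is.na(i) || i < 1 || i > nrow(rec$samples)) {
    abort(sprintf("Unknown channel `%s`.", as.character(channel_id)))
  }
  rec$samples[i, ]
}

#' Canonical frequency bands
#'
#' The band edges used throughout the package: slow oscillation (SO)
#' 0.1-0.9 Hz, theta 4-7.9 Hz, spindle 8-15 Hz, beta 15-29.9 Hz, gamma
#' 30-79.9 Hz, high-gamma and ripple 80-130 Hz.
#'
#' @return A tibble with columns `name`, `lo_hz`, `hi_hz`.
#' @export
so_bands <- function() {
  tibble(
    name = c("so", "theta", "spindle", "beta", "gamma", "high_gamma",
             "ripple"),
    lo_hz = c(0.1, 4, 8, 15, 30, 80, 80),
    hi_hz = c(0.9, 7.9, 15, 29.9, 79.9, 130, 130)
  )
}

#' Define a frequency band
#'
#' @param name Band label, or the name of a canonical band from
#'   [so_bands()] (in which case the edges are looked up).
#' @param lo_hz,hi_hz Band edges in Hz (`0 < lo_hz < hi_hz`).
#' @return A `band_spec` (named list).
#' @export
band_spec <- function(name, lo_hz = NULL, hi_hz = NULL) {
  if (is.null(lo_hz) || is.null(hi_hz)) {
    bands <- so_bands()
    i <- match(name, bands$name)
    if (is.na(i)) abort(sprintf("Unknown canonical band `%s`.", name))
    lo_hz <- bands$lo_hz[i]
    hi_hz <- bands$hi_hz[i]
  }
  if (!(lo_hz > 0 && lo_hz < hi_hz)) {
    abort("Band edges must satisfy 0 < lo_hz < hi_hz.")
  }
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_spec")
}

as_band_spec <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1) return(band_spec(band))
  if (is.list(band)) return(band_spec(band$name %||% "custom",
                                      band$lo_hz, band$hi_hz))
  abort("`band` must be a band_spec, a canonical band name, or a list.")
}

check_band <- function(band, fs_hz) {
  if (band$hi_hz >= fs_hz / 2) {
    abort(sprintf(
      "Band `%s` (%g-%g Hz) reaches the Nyquist frequency (%g Hz).",
      band$name, band$lo_hz, band$hi_hz, fs_hz / 2
    ))
  }
  band
}

# Apply a per-channel vector function to every channel of a recording.
map_channels <- function(rec, f) {
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    out$samples[i, ] <- f(rec$samples[i, ])
  }
  out
}

#' Zero-phase power-line notch filter
#'
#' Removes mains contamination with a frequency-domain notch: full stop
#' within +/-1 Hz of `line_hz`, raised-cosine shoulders out to +/-2 Hz and
#' exactly unit gain elsewhere. Zero-phase by construction.
#'
#' @param x An `lfp_recording` or a numeric vector.
#' @param line_hz Line frequency in Hz (default 50).
#' @param fs_hz Sampling rate; required when `x` is a numeric vector.
#' @param ... Passed between methods.
#' @return Filtered object of the same type as `x`.
#' @export
notch_line <- function(x, line_hz = 50, ...) UseMethod("notch_line")

#' @rdname notch_line
#' @export
notch_line.lfp_recording <- function(x, line_hz = 50, ...) {
  map_channels(x, function(ch) {
    notch_line.numeric(ch, line_hz = line_hz, fs_hz = x$fs_hz)
  })
}

#' @rdname notch_line
#' @export
notch_line.numeric <- function(x, line_hz = 50, fs_hz, ...) {
  if (line_hz >= fs_hz / 2) {
    abort("`line_hz` must be below the Nyquist frequency.")
  }
  stop_w <- 1
  trans_w <- 1
  gain <- function(f) {
    d <- abs(f - line_hz)
    g <- rep(1, length(f))
    g[d <= stop_w] <- 0
    i <- d > stop_w & d < stop_w + trans_w
    g[i] <- 0.5 * (1 - cos(pi * (d[i] - stop_w) / trans_w))
    g
  }
  fft_apply_gain(x, fs_hz, gain, pad_n = round(4 * fs_hz))
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine transitions (one-tenth of
#' each edge frequency, clamped to 0.05-4 Hz and at most half an octave),
#' reaching full stop at or before one octave outside the edges. The
#' transition shape mirrors the roll-off of the modest-order IIR filters
#' conventionally used on LFP while staying numerically exact at
#' slow-oscillation frequencies, and it is exactly zero-phase.
#'
#' @param x An `lfp_recording` or a numeric vector.
#' @param band A `band_spec`, canonical band name, or list with
#'   `lo_hz`/`hi_hz`.
#' @param fs_hz Sampling rate; required when `x` is a numeric vector.
#' @param ... Passed between methods.
#' @return Filtered object of the same type as `x` (same length).
#' @export
bandpass <- function(x, band, ...) UseMethod("bandpass")

#' @rdname bandpass
#' @export
bandpass.lfp_recording <- function(x, band, ...) {
  map_channels(x, function(ch) bandpass.numeric(ch, band, fs_hz = x$fs_hz))
}

#' @rdname bandpass
#' @export
bandpass.numeric <- function(x, band, fs_hz, ...) {
  band <- check_band(as_band_spec(band), fs_hz)
  w_lo <- edge_transition(band$lo_hz)
  w_hi <- min(edge_transition(band$hi_hz), fs_hz / 2 - band$hi_hz)
  gain <- bandpass_gain(band$lo_hz, band$hi_hz, w_lo, w_hi)
  # pad with ~3 periods of the low edge so slow transients cannot wrap
  pad_n <- round(3 * fs_hz / band$lo_hz)
  fft_apply_gain(x, fs_hz, gain, pad_n = pad_n)
}

#' Slow-oscillation filter for state detection
#'
#' Band-passes to the SO band (0.1-0.9 Hz) with a deliberately gentle
#' upper roll-off (raised cosine over 0.9-1.2 Hz). State boundaries are
#' read from zero crossings of this trace, and a sharp cutoff just above
#' the band discards the waveform shape (state plateaus and edges) that
#' localizes them; the gentle shoulder keeps edge localization accurate
#' while still meeting full attenuation well inside one octave.
#' Zero-phase, like every filter in the package.
#'
#' @param x Numeric voltage series or `lfp_recording`.
#' @param fs_hz Sampling rate (vector input only).
#' @return Filtered object of the same type as `x`.
#' @export
so_filter <- function(x, fs_hz) {
  if (inherits(x, "lfp_recording")) {
    return(map_channels(x, function(ch) so_filter(ch, x$fs_hz)))
  }
  gain <- bandpass_gain(0.1, 0.9, 0.05, 0.3)
  fft_apply_gain(x, fs_hz, gain, pad_n = round(3 * fs_hz / 0.1))
}

#' Z-score a signal
#'
#' Normalizes a voltage series to zero mean and unit SD over the whole
#' series (the "baseline" normalization used before wavelet power and
#' envelope thresholding).
#'
#' @param x Numeric vector with nonzero variance.
#' @return Dimensionless numeric vector.
#' @export
zscore_channel <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot z-score a constant series (degenerate variance).")
  }
  (x - mean(x)) / s
}

#' Concatenate recording segments
#'
#' Joins recordings in time, recording each junction in `boundaries_s` so
#' that downstream state and event detection never emits an interval that
#' straddles a junction.
#'
#' @param segments List of `lfp_recording` objects with identical sampling
#'   rates and channel tables.
#' @return A single `lfp_recording`.
#' @export
concatenate_segments <- function(segments) {
  if (length(segments) == 0) abort("No segments supplied.")
  if (length(segments) == 1) return(segments[[1]])
  ref <- segments[[1]]
  for (s in segments[-1]) {
    if (!isTRUE(all.equal(s$fs_hz, ref$fs_hz))) {
      abort("All segments must share the same sampling rate.")
    }
    if (!identical(s$channels$channel_id, ref$channels$channel_id)) {
      abort("All segments must share the same channel set.")
    }
  }
  lens <- vapply(segments, function(s) ncol(s$samples), numeric(1))
  bounds <- cumsum(lens / ref$fs_hz)
  inner <- head(bounds, -1)
  extra <- unlist(lapply(seq_along(segments), function(i) {
    off <- if (i == 1) 0 else bounds[i - 1]
    segments[[i]]$boundaries_s + off
  }))
  new_recording(
    do.call(cbind, lapply(segments, function(s) s$samples)),
    fs_hz = ref$fs_hz, channels = ref$channels, t0_s = ref$t0_s,
    boundaries_s = sort(unique(c(inner, extra)))
  )
}
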