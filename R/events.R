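# Spindle and sharp-wave-ripple detection by band-limited Hilbert-
# envelope thresholding, and event summary metrics.

#' Envelope-detector parameter sets
#'
#' `spindle_params()` and `ripple_params()` return the standard presets:
#'
#' * spindles: 8-15 Hz band, 40 ms smoothing kernel, upper threshold at
#'   mean + 2.5 SD of the smoothed envelope, lower threshold at 1.5 x its
#'   mean, peaks < 200 ms apart merged, durations restricted to
#'   200-2000 ms;
#' * ripples: 80-130 Hz band, 15 ms kernel, upper threshold mean + 2 SD,
#'   peaks < 100 ms apart merged, durations 20-400 ms. The nominal lower
#'   threshold of 4 x SD exceeds the upper threshold and therefore cannot
#'   delimit event edges; the working default is mean + 1 SD
#'   (`literal_lower = TRUE` restores the nominal rule).
#'
#' @param band,smooth_kernel_ms,upper_k_sd,lower_rule,merge_gap_ms,dur_min_ms,dur_max_ms,kind
#'   Detector parameters; `lower_rule` is a list with `kind`
#'   (`"mean_multiple"` or `"mean_plus_sd"`) and `value`.
#' @param literal_lower Use the nominal 4 x SD ripple lower threshold.
#' @return An `event_params` list.
#' @export
event_params <- function(band, smooth_kernel_ms, upper_k_sd, lower_rule,
                         merge_gap_ms, dur_min_ms, dur_max_ms,
                         kind = "event") {
  if (!(dur_min_ms < dur_max_ms)) abort("`dur_min_ms` must be < `dur_max_ms`.")
  if (merge_gap_ms < 0) abort("`merge_gap_ms` must be >= 0.")
  if (!lower_rule$kind %in% c("mean_multiple", "mean_plus_sd")) {
    abort("`lower_rule$kind` must be 'mean_multiple' or 'mean_plus_sd'.")
  }
  structure(
    list(band = as_band_spec(band), smooth_kernel_ms = smooth_kernel_ms,
         upper_k_sd = upper_k_sd, lower_rule = lower_rule,
         merge_gap_ms = merge_gap_ms, dur_min_ms = dur_min_ms,
         dur_max_ms = dur_max_ms, kind = kind),
    class = "event_params"
  )
}

#' @rdname event_params
#' @export
spindle_params <- function() {
  event_params(band_spec("spindle"), smooth_kernel_ms = 40,
               upper_k_sd = 2.5,
               lower_rule = list(kind = "mean_multiple", value = 1.5),
               merge_gap_ms = 200, dur_min_ms = 200, dur_max_ms = 2000,
               kind = "spindle")
}

#' @rdname event_params
#' @export
ripple_params <- function(literal_lower = FALSE) {
  lower <- if (literal_lower) {
    warn(paste("Nominal ripple lower threshold (4 x SD) exceeds the",
               "upper threshold (2 x SD); event edges will collapse."))
    list(kind = "mean_plus_sd", value = 4)
  } else {
    list(kind = "mean_plus_sd", value = 1)
  }
  event_params(band_spec("ripple"), smooth_kernel_ms = 15,
               upper_k_sd = 2,
               lower_rule = lower,
               merge_gap_ms = 100, dur_min_ms = 20, dur_max_ms = 400,
               kind = "ripple")
}

#' Detect oscillatory events by envelope thresholding
#'
#' Pipeline: band-pass the raw signal, z-score it against its whole-
#' recording baseline, take the magnitude of the analytic signal, smooth
#' with a centered moving average of `smooth_kernel_ms`; samples above
#' the upper threshold (mean + `upper_k_sd` x SD of the smoothed
#' envelope) seed candidate events; candidate peaks closer than
#' `merge_gap_ms` are merged; event edges are the flanking crossings of
#' the lower threshold; events outside the duration limits or straddling
#' a concatenation boundary are dropped.
#'
#' The per-event instantaneous frequency is the number of band-passed
#' cycles within the supra-upper-threshold span divided by that span,
#' measured as the unwrapped analytic-phase advance over 2 pi (the
#' continuum version of counting threshold-crossing cycles).
#'
#' @param signal Raw voltage series (mV).
#' @param fs_hz Sampling rate.
#' @param params An [event_params()] preset.
#' @param boundaries_s Concatenation boundaries (seconds).
#' @param channel_id Channel label carried into the result.
#' @return Tibble of events: `kind`, `channel_id`, `start_s`, `end_s`,
#'   `peak_s`, `amplitude` (baseline-normalized envelope peak),
#'   `inst_freq_hz`. Attributes `upper_threshold` and `lower_threshold`
#'   record the thresholds used.
#' @export
detect_envelope_events <- function(signal, fs_hz, params,
                                   boundaries_s = numeric(0),
                                   channel_id = NA_character_) {
  check_band(params$band, fs_hz)
  z <- zscore_channel(bandpass.numeric(signal, params$band, fs_hz = fs_hz))
  an <- analytic_signal(z)
  env <- boxcar_smooth(Mod(an), round(params$smooth_kernel_ms / 1000 * fs_hz))
  if (sd(env) == 0) abort("Degenerate (zero-variance) envelope.")
  mu <- mean(env); s <- sd(env)
  upper <- mu + params$upper_k_sd * s
  lower <- if (params$lower_rule$kind == "mean_multiple") {
    params$lower_rule$value * mu
  } else {
    mu + params$lower_rule$value * s
  }
  n <- length(env)
  runs <- logical_runs(env > upper)
  runs <- runs[runs$value, , drop = FALSE]
  empty <- tibble(kind = character(0), channel_id = character(0),
                  start_s = numeric(0), end_s = numeric(0),
                  peak_s = numeric(0), amplitude = numeric(0),
                  inst_freq_hz = numeric(0))
  attr(empty, "upper_threshold") <- upper
  attr(empty, "lower_threshold") <- lower
  if (nrow(runs) == 0) return(empty)
  # peak sample of each supra-threshold run
  runs$peak <- vapply(seq_len(nrow(runs)), function(i) {
    ii <- runs$start[i]:runs$end[i]
    ii[which.max(env[ii])]
  }, integer(1))
  # merge runs whose neighboring peaks are < merge_gap_ms apart
  gap_n <- params$merge_gap_ms / 1000 * fs_hz
  grp <- cumsum(c(1L, as.integer(diff(runs$peak) >= gap_n)))
  ph <- unwrap_phase(Arg(an))
  out <- list()
  for (g in unique(grp)) {
    rr <- runs[grp == g, , drop = FALSE]
    first <- min(rr$start); last <- max(rr$end)
    a <- first
    while (a > 1L && env[a - 1L] >= lower) a <- a - 1L
    b <- last
    while (b < n && env[b + 1L] >= lower) b <- b + 1L
    ii <- a:b
    pk <- ii[which.max(env[ii])]
    span_s <- (last - first + 1L) / fs_hz
    inst <- if (last > first) {
      (ph[last] - ph[first]) / (2 * pi) / ((last - first) / fs_hz)
    } else NA_real_
    out[[length(out) + 1]] <- tibble(
      kind = params$kind, channel_id = channel_id,
      start_s = (a - 1L) / fs_hz, end_s = b / fs_hz,
      peak_s = (pk - 0.5) / fs_hz,
      amplitude = env[pk], inst_freq_hz = inst
    )
  }
  ev <- dplyr::bind_rows(out)
  # distinct lower-threshold intervals (merged groups may expand to the
  # same edges)
  ev <- dplyr::distinct(ev, .data$start_s, .data$end_s,
                        .keep_all = TRUE)
  dur_ms <- (ev$end_s - ev$start_s) * 1000
  ev <- ev[dur_ms >= params$dur_min_ms & dur_ms <= params$dur_max_ms, ,
           drop = FALSE]
  if (length(boundaries_s) && nrow(ev)) {
    crosses <- vapply(seq_len(nrow(ev)), function(i) {
      any(boundaries_s > ev$start_s[i] & boundaries_s < ev$end_s[i])
    }, logical(1))
    ev <- ev[!crosses, , drop = FALSE]
  }
  attr(ev, "upper_threshold") <- upper
  attr(ev, "lower_threshold") <- lower
  ev
}

#' Annotate events with their normalized-cycle latency
#'
#' @param events Event tibble from [detect_envelope_events()].
#' @param pv A [build_phase_vector()] result (same channel).
#' @return `events` with a `latency_pct` column (the phase-vector value
#'   at the event peak; `NA` outside complete cycles).
#' @export
event_latency <- function(events, pv) {
  idx <- pmin(pmax(round(events$peak_s * pv$fs_hz), 1L), pv$n_samples)
  events$latency_pct <- pv$values[idx]
  events
}

#' Summarize detected events
#'
#' Computes the aggregate metrics of an event population: mean amplitude
#' and duration with their coefficients of variation (CV = SD/mean,
#' population SD), event density per Up-state, the percentage of
#' high-amplitude events (amplitude > `high_amp_mult` x the mean event
#' amplitude of the recording), mean instantaneous frequency, and mean
#' normalized-cycle latency when available.
#'
#' @param events Event tibble (optionally with `latency_pct` from
#'   [event_latency()]).
#' @param seg Optional `uds_segmentation` used for the per-Up-state
#'   density.
#' @param pv Optional phase vector; a convenience for annotating latency
#'   before summarizing.
#' @param high_amp_mult Multiplier defining high-amplitude events
#'   (default 5).
#' @return One-row tibble: `n_events`, `mean_amplitude`, `amplitude_cv`,
#'   `mean_duration_s`, `duration_cv`, `density_per_up`,
#'   `pct_high_amplitude`, `mean_inst_freq_hz`, `mean_latency_pct`.
#'   With no events, `n_events = 0` and all other fields are `NA`.
#' @export
compute_event_metrics <- function(events, seg = NULL, pv = NULL,
                                  high_amp_mult = 5) {
  if (!is.null(pv)) events <- event_latency(events, pv)
  n <- nrow(events)
  if (n == 0) {
    return(tibble(
      n_events = 0L, mean_amplitude = NA_real_, amplitude_cv = NA_real_,
      mean_duration_s = NA_real_, duration_cv = NA_real_,
      density_per_up = NA_real_, pct_high_amplitude = NA_real_,
      mean_inst_freq_hz = NA_real_, mean_latency_pct = NA_real_
    ))
  }
  pop_cv <- function(x) {
    if (mean(x) == 0) return(NA_real_)
    sqrt(mean((x - mean(x))^2)) / mean(x)
  }
  dur <- events$end_s - events$start_s
  n_up <- if (is.null(seg)) NA_integer_ else
    sum(seg$states$label == "Up")
  lat <- if ("latency_pct" %in% names(events)) {
    mean(events$latency_pct, na.rm = TRUE)
  } else NA_real_
  tibble(
    n_events = n,
    mean_amplitude = mean(events$amplitude),
    amplitude_cv = pop_cv(events$amplitude),
    mean_duration_s = mean(dur),
    duration_cv = pop_cv(dur),
    density_per_up = n / n_up,
    pct_high_amplitude =
      100 * mean(events$amplitude > high_amp_mult * mean(events$amplitude)),
    mean_inst_freq_hz = mean(events$inst_freq_hz, na.rm = TRUE),
    mean_latency_pct = lat
  )
}
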