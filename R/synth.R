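# Synthetic LFP generator with ground-truth annotations.
#
# The generator plants exactly the structure the analysis stages assume --
# alternating Up/Down states, a slow-oscillation (SO) waveform, Up-state
# nested band-limited bursts, spindle and ripple transients, state-
# modulated Poisson spiking, pink background noise and 50 Hz line
# contamination -- and records everything it planted, so every detector
# can be scored by parameter recovery.

#' Specify a duration distribution
#'
#' @param family `"gamma"` or `"lognormal"`. A `cv` of 0 degenerates to a
#'   constant at `mean_s` for either family.
#' @param mean_s Mean duration in seconds (must be positive).
#' @param cv Coefficient of variation (SD/mean, >= 0).
#' @param min_s,max_s Optional truncation bounds (draws are clipped).
#' @return A `dur_spec` list.
#' @export
dur_spec <- function(family = c("gamma", "lognormal"), mean_s, cv = 0.3,
                     min_s = NULL, max_s = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean_s) || mean_s <= 0) {
    abort("`mean_s` must be positive (configuration error).")
  }
  if (cv < 0) abort("`cv` must be >= 0.")
  structure(list(family = family, mean_s = mean_s, cv = cv,
                 min_s = min_s, max_s = max_s), class = "dur_spec")
}

draw_durations <- function(spec, n) {
  if (n == 0) return(numeric(0))
  x <- if (spec$cv == 0) {
    rep(spec$mean_s, n)
  } else if (spec$family == "gamma") {
    shape <- 1 / spec$cv^2
    rgamma(n, shape = shape, scale = spec$mean_s / shape)
  } else {
    sdlog <- sqrt(log(1 + spec$cv^2))
    rlnorm(n, meanlog = log(spec$mean_s) - sdlog^2 / 2, sdlog = sdlog)
  }
  if (!is.null(spec$min_s)) x <- pmax(x, spec$min_s)
  if (!is.null(spec$max_s)) x <- pmin(x, spec$max_s)
  x
}

#' Specify an Up-state nested band-limited burst
#'
#' The burst envelope across each Up-state follows a beta-density profile
#' whose mode sits at `peak_latency_pct` of the normalized SO cycle
#' (50 = Up-state onset, 100 = Up-state end) with spread `spread_pct`
#' (approximate SD in normalized units). The carrier is a sinusoid at the
#' band center with a random phase per state.
#'
#' @param lo_hz,hi_hz Band edges in Hz.
#' @param amplitude_mv Peak envelope amplitude in mV.
#' @param peak_latency_pct Position of the envelope peak in (50, 100].
#' @param spread_pct Envelope spread in normalized units.
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(lo_hz, hi_hz, amplitude_mv, peak_latency_pct = 65,
                       spread_pct = 10) {
  if (!(peak_latency_pct > 50 && peak_latency_pct <= 100)) {
    abort("`peak_latency_pct` must lie in (50, 100].")
  }
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz,
                 amplitude_mv = amplitude_mv,
                 peak_latency_pct = peak_latency_pct,
                 spread_pct = spread_pct), class = "burst_spec")
}

#' Synthetic recording configuration
#'
#' Defaults describe a urethane-like slow-oscillation regime: ~0.4 Hz SO
#' (Up 1.1 s, Down 1.4 s, gamma-distributed with CV 0.3), 0.5 mV SO
#' amplitude, gamma-band bursts peaking early in the Up-state, ~11 Hz
#' spindles clustered at Up-state onset, ~100 Hz ripples, state-modulated
#' Poisson spiking (3 Hz Up / 0.3 Hz Down), pink background noise and a
#' small 50 Hz line component.
#'
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate (default 1000).
#' @param up_dur,down_dur [dur_spec()] for Up/Down state durations.
#' @param so_amplitude_mv Mean per-cycle peak-to-trough amplitude of the
#'   SO-band (0.1-0.9 Hz) component, in mV.
#' @param so_rise_s Rise/fall time of the Up-state plateau shoulders (s).
#' @param band_bursts List of [burst_spec()] entries.
#' @param spindle_rate_per_up,ripple_rate_per_up Planted events per
#'   Up-state (deterministic count `floor(rate)` plus a Bernoulli draw of
#'   the fractional part, capped by what fits in the state).
#' @param spindle_dur,ripple_dur [dur_spec()] for event durations; legal
#'   supports are [0.2, 2] s (spindles) and [0.02, 0.4] s (ripples).
#' @param spindle_freq_hz Spindle carrier frequency in [8, 15].
#' @param ripple_freq_hz Ripple carrier frequency in [80, 130].
#' @param spindle_amplitude_mv,ripple_amplitude_mv Peak envelope
#'   amplitudes in mV.
#' @param spike_rate_up_hz,spike_rate_down_hz Per-unit Poisson rates.
#' @param n_units Number of units to simulate.
#' @param noise_pink_sd SD of the pink (1/f) background noise in mV.
#' @param line_50hz_amp Amplitude of the 50 Hz line component in mV.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output. Independent substreams drive states, events, spikes and
#'   noise.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 60,
                         fs_hz = 1000,
                         up_dur = dur_spec("gamma", 1.1, 0.3),
                         down_dur = dur_spec("gamma", 1.4, 0.3),
                         so_amplitude_mv = 0.8,
                         so_rise_s = 0.15,
                         band_bursts = list(
                           burst_spec(30, 79.9, amplitude_mv = 0.06,
                                      peak_latency_pct = 65,
                                      spread_pct = 10)
                         ),
                         spindle_rate_per_up = 0.3,
                         spindle_dur = dur_spec("gamma", 0.6, 0.25,
                                                min_s = 0.3, max_s = 1.8),
                         spindle_freq_hz = 11,
                         spindle_amplitude_mv = 0.1,
                         ripple_rate_per_up = 0.3,
                         ripple_dur = dur_spec("gamma", 0.12, 0.25,
                                               min_s = 0.05, max_s = 0.35),
                         ripple_freq_hz = 100,
                         ripple_amplitude_mv = 0.15,
                         spike_rate_up_hz = 3,
                         spike_rate_down_hz = 0.3,
                         n_units = 5,
                         noise_pink_sd = 0.03,
                         line_50hz_amp = 0.02,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg$up_dur, "dur_spec"),
            inherits(cfg$down_dur, "dur_spec"))
  if (cfg$duration_s <= 0) abort("`duration_s` must be positive.")
  rates <- c(cfg$spindle_rate_per_up, cfg$ripple_rate_per_up,
             cfg$spike_rate_up_hz, cfg$spike_rate_down_hz)
  if (any(rates < 0)) abort("All rates must be >= 0 (configuration error).")
  if (!(cfg$spindle_freq_hz >= 8 && cfg$spindle_freq_hz <= 15)) {
    abort("`spindle_freq_hz` must lie in [8, 15].")
  }
  if (!(cfg$ripple_freq_hz >= 80 && cfg$ripple_freq_hz <= 130)) {
    abort("`ripple_freq_hz` must lie in [80, 130].")
  }
  hi_edges <- c(vapply(cfg$band_bursts, function(b) b$hi_hz, numeric(1)),
                cfg$spindle_freq_hz, cfg$ripple_freq_hz)
  if (length(hi_edges) && cfg$fs_hz <= 2 * max(hi_edges)) {
    abort("`fs_hz` must exceed twice the highest band edge.")
  }
  cfg
}

#' Generate the planted Up/Down state sequence
#'
#' Draws alternating Down/Up durations from the configured distributions,
#' starting with a Down-state (a cycle is a Down-state plus the following
#' Up-state), and tiles `[0, duration_s)` exactly (the last state is
#' truncated).
#'
#' @param config A [synth_config()].
#' @return A `ground_truth` object with `$states`
#'   (tibble: `label`, `start_s`, `end_s`), empty `$events`, and the
#'   config attached.
#' @export
generate_state_sequence <- function(config) {
  validate_synth_config(config)
  states <- withr::with_seed(substream_seed(config$seed, "states"), {
    # draw in blocks until the tiling covers the recording
    lab <- character(0); dur <- numeric(0)
    total <- 0
    up_next <- FALSE
    while (total < config$duration_s) {
      n <- max(16L, ceiling(
        2 * (config$duration_s - total) /
          (config$up_dur$mean_s + config$down_dur$mean_s)
      ))
      for (i in seq_len(n)) {
        d <- draw_durations(if (up_next) config$up_dur else config$down_dur, 1)
        lab <- c(lab, if (up_next) "Up" else "Down")
        dur <- c(dur, d)
        total <- total + d
        up_next <- !up_next
        if (total >= config$duration_s) break
      }
    }
    ends <- cumsum(dur)
    keep <- which(c(0, head(ends, -1)) < config$duration_s)
    tibble(
      label = lab[keep],
      start_s = c(0, head(ends, -1))[keep],
      end_s = pmin(ends[keep], config$duration_s)
    )
  })
  structure(
    list(states = states, events = empty_truth_events(), spikes = NULL,
         config = config),
    class = "ground_truth"
  )
}

empty_truth_events <- function() {
  tibble(kind = character(0), start_s = numeric(0), end_s = numeric(0),
         center_freq_hz = numeric(0))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d states, %d events, %s spikes over %.1f s\n",
    nrow(x$states), nrow(x$events),
    if (is.null(x$spikes)) "no" else format(nrow(x$spikes)),
    x$config$duration_s
  ))
  invisible(x)
}

# Beta-profile envelope over (0, 1) with mode at m and spread sd_u,
# normalized to peak 1.
beta_envelope <- function(u, m, sd_u) {
  m <- min(max(m, 0.02), 0.98)
  conc <- max(2, m * (1 - m) / max(sd_u, 1e-3)^2)
  a <- m * conc + 1
  b <- (1 - m) * conc + 1
  env <- stats::dbeta(u, a, b)
  peak <- stats::dbeta((a - 1) / (a + b - 2), a, b)
  env / peak
}

# Hann-windowed sinusoid of duration d starting at t = 0.
hann_burst <- function(n_samp, fs_hz, freq_hz, phase) {
  t <- (seq_len(n_samp) - 1) / fs_hz
  d <- n_samp / fs_hz
  env <- 0.5 * (1 - cos(2 * pi * (t + 0.5 / fs_hz) / d))
  list(env = env, carrier = cos(2 * pi * freq_hz * t + phase))
}

# Plant events of one kind into the Up-states. Deterministic count
# floor(rate) + Bernoulli(fraction) per Up-state, capped by what fits
# (events are kept >= gap_s apart and inside the state).
plant_events <- function(states, rate, dspec, freq_hz, near_onset,
                         gap_s, duration_s) {
  ups <- states[states$label == "Up", , drop = FALSE]
  out <- list()
  frac <- rate - floor(rate)
  for (i in seq_len(nrow(ups))) {
    n_want <- floor(rate) + (runif(1) < frac)
    if (n_want == 0) next
    s0 <- ups$start_s[i]; s1 <- ups$end_s[i]
    len <- s1 - s0
    cursor <- if (near_onset) s0 + runif(1, 0.02, 0.10) * len else
      s0 + runif(1, 0, 0.5) * len
    for (j in seq_len(n_want)) {
      d <- draw_durations(dspec, 1)
      if (cursor + d > s1 - 0.02 || cursor + d > duration_s) break
      out[[length(out) + 1]] <- tibble(
        start_s = cursor, end_s = cursor + d, center_freq_hz = freq_hz
      )
      cursor <- cursor + d + gap_s
    }
  }
  if (length(out) == 0) return(empty_truth_events()[, -1])
  dplyr::bind_rows(out)
}

#' Synthesize the LFP from a planted state sequence
#'
#' Builds the voltage trace as the sum of: (1) an SO component in which
#' each Up-state is a depolarized plateau with cosine shoulders riding on
#' a hyperpolarized baseline, mean-removed and rescaled once so that the
#' mean per-cycle peak-to-trough of its SO-band-filtered version equals
#' `so_amplitude_mv`; (2) per-Up-state band-limited bursts whose beta-
#' shaped envelope peaks at `peak_latency_pct` of the normalized cycle;
#' (3) Hann-windowed spindle and ripple transients (appended to
#' `truth$events`); (4) pink 1/f noise; and (5) a 50 Hz line sinusoid.
#'
#' @param truth A `ground_truth` from [generate_state_sequence()].
#' @param config The same [synth_config()].
#' @return A list with elements `recording` (an `lfp_recording`, one
#'   channel) and `truth` (with planted events appended).
#' @export
synthesize_lfp <- function(truth, config) {
  validate_synth_config(config)
  n <- round(config$duration_s * config$fs_hz)
  fs <- config$fs_hz
  t <- (seq_len(n) - 1) / fs
  states <- truth$states

  idx <- function(a, b) { # sample indices covering [a, b) seconds
    lo <- floor(a * fs) + 1L
    hi <- min(n, ceiling(b * fs))
    if (hi < lo) integer(0) else lo:hi
  }

  # --- SO component -------------------------------------------------
  # Up-state plateau with cosine shoulders *centered* on the planted
  # transitions (half the rise before, half after), so the mid-height of
  # each edge -- where a band-limited zero crossing localizes -- sits on
  # the transition itself.
  so <- numeric(n)
  for (i in seq_len(nrow(states))) {
    if (states$label[i] != "Up") next
    k_state <- length(idx(states$start_s[i], states$end_s[i]))
    rise <- min(floor(k_state / 2), round(config$so_rise_s * fs))
    a <- floor(states$start_s[i] * fs) + 1L - floor(rise / 2)
    b <- min(n, ceiling(states$end_s[i] * fs)) + floor(rise / 2)
    k <- b - a + 1L
    env <- rep(1, k)
    if (rise > 0) {
      env[seq_len(rise)] <- 0.5 * (1 - cos(pi * seq_len(rise) / rise))
      env[k + 1 - seq_len(rise)] <- env[seq_len(rise)]
    }
    ii <- max(1L, a):min(n, b)
    so[ii] <- so[ii] + env[ii - a + 1L]
  }
  so <- so - mean(so)
  # self-calibration: scale so that the SO-band per-cycle peak-to-trough
  # matches the configured amplitude
  if (config$so_amplitude_mv > 0) {
    so_f <- so_filter(so, fs)
    p2t <- so_cycle_p2t(states, so_f, fs, n)
    ref <- if (length(p2t)) mean(p2t) else diff(range(so_f))
    if (ref > 0) so <- so * config$so_amplitude_mv / ref
  } else {
    so <- numeric(n)
  }

  # --- events and bursts (events substream) -------------------------
  x <- so
  truth$events <- empty_truth_events()
  withr::with_seed(substream_seed(config$seed, "events"), {
    for (b in config$band_bursts) {
      if (b$hi_hz >= fs / 2) {
        abort("Burst band edge above the Nyquist frequency.")
      }
      fc <- (b$lo_hz + b$hi_hz) / 2
      m <- (b$peak_latency_pct - 50) / 50
      sd_u <- b$spread_pct / 50
      for (i in seq_len(nrow(states))) {
        if (states$label[i] != "Up") next
        ii <- idx(states$start_s[i], states$end_s[i])
        k <- length(ii)
        if (k < 8) next
        u <- (seq_len(k) - 0.5) / k
        env <- beta_envelope(u, m, sd_u) * b$amplitude_mv
        x[ii] <- x[ii] + env * cos(2 * pi * fc * t[ii] + runif(1, 0, 2 * pi))
      }
    }
    spin <- plant_events(states, config$spindle_rate_per_up,
                         config$spindle_dur, config$spindle_freq_hz,
                         near_onset = TRUE, gap_s = 0.4,
                         duration_s = config$duration_s)
    rip <- plant_events(states, config$ripple_rate_per_up,
                        config$ripple_dur, config$ripple_freq_hz,
                        near_onset = FALSE, gap_s = 0.15,
                        duration_s = config$duration_s)
    for (ev in list(list(tab = spin, amp = config$spindle_amplitude_mv,
                         kind = "spindle"),
                    list(tab = rip, amp = config$ripple_amplitude_mv,
                         kind = "ripple"))) {
      tab <- ev$tab
      if (nrow(tab) == 0) next
      for (j in seq_len(nrow(tab))) {
        ii <- idx(tab$start_s[j], tab$end_s[j])
        if (length(ii) < 4) next
        hb <- hann_burst(length(ii), fs, tab$center_freq_hz[j],
                         runif(1, 0, 2 * pi))
        x[ii] <- x[ii] + ev$amp * hb$env * hb$carrier
        truth$events <- dplyr::bind_rows(
          truth$events,
          tibble(kind = ev$kind, start_s = tab$start_s[j],
                 end_s = tab$end_s[j],
                 center_freq_hz = tab$center_freq_hz[j])
        )
      }
    }
  })
  truth$events <- dplyr::arrange(truth$events, .data$start_s)

  # --- noise (noise substream) --------------------------------------
  withr::with_seed(substream_seed(config$seed, "noise"), {
    x <- x + pink_noise(n, fs, config$noise_pink_sd)
  })
  if (config$line_50hz_amp > 0) {
    x <- x + config$line_50hz_amp * sin(2 * pi * 50 * t)
  }

  rec <- new_recording(matrix(x, nrow = 1), fs_hz = fs,
                       channels = tibble(channel_id = "sim1",
                                         region = "other",
                                         depth_um = NA_real_))
  list(recording = rec, truth = truth)
}

# Per-complete-cycle (Down + following Up) peak-to-trough of a filtered
# trace, given the planted states.
so_cycle_p2t <- function(states, so_f, fs, n) {
  p2t <- numeric(0)
  for (i in seq_len(nrow(states) - 1)) {
    if (states$label[i] == "Down" && states$label[i + 1] == "Up") {
      di <- (floor(states$start_s[i] * fs) + 1L):min(n, ceiling(states$end_s[i] * fs))
      ui <- (floor(states$start_s[i + 1] * fs) + 1L):min(n, ceiling(states$end_s[i + 1] * fs))
      p2t <- c(p2t, max(so_f[ui]) - min(so_f[di]))
    }
  }
  p2t
}

#' Synthesize state-modulated Poisson spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process with rate
#' `spike_rate_up_hz` during Up-states and `spike_rate_down_hz` during
#' Down-states. Spike times are quantized to 1 ms and labelled with the
#' state they fall in.
#'
#' @param truth A `ground_truth` with non-empty `$states`.
#' @param config The same [synth_config()].
#' @return The `ground_truth` with `$spikes` set to a tibble
#'   (`unit_id`, `time_s`, `state`).
#' @export
synthesize_spikes <- function(truth, config) {
  validate_synth_config(config)
  states <- truth$states
  if (nrow(states) == 0) abort("`truth$states` is empty.")
  truth$spikes <- withr::with_seed(substream_seed(config$seed, "spikes"), {
    out <- list()
    for (u in seq_len(config$n_units)) {
      times <- numeric(0); labs <- character(0)
      for (i in seq_len(nrow(states))) {
        rate <- if (states$label[i] == "Up") config$spike_rate_up_hz else
          config$spike_rate_down_hz
        len <- states$end_s[i] - states$start_s[i]
        k <- rpois(1, rate * len)
        if (k > 0) {
          times <- c(times, runif(k, states$start_s[i], states$end_s[i]))
          labs <- c(labs, rep(states$label[i], k))
        }
      }
      o <- order(times)
      times <- round(times[o] * 1000) / 1000 # 1 ms quantization
      labs <- labs[o]
      keep <- !duplicated(times)
      out[[u]] <- tibble(
        unit_id = sprintf("unit%02d", u),
        time_s = times[keep], state = labs[keep]
      )
    }
    dplyr::bind_rows(out)
  })
  truth
}

#' Simulate a full synthetic recording
#'
#' Convenience wrapper running [generate_state_sequence()],
#' [synthesize_lfp()] and [synthesize_spikes()].
#'
#' @param config A [synth_config()].
#' @return A list with `recording`, `truth` (states, planted events,
#'   spikes) and `spikes` (the spike tibble, also inside `truth`).
#' @export
simulate_recording <- function(config) {
  truth <- generate_state_sequence(config)
  lfp <- synthesize_lfp(truth, config)
  truth <- synthesize_spikes(lfp$truth, config)
  list(recording = lfp$recording, truth = truth, spikes = truth$spikes)
}

#' Match detected events against planted ground truth
#'
#' Greedy one-to-one matching by maximal temporal overlap: candidate
#' pairs are ranked by overlap and accepted while both members are still
#' unmatched, provided the overlap is at least `min_overlap_frac` of the
#' truth event's duration.
#'
#' @param detected Tibble of detected events (`start_s`, `end_s`).
#' @param truth_events Tibble of planted events (`start_s`, `end_s`).
#' @param min_overlap_frac Required overlap as a fraction of the truth
#'   event duration, in (0, 1].
#' @return A `match_report`: `n_truth`, `n_detected`, `n_matched`,
#'   `precision`, `recall`, and `$matches` (tibble with per-match signed
#'   `onset_error_ms`, detected minus truth).
#' @export
match_events <- function(detected, truth_events, min_overlap_frac = 0.5) {
  if (!(min_overlap_frac > 0 && min_overlap_frac <= 1)) {
    abort("`min_overlap_frac` must lie in (0, 1].")
  }
  nd <- nrow(detected); nt <- nrow(truth_events)
  matches <- tibble(truth_idx = integer(0), det_idx = integer(0),
                    overlap_s = numeric(0), onset_error_ms = numeric(0))
  if (nd > 0 && nt > 0) {
    ov <- outer(seq_len(nt), seq_len(nd), function(i, j) {
      pmax(0, pmin(truth_events$end_s[i], detected$end_s[j]) -
             pmax(truth_events$start_s[i], detected$start_s[j]))
    })
    need <- min_overlap_frac *
      (truth_events$end_s - truth_events$start_s)
    cand <- which(ov >= need & ov > 0, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(ov[cand], decreasing = TRUE), , drop = FALSE]
      t_used <- logical(nt); d_used <- logical(nd)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (t_used[i] || d_used[j]) next
        t_used[i] <- TRUE; d_used[j] <- TRUE
        matches <- dplyr::add_row(
          matches, truth_idx = i, det_idx = j, overlap_s = ov[i, j],
          onset_error_ms =
            1000 * (detected$start_s[j] - truth_events$start_s[i])
        )
      }
    }
  }
  nm <- nrow(matches)
  precision <- if (nd == 0) {
    if (nt > 0) warn("No detected events; precision reported as 0.")
    0
  } else nm / nd
  recall <- if (nt == 0) NA_real_ else nm / nt
  structure(
    list(n_truth = nt, n_detected = nd, n_matched = nm,
         precision = precision, recall = recall, matches = matches),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> truth %d, detected %d, matched %d | precision %.3f, recall %s\n",
    x$n_truth, x$n_detected, x$n_matched, x$precision,
    ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))
  ))
  invisible(x)
}
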