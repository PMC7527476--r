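# Up/Down-state segmentation from the Hilbert phase of the slow
# oscillation, SO summary metrics, and the normalized-cycle phase vector.

#' Detect Up- and Down-states from the SO-filtered LFP
#'
#' The instantaneous phase phi(t) of the SO-band (0.1-0.9 Hz) filtered
#' signal is taken from the analytic signal; candidate Up-states are
#' maximal runs on one side of cos(phi) = 0. Candidates shorter than
#' `min_up_s` or whose mean SO-filtered amplitude (relative to the
#' recording mean, which is zero after band-passing) is below
#' `min_up_amp_mv` are absorbed into the surrounding Down-state. Leading
#' and trailing partial states are discarded, and no state crosses a
#' concatenation boundary (each inter-boundary segment is segmented
#' independently).
#'
#' Which side of cos(phi) = 0 is "Up" depends on electrode depth. With
#' `polarity = "auto"` and a broadband `raw` trace supplied, the side with
#' the larger mean gamma-band (30-79.9 Hz) envelope is taken as Up (fast
#' activity rides the Up-state); without `raw`, the positive side is used.
#'
#' @param so_filtered SO-band filtered voltage series (mV).
#' @param fs_hz Sampling rate.
#' @param min_up_s Minimum Up-state duration in seconds (default 0.3).
#' @param min_up_amp_mv Minimum mean Up-state amplitude in mV
#'   (default 0.05).
#' @param polarity `"auto"`, `"pos"` or `"neg"`.
#' @param raw Optional broadband series (same length) for automatic
#'   polarity resolution.
#' @param boundaries_s Concatenation boundaries in seconds.
#' @return A `uds_segmentation`: `$states` (tibble `label`, `start_s`,
#'   `end_s`, `chunk`), `$phase` (per-sample SO phase, radians),
#'   `$polarity`, `$fs_hz`, `$n_samples`.
#' @export
detect_uds <- function(so_filtered, fs_hz, min_up_s = 0.3,
                       min_up_amp_mv = 0.05,
                       polarity = c("auto", "pos", "neg"),
                       raw = NULL, boundaries_s = numeric(0)) {
  polarity <- match.arg(polarity)
  n <- length(so_filtered)
  cuts <- unique(pmin(pmax(round(boundaries_s * fs_hz), 0L), n))
  edges <- c(0L, sort(cuts), n)
  phase <- numeric(n)
  states <- list()
  used_polarity <- polarity
  for (ci in seq_len(length(edges) - 1)) {
    lo <- edges[ci] + 1L; hi <- edges[ci + 1]
    if (hi - lo + 1L < 4L) next
    xc <- so_filtered[lo:hi]
    ph <- instantaneous_phase(xc)
    phase[lo:hi] <- ph
    sgn <- resolve_polarity(polarity, xc, raw, lo, hi, fs_hz)
    used_polarity <- if (sgn > 0) "pos" else "neg"
    up_flag <- sgn * cos(ph) > 0
    runs <- logical_runs(up_flag)
    # gate candidate Up-states, absorbing failures into Down
    for (r in seq_len(nrow(runs))) {
      if (!runs$value[r]) next
      len_s <- (runs$end[r] - runs$start[r] + 1L) / fs_hz
      amp <- sgn * mean(xc[runs$start[r]:runs$end[r]])
      if (len_s < min_up_s || amp < min_up_amp_mv) runs$value[r] <- FALSE
    }
    # merge consecutive same-label runs, drop partial edge states
    merged <- logical_runs(rep(runs$value, runs$end - runs$start + 1L))
    if (nrow(merged) > 2) {
      merged <- merged[-c(1, nrow(merged)), , drop = FALSE]
      states[[length(states) + 1]] <- tibble(
        label = ifelse(merged$value, "Up", "Down"),
        start_s = (lo - 1L + merged$start - 1L) / fs_hz,
        end_s = (lo - 1L + merged$end) / fs_hz,
        chunk = ci
      )
    }
  }
  states <- if (length(states)) dplyr::bind_rows(states) else
    tibble(label = character(0), start_s = numeric(0),
           end_s = numeric(0), chunk = integer(0))
  seg <- structure(
    list(states = states, phase = phase, polarity = used_polarity,
         fs_hz = fs_hz, n_samples = n),
    class = "uds_segmentation"
  )
  # A recording where every candidate fails the gates legitimately has
  # zero Up-states; only a recording with SO cycles but too few of them
  # is an error (3 cycles at the 0.1 Hz band edge = 30 s minimum).
  if (any(states$label == "Up") && nrow(complete_cycles(seg)) < 3) {
    abort(paste("Fewer than 3 complete SO cycles detected;",
                "the recording is too short or lacks SO activity."))
  }
  seg
}

resolve_polarity <- function(polarity, xc, raw, lo, hi, fs_hz) {
  if (polarity == "pos") return(1)
  if (polarity == "neg") return(-1)
  if (is.null(raw)) return(1)
  genv <- Mod(analytic_signal(
    bandpass.numeric(raw[lo:hi], band_spec("gamma"), fs_hz = fs_hz)
  ))
  pos_side <- xc > 0
  if (mean(genv[pos_side]) >= mean(genv[!pos_side])) 1 else -1
}

#' @export
print.uds_segmentation <- function(x, ...) {
  cyc <- complete_cycles(x)
  cat(sprintf(
    "<uds_segmentation> %d states (%d complete cycles), polarity %s, %g Hz\n",
    nrow(x$states), nrow(cyc), x$polarity, x$fs_hz
  ))
  invisible(x)
}

#' Complete SO cycles of a segmentation
#'
#' A cycle is a Down-state plus the immediately following Up-state
#' (contiguous, same concatenation chunk).
#'
#' @param seg A `uds_segmentation`.
#' @return Tibble with `cycle`, `down_start_s`, `up_start_s`, `up_end_s`.
#' @export
complete_cycles <- function(seg) {
  st <- seg$states
  out <- tibble(cycle = integer(0), down_start_s = numeric(0),
                up_start_s = numeric(0), up_end_s = numeric(0))
  if (nrow(st) < 2) return(out)
  k <- 0L
  for (i in seq_len(nrow(st) - 1)) {
    if (st$label[i] == "Down" && st$label[i + 1] == "Up" &&
        st$chunk[i] == st$chunk[i + 1] &&
        abs(st$end_s[i] - st$start_s[i + 1]) < 1e-9) {
      k <- k + 1L
      out <- dplyr::add_row(out, cycle = k,
                            down_start_s = st$start_s[i],
                            up_start_s = st$start_s[i + 1],
                            up_end_s = st$end_s[i + 1])
    }
  }
  out
}

#' Slow-oscillation summary metrics
#'
#' Computed over complete cycles (Down + following Up): the SO frequency
#' is the cycle count divided by the summed cycle durations (so discarded
#' edges do not bias it), and the SO amplitude is the mean per-cycle
#' peak-to-trough (maximum of the SO-filtered trace during the Up-state
#' minus its minimum during the Down-state).
#'
#' @param seg A `uds_segmentation`.
#' @param so_filtered The SO-band filtered series used for detection.
#' @return One-row tibble: `n_cycles`, `so_freq_hz`, `mean_up_s`,
#'   `mean_down_s`, `mean_cycle_s`, `so_amplitude_mv`.
#' @export
so_metrics <- function(seg, so_filtered) {
  cyc <- complete_cycles(seg)
  if (nrow(cyc) == 0) abort("No complete SO cycle in the segmentation.")
  fs <- seg$fs_hz
  up_len <- cyc$up_end_s - cyc$up_start_s
  down_len <- cyc$up_start_s - cyc$down_start_s
  amp <- vapply(seq_len(nrow(cyc)), function(i) {
    di <- sample_span(cyc$down_start_s[i], cyc$up_start_s[i], fs,
                      length(so_filtered))
    ui <- sample_span(cyc$up_start_s[i], cyc$up_end_s[i], fs,
                      length(so_filtered))
    max(so_filtered[ui]) - min(so_filtered[di])
  }, numeric(1))
  tibble(
    n_cycles = nrow(cyc),
    so_freq_hz = nrow(cyc) / sum(up_len + down_len),
    mean_up_s = mean(up_len),
    mean_down_s = mean(down_len),
    mean_cycle_s = mean(up_len + down_len),
    so_amplitude_mv = mean(amp)
  )
}

# Sample indices covering [a, b) seconds.
sample_span <- function(a, b, fs, n) {
  lo <- round(a * fs) + 1L
  hi <- min(n, round(b * fs))
  if (hi < lo) lo else lo:hi
}

#' Build the normalized-cycle phase vector
#'
#' Within each complete cycle the vector rises linearly from 0 at the
#' Down-state onset to 50 at the Down-to-Up transition and on to 100 at
#' the Up-state end, giving 40 bins per state (bin width 1.25 normalized
#' units). Samples outside complete cycles are `NA`.
#'
#' @param seg A `uds_segmentation`.
#' @return A `phase_vector`: `$values` in `[0, 100)`, `$bin` in `0:79`
#'   (0-39 Down, 40-79 Up), `$cycle` index, all per sample.
#' @export
build_phase_vector <- function(seg) {
  cyc <- complete_cycles(seg)
  if (nrow(cyc) == 0) abort("No complete SO cycle in the segmentation.")
  n <- seg$n_samples
  fs <- seg$fs_hz
  values <- rep(NA_real_, n)
  cycle <- rep(NA_integer_, n)
  for (i in seq_len(nrow(cyc))) {
    ds <- round(cyc$down_start_s[i] * fs)
    us <- round(cyc$up_start_s[i] * fs)
    ue <- min(n, round(cyc$up_end_s[i] * fs))
    dj <- (ds + 1L):us
    values[dj] <- 50 * (dj - ds - 1L) / (us - ds)
    if (ue > us) {
      uj <- (us + 1L):ue
      values[uj] <- 50 + 50 * (uj - us - 1L) / (ue - us)
    }
    cycle[(ds + 1L):ue] <- i
  }
  structure(
    list(values = values, bin = pmin(floor(values / 1.25), 79),
         cycle = cycle, fs_hz = fs, n_samples = n),
    class = "phase_vector"
  )
}

#' @export
print.phase_vector <- function(x, ...) {
  cat(sprintf(
    "<phase_vector> %d samples, %d in complete cycles (%d cycles)\n",
    x$n_samples, sum(!is.na(x$values)),
    length(unique(stats::na.omit(x$cycle)))
  ))
  invisible(x)
}
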