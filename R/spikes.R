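# State-resolved spike-train metrics and spike-SO coherence.

#' Filter units by overall firing rate
#'
#' Units whose total rate falls below `min_rate_per_min` are removed:
#' the conventional gates are 10 spikes/min (~0.17 Hz) for firing
#' analysis and 30 spikes/min (0.5 Hz) for coherence analysis.
#'
#' @param spikes Tibble with `unit_id` and `time_s`.
#' @param duration_s Recording duration in seconds.
#' @param min_rate_per_min Minimum rate in spikes per minute.
#' @return The spikes tibble restricted to retained units.
#' @export
filter_units <- function(spikes, duration_s, min_rate_per_min = 10) {
  keep <- spikes |>
    dplyr::count(.data$unit_id) |>
    dplyr::filter(.data$n / duration_s * 60 >= min_rate_per_min) |>
    dplyr::pull(.data$unit_id)
  dplyr::filter(spikes, .data$unit_id %in% keep)
}

# Label each spike with the state containing it, restricted to complete
# cycles; spikes outside complete cycles get "outside".
label_spikes <- function(time_s, seg) {
  cyc <- complete_cycles(seg)
  lab <- rep("outside", length(time_s))
  for (i in seq_len(nrow(cyc))) {
    lab[time_s >= cyc$down_start_s[i] & time_s < cyc$up_start_s[i]] <- "Down"
    lab[time_s >= cyc$up_start_s[i] & time_s < cyc$up_end_s[i]] <- "Up"
  }
  lab
}

#' State-resolved firing metrics per unit
#'
#' Spikes within complete SO cycles are labelled Up or Down by interval
#' membership. Rates divide spike counts by total state occupancy;
#' `rate_total_hz` divides all spikes (irrespective of state) by the
#' recording duration; `pct_up`/`pct_down` are percentages of the firing
#' within complete cycles. ISI statistics are reported over the whole
#' recording and over within-Up-state spike pairs only.
#'
#' @param spikes Tibble with `unit_id`, `time_s` (assumed pre-filtered
#'   with [filter_units()]).
#' @param seg A `uds_segmentation`.
#' @param duration_s Recording duration in seconds.
#' @return Tibble, one row per unit: `unit_id`, `n_spikes`, `n_up`,
#'   `n_down`, `n_outside`, `rate_up_hz`, `rate_down_hz`,
#'   `rate_total_hz`, `pct_up`, `pct_down`, `isi_mean_s`, `isi_cv`,
#'   `isi_up_mean_s`, `isi_up_cv`.
#' @export
state_firing_metrics <- function(spikes, seg, duration_s) {
  if (nrow(seg$states) == 0) abort("Segmentation is empty.")
  cyc <- complete_cycles(seg)
  t_up <- sum(cyc$up_end_s - cyc$up_start_s)
  t_down <- sum(cyc$up_start_s - cyc$down_start_s)
  one_unit <- function(tt) {
    tt <- sort(tt)
    lab <- label_spikes(tt, seg)
    n_up <- sum(lab == "Up"); n_down <- sum(lab == "Down")
    in_cyc <- n_up + n_down
    isi <- diff(tt)
    # within-Up-state pairs: consecutive spikes inside the same Up-state
    up_isi <- numeric(0)
    for (i in seq_len(nrow(cyc))) {
      ui <- tt[tt >= cyc$up_start_s[i] & tt < cyc$up_end_s[i]]
      if (length(ui) > 1) up_isi <- c(up_isi, diff(ui))
    }
    cv <- function(x) if (length(x) < 2 || mean(x) == 0) NA_real_ else
      sd(x) / mean(x)
    tibble(
      n_spikes = length(tt), n_up = n_up, n_down = n_down,
      n_outside = sum(lab == "outside"),
      rate_up_hz = if (t_up > 0) n_up / t_up else NA_real_,
      rate_down_hz = if (t_down > 0) n_down / t_down else NA_real_,
      rate_total_hz = length(tt) / duration_s,
      pct_up = if (in_cyc > 0) 100 * n_up / in_cyc else NA_real_,
      pct_down = if (in_cyc > 0) 100 * n_down / in_cyc else NA_real_,
      isi_mean_s = if (length(isi)) mean(isi) else NA_real_,
      isi_cv = cv(isi),
      isi_up_mean_s = if (length(up_isi)) mean(up_isi) else NA_real_,
      isi_up_cv = cv(up_isi)
    )
  }
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::reframe(one_unit(.data$time_s)) |>
    dplyr::ungroup()
}

#' Magnitude-squared coherence between a spike train and the SO
#'
#' The spike train is binarized at the LFP sampling rate (1 ms bins at
#' 1 kHz; multiple spikes per bin collapse to the bin count) and the
#' coherence \eqn{C_{xy}(f) = |P_{xy}(f)|^2 / (p_{xx}(f) p_{yy}(f))} is
#' estimated by Welch segment averaging (Hann taper, per-segment mean
#' removal). The maximum and its frequency are reported over the SO
#' search band 0.1-0.9 Hz.
#'
#' @param spike_times_s Spike timestamps in seconds.
#' @param so_filtered SO-band filtered LFP at `fs_hz`.
#' @param fs_hz Sampling rate.
#' @param segment_s Welch segment length in seconds (default 60, giving
#'   ~0.017 Hz resolution across the SO band).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param max_freq_hz Truncate the returned spectrum here (default 10).
#' @return A `coherence_result`: `$spectrum` (tibble `freq_hz`,
#'   `coherence`), `$max_coherence`, `$max_freq_hz`, `$n_segments`
#'   (as averaged), `$n_disjoint_segments` (count of non-overlapping
#'   segments, for the analytic null bound).
#' @export
spike_so_coherence <- function(spike_times_s, so_filtered, fs_hz,
                               segment_s = 60, overlap = 0.5,
                               max_freq_hz = 10) {
  n <- length(so_filtered)
  y <- tabulate(pmin(pmax(round(spike_times_s * fs_hz), 1L), n), nbins = n)
  welch_coherence(so_filtered, y, fs_hz, segment_s, overlap, max_freq_hz)
}

#' Welch magnitude-squared coherence between two series
#'
#' @inheritParams spike_so_coherence
#' @param x,y Equal-length numeric series.
#' @param search_band Band (Hz) over which the maximum is reported.
#' @return A `coherence_result` (see [spike_so_coherence()]).
#' @export
welch_coherence <- function(x, y, fs_hz, segment_s = 60, overlap = 0.5,
                            max_freq_hz = 10, search_band = c(0.1, 0.9)) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  nper <- round(segment_s * fs_hz)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  if (length(starts) < 4) {
    abort("Fewer than 4 averaging segments; the estimate is unstable.")
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nper) - 1) / (nper - 1)))
  pxx <- pyy <- numeric(nper)
  pxy <- complex(nper)
  for (s in starts) {
    xi <- x[s:(s + nper - 1L)]; yi <- y[s:(s + nper - 1L)]
    X <- fft((xi - mean(xi)) * w)
    Y <- fft((yi - mean(yi)) * w)
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + Conj(X) * Y
  }
  freq <- (seq_len(nper) - 1) / nper * fs_hz
  keep <- freq <= max_freq_hz & seq_len(nper) <= floor(nper / 2) + 1
  denom <- pxx * pyy
  # bounded by Cauchy-Schwarz; clamp floating-point spill
  coh <- pmin(1, pmax(0, ifelse(denom > 0, Mod(pxy)^2 / denom, 0)))
  spectrum <- tibble(freq_hz = freq[keep], coherence = coh[keep])
  sb <- spectrum[spectrum$freq_hz >= search_band[1] &
                   spectrum$freq_hz <= search_band[2], ]
  i <- which.max(sb$coherence)
  structure(
    list(spectrum = spectrum,
         max_coherence = sb$coherence[i],
         max_freq_hz = sb$freq_hz[i],
         n_segments = length(starts),
         n_disjoint_segments = floor(length(x) / nper)),
    class = "coherence_result"
  )
}

#' Analytic null bound for Welch coherence
#'
#' For `l` disjoint averaging segments and independent signals, the
#' magnitude-squared coherence estimate has CDF
#' \eqn{P(C < c) = 1 - (1 - c)^{l - 1}}; the `1 - alpha` quantile is
#' \eqn{1 - alpha^{1/(l-1)}}. The formula is exact for non-overlapping
#' segments and conservative for an overlapped estimator (which averages
#' slightly more information).
#'
#' @param n_segments Number of disjoint segments `l`.
#' @param alpha Tail probability (default 0.05).
#' @return The coherence quantile.
#' @export
coherence_null_bound <- function(n_segments, alpha = 0.05) {
  if (n_segments < 2) abort("Need at least 2 segments.")
  1 - alpha^(1 / (n_segments - 1))
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf(
    "<coherence_result> max C = %.3f at %.3f Hz (%d segments)\n",
    x$max_coherence, x$max_freq_hz, x$n_segments
  ))
  invisible(x)
}
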