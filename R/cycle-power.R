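# Morlet-wavelet band power aligned to the normalized SO cycle.

#' Instantaneous band area power via complex Morlet wavelets
#'
#' Convolves the z-scored signal with complex Morlet wavelets (analytic,
#' unit-energy, `n_cycles` cycles wide) on a grid of center frequencies
#' spanning the band, and integrates the squared magnitudes across the
#' grid with the trapezoidal rule, giving one nonnegative "area power"
#' value per sample. With unit-energy wavelets the expected area power of
#' white noise is proportional to the bandwidth, and doubling the signal
#' amplitude quadruples the power.
#'
#' @param z_signal Z-scored (dimensionless) signal.
#' @param band A `band_spec` or canonical band name.
#' @param fs_hz Sampling rate.
#' @param freq_step_hz Grid spacing in Hz (default 0.5).
#' @param n_cycles Wavelet width in cycles (default 6).
#' @return Numeric series of instantaneous area power (same length).
#' @export
morlet_band_power <- function(z_signal, band, fs_hz, freq_step_hz = 0.5,
                              n_cycles = 6) {
  band <- check_band(as_band_spec(band), fs_hz)
  freqs <- unique(c(seq(band$lo_hz, band$hi_hz, by = freq_step_hz),
                    band$hi_hz))
  n <- length(z_signal)
  # pad a little beyond the wavelet support (widest at the low edge) so
  # the circular convolution cannot wrap
  support <- ceiling(4 * n_cycles / (2 * pi * band$lo_hz) * fs_hz)
  m <- stats::nextn(n + support, c(2, 3))
  X <- fft(c(z_signal, numeric(m - n)))
  f <- fft_freqs(m, fs_hz)
  df_bin <- fs_hz / m
  pow <- matrix(0, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    fc <- freqs[k]
    sigma_f <- fc / n_cycles
    g <- numeric(m)
    i <- f > 0
    g[i] <- exp(-(f[i] - fc)^2 / (2 * sigma_f^2))
    # unit-energy normalization on the discrete grid
    g <- g / sqrt(sum(g^2) * df_bin)
    w <- fft(X * g, inverse = TRUE)[seq_len(n)] / m
    pow[k, ] <- Mod(w)^2
  }
  # trapezoidal integration across the frequency grid at each sample
  wts <- numeric(length(freqs))
  dfs <- diff(freqs)
  wts[1] <- dfs[1] / 2
  wts[length(freqs)] <- dfs[length(dfs)] / 2
  if (length(freqs) > 2) {
    wts[2:(length(freqs) - 1)] <- (dfs[-length(dfs)] + dfs[-1]) / 2
  }
  as.numeric(crossprod(pow, wts))
}

#' Align an instantaneous power series to the normalized SO cycle
#'
#' Averages the power over all valid samples falling in each of the 80
#' normalized-cycle bins (40 Down, 40 Up), pooling cycles. This
#' compensates for the variable length of SO cycles.
#'
#' @param power Instantaneous power series (sample-aligned with `pv`).
#' @param pv A [build_phase_vector()] result.
#' @param band Optional band label carried into the result.
#' @return A `cycle_power_profile`: `$per_bin` (tibble `bin`, `value`,
#'   `n_samples`), `$n_cycles`, `$band`.
#' @export
align_power_to_cycle <- function(power, pv, band = NULL) {
  if (length(power) != pv$n_samples) {
    abort("`power` and the phase vector must be sample-aligned.")
  }
  ok <- !is.na(pv$bin)
  counts <- tabulate(pv$bin[ok] + 1L, nbins = 80L)
  if (any(counts == 0)) {
    abort(sprintf("Normalized-cycle bin %d has no samples.",
                  which(counts == 0)[1] - 1L))
  }
  sums <- as.numeric(rowsum(power[ok], pv$bin[ok], reorder = TRUE))
  structure(
    list(per_bin = tibble(bin = 0:79, value = sums / counts,
                          n_samples = counts),
         n_cycles = length(unique(stats::na.omit(pv$cycle))),
         band = band),
    class = "cycle_power_profile"
  )
}

#' @export
print.cycle_power_profile <- function(x, ...) {
  cat(sprintf("<cycle_power_profile> band %s, %d cycles\n",
              if (is.null(x$band)) "?" else as_band_spec(x$band)$name,
              x$n_cycles))
  invisible(x)
}

#' Summarize a normalized-cycle power profile
#'
#' Down-state power is the mean over bins 0-39, Up-state power the mean
#' over bins 40-79; the latency to peak power is the center of the
#' maximum bin in normalized units (0-100), ties broken toward the
#' earlier bin.
#'
#' @param profile A `cycle_power_profile`.
#' @return One-row tibble: `down_power`, `up_power`, `peak_power`,
#'   `latency_pct`, `n_cycles`.
#' @export
summarize_cycle_power <- function(profile) {
  v <- profile$per_bin$value
  peak_bin <- which.max(v) - 1L
  tibble(
    down_power = mean(v[1:40]),
    up_power = mean(v[41:80]),
    peak_power = v[peak_bin + 1L],
    latency_pct = peak_bin * 1.25 + 0.625,
    n_cycles = profile$n_cycles
  )
}
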