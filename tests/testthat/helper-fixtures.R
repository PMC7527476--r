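# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

FS <- 1000

# A pure sinusoid as a one-channel voltage series.
sine_wave <- function(freq_hz, amp_mv, duration_s, fs_hz = FS) {
  t <- (seq_len(round(duration_s * fs_hz)) - 1) / fs_hz
  amp_mv * sin(2 * pi * freq_hz * t)
}

# Piecewise half-sine arcs: one arc per state, positive for Up and
# negative for Down. Zero crossings sit exactly on the state boundaries,
# so the planted segmentation is recoverable to within a sample.
arc_signal <- function(labels, durs_s, amp_mv = 0.2, fs_hz = FS) {
  unlist(mapply(function(l, d) {
    k <- round(d * fs_hz)
    arc <- sin(pi * (seq_len(k) - 0.5) / k)
    if (l == "Up") amp_mv * arc else -amp_mv * arc
  }, labels, durs_s, SIMPLIFY = FALSE), use.names = FALSE)
}

# Construct a uds_segmentation directly (bypassing detection) from
# alternating state durations, for tests that need exact boundaries.
manual_seg <- function(labels, durs_s, fs_hz = FS) {
  ends <- cumsum(durs_s)
  starts <- c(0, head(ends, -1))
  n <- round(sum(durs_s) * fs_hz)
  structure(
    list(
      states = tibble::tibble(label = labels, start_s = starts,
                              end_s = ends, chunk = 1L),
      phase = numeric(n), polarity = "pos", fs_hz = fs_hz, n_samples = n
    ),
    class = "uds_segmentation"
  )
}

# A Hann-windowed oscillatory burst added into a background series.
add_burst <- function(x, fs_hz, at_s, dur_s, freq_hz, amp) {
  k <- round(dur_s * fs_hz)
  i <- round(at_s * fs_hz) + seq_len(k)
  tt <- (seq_len(k) - 1) / fs_hz
  env <- 0.5 * (1 - cos(2 * pi * (tt + 0.5 / fs_hz) / dur_s))
  x[i] <- x[i] + amp * env * cos(2 * pi * freq_hz * tt)
  x
}

# One moderately sized default simulation, memoized across tests in the
# same file run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_recording(synth_config(duration_s = 300, seed = 42))
    }
    cache
  }
})
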