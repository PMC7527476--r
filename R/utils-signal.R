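# Low-level spectral primitives shared by the filtering, detection and
# power modules. All filters here are applied in the frequency domain with
# purely real gains, so they are exactly zero-phase by construction.

# Frequency (Hz, signed) of each DFT bin for a length-m signal.
fft_freqs <- function(m, fs_hz) {
  k <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)
  if (m == 1) k <- 0L
  k / m * fs_hz
}

# Apply a real, even gain function of |f| with odd-reflection padding.
# pad_n samples are anti-symmetrically mirrored about each endpoint
# (2*x[end] - reversed interior, preserving value and slope continuity,
# as forward-backward filtering conventionally extends its input) so the
# circular convolution of the DFT cannot wrap filter transients into the
# data.
fft_apply_gain <- function(x, fs_hz, gain_fun, pad_n) {
  n <- length(x)
  pad_n <- max(0L, min(as.integer(pad_n), n - 1L))
  if (pad_n > 0L) {
    left <- 2 * x[1] - x[rev(seq_len(pad_n) + 1L)]
    right <- 2 * x[n] - x[n - seq_len(pad_n)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  m <- length(xp)
  g <- gain_fun(abs(fft_freqs(m, fs_hz)))
  y <- Re(fft(fft(xp) * g, inverse = TRUE)) / m
  y[pad_n + seq_len(n)]
}

# Raised-cosine band-pass gain: unity on [lo, hi], half-cosine transitions
# of widths w_lo / w_hi below lo and above hi, zero beyond.
bandpass_gain <- function(lo, hi, w_lo, w_hi) {
  force(lo); force(hi); force(w_lo); force(w_hi)
  function(f) {
    g <- numeric(length(f))
    g[f >= lo & f <= hi] <- 1
    i <- f >= lo - w_lo & f < lo
    g[i] <- 0.5 * (1 - cos(pi * (f[i] - (lo - w_lo)) / w_lo))
    i <- f > hi & f <= hi + w_hi
    g[i] <- 0.5 * (1 + cos(pi * (f[i] - hi) / w_hi))
    g
  }
}

# Transition width for a band edge: 10% of the edge frequency, clamped to
# [0.05, 4] Hz and never wider than half the edge (so the response is at
# full stop at most one octave out, meeting the 30 dB/octave contract).
edge_transition <- function(edge_hz) {
  min(edge_hz / 2, max(0.05, min(4, 0.1 * edge_hz)))
}

# Analytic signal via the standard DFT construction.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("analytic_signal() needs at least 2 samples.")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

instantaneous_phase <- function(x) Arg(analytic_signal(x))

# Unwrap a phase series (radians).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Centered moving-average smoothing, zero-phase, reflection at the edges.
boxcar_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) / 2L
  n <- length(x)
  xp <- c(rev(x[seq_len(half) + 1L]), x, rev(x[n - seq_len(half)]))
  cs <- cumsum(c(0, xp))
  (cs[(width + 1):(n + width)] - cs[1:n]) / width
}

# Trapezoidal integral of y over grid x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# 1/f-amplitude ("pink") Gaussian noise, flattened below f_floor_hz so the
# variance does not blow up at DC; scaled to the requested SD.
pink_noise <- function(n, fs_hz, sd_mv, f_floor_hz = 0.1) {
  if (sd_mv <= 0 || n == 0) return(numeric(n))
  w <- rnorm(n)
  f <- abs(fft_freqs(n, fs_hz))
  shape <- 1 / sqrt(pmax(f, f_floor_hz))
  shape[1] <- 0 # no DC
  y <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  y * sd_mv / sd(y)
}

# rle() over a logical vector returning run start/end sample indices.
logical_runs <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(value = r$values, start = starts, end = ends)
}

# Derive a deterministic per-purpose substream seed (< 2^31) from a global
# seed, so the state, event, spike and noise draws are independent streams.
substream_seed <- function(seed, purpose) {
  offs <- c(states = 101L, lfp = 211L, events = 307L,
            spikes = 401L, noise = 503L, misc = 601L)
  off <- offs[[purpose]]
  as.integer((as.numeric(seed) * 1103L + off) %% 2147483587)
}
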