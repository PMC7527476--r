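# Envelope-threshold event detection and event metrics.

overlapping <- function(events, start_s, end_s) {
  events[events$end_s > start_s & events$start_s < end_s, ]
}

test_that("a planted spindle burst is detected with its frequency", {
  x <- withr::with_seed(31, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  x <- add_burst(x, FS, at_s = 10, dur_s = 0.5, freq_hz = 11, amp = 0.1)
  ev <- detect_envelope_events(x, FS, spindle_params())
  hit <- overlapping(ev, 10, 10.5)
  expect_equal(nrow(hit), 1)
  dur <- hit$end_s - hit$start_s
  expect_gt(dur, 0.25)
  expect_lt(dur, 0.55)
  expect_lt(abs(hit$inst_freq_hz - 11), 0.5)
  expect_true(hit$start_s < hit$peak_s & hit$peak_s < hit$end_s)
})

test_that("bursts shorter than the minimum duration are rejected", {
  # moderate SNR: at very high SNR the 40 ms smoothing kernel plus the
  # low lower-threshold tails can stretch a 150 ms burst past 200 ms
  x <- withr::with_seed(32, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  x <- add_burst(x, FS, at_s = 10, dur_s = 0.15, freq_hz = 11, amp = 0.04)
  ev <- detect_envelope_events(x, FS, spindle_params())
  expect_equal(nrow(overlapping(ev, 9.95, 10.2)), 0)
})

test_that("nearby burst peaks merge into a single spindle", {
  x <- withr::with_seed(33, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  # two 150 ms bursts whose peaks sit 120 ms apart: each alone fails the
  # duration gate; merged they pass (merge precedes duration filtering)
  x <- add_burst(x, FS, at_s = 10.000, dur_s = 0.15, freq_hz = 11, amp = 0.1)
  x <- add_burst(x, FS, at_s = 10.120, dur_s = 0.15, freq_hz = 11, amp = 0.1)
  ev <- detect_envelope_events(x, FS, spindle_params())
  expect_equal(nrow(overlapping(ev, 9.9, 10.4)), 1)
})

test_that("over-long ripple events are rejected", {
  x <- withr::with_seed(34, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  x <- add_burst(x, FS, at_s = 10, dur_s = 0.8, freq_hz = 100, amp = 0.2)
  ev <- detect_envelope_events(x, FS, ripple_params())
  expect_equal(nrow(overlapping(ev, 10, 10.8)), 0)
  # a 120 ms ripple at the same amplitude is kept
  x2 <- withr::with_seed(34, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  x2 <- add_burst(x2, FS, at_s = 10, dur_s = 0.12, freq_hz = 100, amp = 0.2)
  ev2 <- detect_envelope_events(x2, FS, ripple_params())
  hit <- overlapping(ev2, 10, 10.12)
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$inst_freq_hz - 100), 2)
})

test_that("events never cross a concatenation boundary", {
  x <- withr::with_seed(35, sleeposc:::pink_noise(20 * FS, FS, 0.03))
  x <- add_burst(x, FS, at_s = 9.8, dur_s = 0.5, freq_hz = 11, amp = 0.1)
  ev <- detect_envelope_events(x, FS, spindle_params(),
                               boundaries_s = 10)
  expect_equal(nrow(overlapping(ev, 9.8, 10.3)), 0)
})

test_that("detector rejects degenerate input", {
  expect_error(detect_envelope_events(rep(0, FS * 20), FS,
                                      spindle_params()),
               "constant|variance")
  expect_error(
    detect_envelope_events(rnorm(FS), 200, ripple_params()),
    "Nyquist"
  )
  expect_error(event_params("spindle", 40, 2.5,
                            list(kind = "mean_multiple", value = 1.5),
                            200, 500, 400),
               "dur_min_ms")
})

test_that("spindle false positives on pure pink noise stay rare", {
  # regression bound for the default preset (mean + 2.5 SD upper
  # threshold): the observed rate on 1/f noise is ~3/min
  pn <- withr::with_seed(36, sleeposc:::pink_noise(600 * FS, FS, 0.03))
  ev <- detect_envelope_events(pn, FS, spindle_params())
  expect_lte(nrow(ev) / 10, 4)
})

test_that("event summary metrics follow their definitions", {
  ev <- tibble::tibble(
    kind = "spindle", channel_id = "a",
    start_s = seq(0, 90, by = 10), end_s = seq(0.5, 90.5, by = 10),
    peak_s = seq(0.25, 90.25, by = 10),
    amplitude = rep(4, 10), inst_freq_hz = rep(11, 10)
  )
  seg <- manual_seg(rep(c("Down", "Up"), 20), rep(c(1.5, 1), 20))
  m <- compute_event_metrics(ev, seg = seg)
  expect_equal(m$n_events, 10L)
  expect_equal(m$amplitude_cv, 0)
  expect_equal(m$duration_cv, 0)
  expect_equal(m$density_per_up, 0.5)
  expect_equal(m$mean_inst_freq_hz, 11)
})

test_that("the five-times-mean high-amplitude rule is literal", {
  mk <- function(amps) {
    tibble::tibble(kind = "spindle", channel_id = "a",
                   start_s = seq_along(amps), end_s = seq_along(amps) + 0.5,
                   peak_s = seq_along(amps) + 0.25,
                   amplitude = amps, inst_freq_hz = 11)
  }
  # mean 3.2, threshold 16: even the 12 fails the 5x rule
  expect_equal(compute_event_metrics(mk(c(1, 1, 1, 1, 12)))$pct_high_amplitude, 0)
  # a smaller multiple flags it
  expect_equal(
    compute_event_metrics(mk(c(1, 1, 1, 1, 12)),
                          high_amp_mult = 2)$pct_high_amplitude, 20
  )
})

test_that("an empty event list yields an NA summary, not zeros", {
  ev <- detect_envelope_events(
    withr::with_seed(37, sleeposc:::pink_noise(40 * FS, FS, 0.03)),
    FS, spindle_params()
  )[0, ]
  m <- compute_event_metrics(ev)
  expect_equal(m$n_events, 0L)
  expect_true(is.na(m$mean_amplitude))
  expect_true(is.na(m$density_per_up))
})

test_that("spindles planted at Up-state onset have early Up latencies", {
  cfg <- synth_config(duration_s = 180, seed = 38,
                      spindle_rate_per_up = 1, ripple_rate_per_up = 0)
  sim <- simulate_recording(cfg)
  x <- notch_line(channel_signal(sim$recording, 1), fs_hz = FS)
  seg <- detect_uds(so_filter(x, FS), FS)
  pv <- build_phase_vector(seg)
  ev <- event_latency(detect_envelope_events(x, FS, spindle_params()), pv)
  m <- compute_event_metrics(ev, seg = seg)
  expect_gt(m$mean_latency_pct, 50)
  expect_lt(m$mean_latency_pct, 80)
})
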