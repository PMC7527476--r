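# Synthetic generator: state sequences, planted events, spikes, matching.

test_that("constant duration specs tile the recording exactly", {
  cfg <- synth_config(
    duration_s = 10,
    up_dur = dur_spec("gamma", 1.0, cv = 0),
    down_dur = dur_spec("gamma", 1.0, cv = 0)
  )
  truth <- generate_state_sequence(cfg)
  st <- truth$states
  expect_equal(sum(st$label == "Up"), 5)
  expect_equal(sum(st$label == "Down"), 5)
  expect_equal(st$end_s - st$start_s, rep(1, 10))
  # strict alternation and gapless tiling of [0, duration)
  expect_true(all(st$label[-1] != st$label[-nrow(st)]))
  expect_equal(st$start_s[-1], st$end_s[-nrow(st)])
  expect_equal(st$start_s[1], 0)
  expect_equal(st$end_s[nrow(st)], 10)
})

test_that("configured duration means are recovered from the sample", {
  cfg <- synth_config(
    duration_s = 600,
    up_dur = dur_spec("gamma", 0.6, 0.3),
    down_dur = dur_spec("gamma", 0.8, 0.3),
    seed = 3
  )
  st <- generate_state_sequence(cfg)$states
  st <- st[-nrow(st), ] # last state is truncated
  up <- st$end_s[st$label == "Up"] - st$start_s[st$label == "Up"]
  dn <- st$end_s[st$label == "Down"] - st$start_s[st$label == "Down"]
  expect_gt(length(up) + length(dn), 200)
  expect_lt(abs(mean(up) - 0.6) / 0.6, 0.05)
  expect_lt(abs(mean(dn) - 0.8) / 0.8, 0.05)
})

test_that("lognormal duration family is supported and means recover", {
  cfg <- synth_config(
    duration_s = 600,
    up_dur = dur_spec("lognormal", 1.0, 0.4),
    down_dur = dur_spec("lognormal", 1.2, 0.4),
    seed = 4
  )
  st <- generate_state_sequence(cfg)$states
  up <- st$end_s[st$label == "Up"] - st$start_s[st$label == "Up"]
  expect_lt(abs(mean(head(up, -1)) - 1.0), 0.05 * 1.0 + 0.03)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- synth_config(duration_s = 60, seed = 123)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$truth$states, b$truth$states)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$spikes, b$spikes)
})

test_that("invalid configurations are rejected", {
  expect_error(dur_spec("gamma", -1), "positive")
  expect_error(synth_config(spindle_freq_hz = 20), "8, 15")
  expect_error(synth_config(ripple_freq_hz = 200), "80, 130")
  expect_error(synth_config(spike_rate_up_hz = -1), "rates")
  expect_error(synth_config(fs_hz = 200), "twice")
})

test_that("planted events are legal and land inside Up-states", {
  cfg <- synth_config(duration_s = 300, seed = 11,
                      spindle_rate_per_up = 1, ripple_rate_per_up = 1)
  sim <- simulate_recording(cfg)
  ev <- sim$truth$events
  spin <- ev[ev$kind == "spindle", ]
  rip <- ev[ev$kind == "ripple", ]
  expect_gt(nrow(spin), 50)
  expect_gt(nrow(rip), 50)
  expect_true(all(spin$end_s - spin$start_s >= 0.2 &
                    spin$end_s - spin$start_s <= 2))
  expect_true(all(rip$end_s - rip$start_s >= 0.02 &
                    rip$end_s - rip$start_s <= 0.4))
  expect_true(all(ev$start_s >= 0 & ev$end_s <= cfg$duration_s))
  # every event lies inside a planted Up-state
  ups <- sim$truth$states[sim$truth$states$label == "Up", ]
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    any(ups$start_s <= ev$start_s[i] & ups$end_s >= ev$end_s[i])
  }, logical(1))
  expect_true(all(inside))
})

test_that("unit rate of one plants one spindle per sufficiently long Up-state", {
  cfg <- synth_config(
    duration_s = 120, seed = 2,
    up_dur = dur_spec("gamma", 1.2, cv = 0),
    down_dur = dur_spec("gamma", 1.2, cv = 0),
    spindle_rate_per_up = 1, ripple_rate_per_up = 0,
    spindle_dur = dur_spec("gamma", 0.5, cv = 0)
  )
  sim <- simulate_recording(cfg)
  n_up <- sum(sim$truth$states$label == "Up" &
                sim$truth$states$end_s - sim$truth$states$start_s > 0.6)
  expect_equal(sum(sim$truth$events$kind == "spindle"), n_up)
})

test_that("SO-band peak-to-trough of the clean generator matches the config", {
  cfg <- synth_config(
    duration_s = 120, seed = 5, so_amplitude_mv = 0.2,
    band_bursts = list(), spindle_rate_per_up = 0, ripple_rate_per_up = 0,
    noise_pink_sd = 0, line_50hz_amp = 0, n_units = 0
  )
  sim <- simulate_recording(cfg)
  x <- channel_signal(sim$recording, 1)
  so_f <- so_filter(x, FS)
  p2t <- sleeposc:::so_cycle_p2t(sim$truth$states, so_f, FS, length(x))
  expect_lt(abs(mean(p2t) - 0.2) / 0.2, 0.1)
})

test_that("spike rates follow the planted states", {
  cfg <- synth_config(duration_s = 600, seed = 7, n_units = 3)
  sim <- simulate_recording(cfg)
  st <- sim$truth$states
  t_up <- sum(st$end_s[st$label == "Up"] - st$start_s[st$label == "Up"])
  t_dn <- sum(st$end_s[st$label == "Down"] - st$start_s[st$label == "Down"])
  sp <- sim$spikes
  rate_up <- sum(sp$state == "Up") / (3 * t_up)
  rate_dn <- sum(sp$state == "Down") / (3 * t_dn)
  expect_lt(abs(rate_up - 3) / 3, 0.1)
  expect_lt(abs(rate_dn - 0.3) / 0.3, 0.1)
  # zero Down rate puts no spike in a Down-state
  cfg0 <- synth_config(duration_s = 60, seed = 8, spike_rate_down_hz = 0)
  sim0 <- simulate_recording(cfg0)
  expect_equal(sum(sim0$spikes$state == "Down"), 0)
})

test_that("greedy event matching scores the hand-built interval set", {
  # 10 truth events of 1 s on a regular grid; 8 detections: 7 overlap
  # their truth event by >= 50%, one falls in a gap
  truth <- tibble::tibble(start_s = seq(0, 90, by = 10),
                          end_s = seq(1, 91, by = 10))
  det <- tibble::tibble(
    start_s = c(seq(0.3, 60.3, by = 10), 75),
    end_s = c(seq(1.1, 61.1, by = 10), 75.8)
  )
  mr <- match_events(det, truth, min_overlap_frac = 0.5)
  expect_equal(mr$n_matched, 7)
  expect_equal(mr$precision, 7 / 8)
  expect_equal(mr$recall, 0.7)
  expect_equal(nrow(mr$matches), 7)
  expect_equal(mr$matches$onset_error_ms,
               rep(300, 7), tolerance = 1e-9)
})

test_that("event matching handles identity and empty edge cases", {
  truth <- tibble::tibble(start_s = c(1, 5), end_s = c(2, 6))
  mr <- match_events(truth, truth)
  expect_equal(mr$precision, 1)
  expect_equal(mr$recall, 1)
  empty <- truth[0, ]
  expect_warning(mr0 <- match_events(empty, truth), "precision")
  expect_equal(mr0$precision, 0)
  expect_equal(mr0$recall, 0)
  expect_error(match_events(truth, truth, min_overlap_frac = 1.5), "0, 1")
})
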