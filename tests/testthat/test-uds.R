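# Up/Down-state detection, SO metrics, and the phase vector.

test_that("a sinusoid is split at its analytic zero crossings", {
  x <- sine_wave(0.5, 0.2, 20)
  seg <- detect_uds(so_filter(x, FS), FS)
  st <- seg$states
  # ~1 s Up alternating with ~1 s Down, 9-10 complete cycles minus edges
  expect_true(all(abs((st$end_s - st$start_s) - 1) < 0.01))
  expect_true(all(st$label[-1] != st$label[-nrow(st)]))
  expect_gte(nrow(complete_cycles(seg)), 8)
  # transitions coincide with the sine's zero crossings (integer seconds)
  expect_true(all(abs(st$start_s - round(st$start_s)) <= 2 / FS))
})

test_that("the amplitude gate suppresses sub-threshold oscillations", {
  x <- sine_wave(0.5, 0.04, 20)
  seg <- detect_uds(so_filter(x, FS), FS)
  expect_equal(sum(seg$states$label == "Up"), 0)
  # at 0.2 mV the same oscillation passes
  seg2 <- detect_uds(so_filter(sine_wave(0.5, 0.2, 20), FS), FS)
  expect_gt(sum(seg2$states$label == "Up"), 0)
})

test_that("candidate Up-states under 300 ms are absorbed into the Down-state", {
  labels <- rep(c("Down", "Up"), 8)
  durs <- rep(1, 16)
  labels <- append(labels, c("Up", "Down"), after = 7) # ...Up, [Up 0.25, Down 1], Down...
  durs <- append(durs, c(0.25, 1), after = 7)
  x <- arc_signal(labels, durs)
  seg <- detect_uds(x, FS)
  st <- seg$states
  up_len <- st$end_s[st$label == "Up"] - st$start_s[st$label == "Up"]
  expect_true(all(up_len >= 0.3))
  # the absorbed candidate merges its flanking Down-states into one
  t0 <- sum(durs[1:8]) # start of the 0.25 s candidate
  host <- st[st$start_s <= t0 & st$end_s >= t0 + 0.25, ]
  expect_equal(nrow(host), 1)
  expect_equal(host$label, "Down")
  expect_gt(host$end_s - host$start_s, 2)
})

test_that("short recordings with too few cycles are rejected", {
  expect_error(detect_uds(so_filter(sine_wave(0.5, 0.2, 5), FS), FS),
               "cycles")
})

test_that("forced polarity flips the state assignment", {
  x <- arc_signal(rep(c("Down", "Up"), 10), rep(1, 20))
  pos <- detect_uds(x, FS, polarity = "pos")
  neg <- detect_uds(x, FS, polarity = "neg")
  i <- findInterval(5.5, pos$states$start_s)
  j <- findInterval(5.5, neg$states$start_s)
  expect_false(pos$states$label[i] == neg$states$label[j])
})

test_that("gamma-envelope polarity resolution finds the active state", {
  sim <- default_sim()
  x <- channel_signal(sim$recording, 1)
  seg <- detect_uds(so_filter(x, FS), FS, polarity = "auto", raw = x)
  expect_equal(seg$polarity, "pos")
  # inverted recording (electrode polarity flip) resolves to neg
  seg_inv <- detect_uds(so_filter(-x, FS), FS, polarity = "auto", raw = -x)
  expect_equal(seg_inv$polarity, "neg")
  g <- glance(seg_inv)
  expect_lt(abs(g$mean_up_s - glance(seg)$mean_up_s), 0.05)
})

test_that("SO metrics recover construction on deterministic input", {
  x <- arc_signal(rep(c("Down", "Up"), 30), rep(1, 60))
  seg <- detect_uds(x, FS)
  m <- so_metrics(seg, x)
  expect_equal(m$so_freq_hz, 0.5, tolerance = 0.01)
  expect_equal(m$mean_cycle_s, 2, tolerance = 0.01)
  # half-sine arcs of amplitude 0.2: peak-to-trough 0.4
  expect_equal(m$so_amplitude_mv, 0.4, tolerance = 0.02)

  s <- sine_wave(0.5, 0.15, 60)
  segs <- detect_uds(so_filter(s, FS), FS)
  ms <- so_metrics(segs, so_filter(s, FS))
  expect_equal(ms$so_amplitude_mv, 0.3, tolerance = 0.05 * 0.3)
  expect_equal(ms$so_freq_hz, 0.5, tolerance = 0.01)
  # consistency: frequency equals 1 / mean cycle within 2%
  expect_lt(abs(ms$so_freq_hz * ms$mean_cycle_s - 1), 0.02)
})

test_that("simulator states are recovered with accurate boundaries", {
  sim <- default_sim()
  x <- channel_signal(sim$recording, 1)
  so_f <- so_filter(x, FS)
  seg <- detect_uds(so_f, FS, raw = x)
  m <- so_metrics(seg, so_f)
  tu <- sim$truth$states
  true_up <- mean(tu$end_s[tu$label == "Up"] - tu$start_s[tu$label == "Up"])
  true_dn <- mean(tu$end_s[tu$label == "Down"] -
                    tu$start_s[tu$label == "Down"])
  expect_lt(abs(m$mean_up_s - true_up) / true_up, 0.1)
  expect_lt(abs(m$mean_down_s - true_dn) / true_dn, 0.1)
  true_freq <- sum(tu$label == "Up") / 300
  expect_lt(abs(m$so_freq_hz - true_freq) / true_freq, 0.05)
  # boundary recall at +/-100 ms
  st <- seg$states
  err <- c(
    vapply(tu$start_s[tu$label == "Up"], function(t) {
      min(abs(st$start_s[st$label == "Up"] - t))
    }, numeric(1)),
    vapply(tu$start_s[tu$label == "Down"], function(t) {
      min(abs(st$start_s[st$label == "Down"] - t))
    }, numeric(1))
  )
  expect_gt(mean(err <= 0.1), 0.95)
})

test_that("phase vector is exact on constructed cycles", {
  seg <- manual_seg(rep(c("Down", "Up"), 4), rep(1, 8))
  pv <- build_phase_vector(seg)
  # transition samples: Down onset of cycle 2 at t = 2 s
  i_down <- round(2 * FS) + 1
  expect_equal(pv$values[i_down], 0)
  i_up <- round(3 * FS) + 1
  expect_equal(pv$values[i_up], 50)
  # midpoints
  expect_equal(pv$values[round(2.5 * FS) + 1], 25)
  expect_equal(pv$values[round(3.5 * FS) + 1], 75)
  # exactly 40 bins per state, nondecreasing within each cycle
  c2 <- which(pv$cycle == 2)
  expect_setequal(unique(pv$bin[c2][pv$values[c2] < 50]), 0:39)
  expect_setequal(unique(pv$bin[c2][pv$values[c2] >= 50]), 40:79)
  expect_true(all(diff(pv$values[c2]) >= 0))
})

test_that("phase vector respects asymmetric cycles", {
  seg <- manual_seg(rep(c("Down", "Up"), 4), rep(c(0.4, 1.6), 4))
  pv <- build_phase_vector(seg)
  # the 50 mark is hit at the Down-to-Up transition (0.4 s into cycle 1)
  expect_equal(pv$values[round(0.4 * FS) + 1], 50)
  expect_equal(pv$values[round(0.2 * FS) + 1], 25)
  # linearity has different slopes on the two states
  expect_equal(pv$values[round(1.2 * FS) + 1], 75)
})

test_that("retained states always alternate and respect the duration gate", {
  for (seed in c(1, 2, 3)) {
    cfg <- synth_config(duration_s = 60, seed = seed)
    sim <- simulate_recording(cfg)
    x <- channel_signal(sim$recording, 1)
    seg <- detect_uds(so_filter(x, FS), FS)
    st <- seg$states
    expect_true(all(st$label[-1] != st$label[-nrow(st)]))
    expect_true(all(st$end_s > st$start_s))
    up_len <- st$end_s[st$label == "Up"] - st$start_s[st$label == "Up"]
    expect_true(all(up_len >= 0.3 - 1.5 / FS))
  }
})
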