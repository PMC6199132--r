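test_that("detect_spikes finds constructed spikes and honours the refractory", {
  tr <- spiky_trace(c(0.5, 1.0, 1.5), amp = 40, base = -55)
  ev <- detect_spikes(tr, threshold = -20)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$time, c(0.5, 1.0, 1.5), tolerance = 1e-6)
  expect_equal(ev$amplitude, rep(40, 3), tolerance = 0.5)
  # two peaks 1 ms apart with 2 ms refractory: larger kept
  tt <- seq(0, 0.1, by = 1e-4)
  v <- rep(-55, length(tt))
  v[tt >= 0.049 & tt <= 0.0492] <- -20
  v[abs(tt - 0.050) < 1e-9] <- -15
  ev2 <- detect_spikes(cg_trace("c", 0, 1e-4, v), threshold = -30,
                       refractory = 0.002)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$time, 0.050, tolerance = 1e-9)
  expect_error(detect_spikes(cg_trace("f", 0, 1e-3, rep(-60, 100))), "MAD")
})

test_that("spike detection on generated data matches the answer key", {
  rec <- cached_control_rec()
  gt <- rec$metadata$ground_truth
  truth <- sort(c(gt$sc_spikes, unlist(gt$lc_spikes)))
  ev <- detect_spikes(rec$traces$extra)
  recall <- mean(vapply(truth, function(t0) any(abs(ev$time - t0) <= 0.002),
                        logical(1)))
  fp <- sum(vapply(ev$time, function(t0) !any(abs(truth - t0) <= 0.002),
                   logical(1)))
  expect_gte(recall, 0.99)
  expect_equal(fp, 0)
})

test_that("amplitude classification separates SC from LC", {
  ev <- event_series(c(1, 2, 3, 4), amplitudes = c(0.1, 0.11, 0.95, 1.0))
  cl <- classify_units(ev)
  expect_equal(cl$label, c("SC", "SC", "LC", "LC"))
  expect_false(attr(cl, "ambiguous"))
  # degenerate: all equal amplitudes -> ambiguous flag, labels returned
  expect_warning(
    cl2 <- classify_units(event_series(1:4, amplitudes = rep(0.5, 4))),
    "ambiguous")
  expect_true(attr(cl2, "ambiguous"))
  expect_equal(nrow(cl2), 4)
  # generated extracellular trace: labels match the ground-truth classes
  rec <- cached_control_rec()
  gt <- rec$metadata$ground_truth
  cl3 <- classify_units(detect_spikes(rec$traces$extra))
  lc_truth <- sort(unlist(gt$lc_spikes))
  for (i in seq_len(nrow(cl3))) {
    near_lc <- any(abs(lc_truth - cl3$time[i]) <= 0.002)
    near_sc <- any(abs(gt$sc_spikes - cl3$time[i]) <= 0.002)
    if (near_lc && !near_sc) expect_equal(cl3$label[i], "LC")
    if (near_sc && !near_lc) expect_equal(cl3$label[i], "SC")
  }
})

test_that("burst grouping equals the brute-force run splitter", {
  b <- group_bursts(c(0, .1, .2, 2.0, 2.1), max_isi = 0.5)
  expect_equal(b$n_spikes, c(3L, 2L))
  expect_equal(nrow(group_bursts(numeric(0), 0.5)), 0)
  set.seed(99)
  for (k in 1:200) {
    times <- sort(runif(sample(1:30, 1), 0, 10))
    max_isi <- runif(1, 0.05, 2)
    got <- group_bursts(times, max_isi)
    want <- split_runs_bf(times, max_isi)
    expect_equal(nrow(got), length(want))
    expect_equal(got$spike_times, unname(want))
  }
})

test_that("cycle segmentation follows the pacemaker-anchor rule", {
  # SC bursts at 0, 2, 4 s; LC bursts at 0.2 s and 2.2 s -> 2 single cycles
  sc <- c(0, 0.02, 0.04, 2, 2.02, 2.04, 4, 4.02, 4.04)
  lc <- c(0.2, 0.25, 0.3, 2.2, 2.25, 2.3)
  cyc <- segment_cycles(sc, lc)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$t_start, c(0, 2))
  expect_equal(cyc$mode, c("single", "single"))
  expect_equal(cyc$sc_off_time, c(0.04, 2.04))
  # two LC bursts inside one cycle -> double
  lc2 <- c(0.3, 0.35, 1.2, 1.25, 2.2, 2.25)
  cyc2 <- segment_cycles(sc, lc2)
  expect_equal(cyc2$mode[1], "double")
  expect_equal(nrow(cyc2$lc_bursts[[1]]), 2)
  expect_error(segment_cycles(c(1, 1.02), lc), "cycles")
  # generated data: cycle starts equal the drive onsets within 10 ms
  rec <- cached_control_rec()
  an <- analyze_quiet(rec)
  on <- rec$metadata$ground_truth$cycles$t_onset
  offs <- vapply(an$cycles$t_start, function(t0) min(abs(on - t0)), numeric(1))
  expect_lt(max(offs), 0.010)
})

test_that("baseline estimation targets the inter-burst resting level", {
  # constant trace at -60 -> exactly -60
  cyc <- segment_cycles(c(0, 0.02, 2, 2.02, 4, 4.02), c(0.2, 0.3, 2.2, 2.3))
  flat <- cg_trace("x", 0, 1e-3, rep(-60, 5000))
  expect_equal(estimate_baseline(flat, cyc)$rest, -60)
  # generated cell: estimate within 3 mV of the leak reversal (-60 mV; the
  # estimate sits slightly below it because of the afterhyperpolarisation)
  rec <- cached_control_rec()
  an <- analyze_quiet(rec)
  expect_lt(abs(an$rest$rest - (-60)), 3)
  # double-bursting drive: inter-burst windows exclude the intra-cycle
  # floor, so the estimate stays near rest
  spec <- apply_modulator(network_spec(seed = 4), "5HT", seed = 4)
  rec2 <- simulate_cg_network(spec, duration = 15, seed = 4)
  an2 <- analyze_quiet(rec2)
  expect_lt(abs(an2$rest$rest - (-60)), 5)
})

test_that("waveform bounds apply the single and double burst rules", {
  # single mode: t_end = first crossing of rest + tol after the last spike
  tt <- seq(0, 2.5, by = 1e-3)
  v <- ifelse(tt < 0.2, -60,
              ifelse(tt < 1.0, -30, -60 + 30 * exp(-(tt - 1.0) / 0.13)))
  tr <- cg_trace("x", 0, 1e-3, v)
  cyc <- data.frame(t_start = 0, t_next = 2.5, sc_off_time = 0.45,
                    mode = "single", n_lc_bursts = 1)
  cyc$lc_bursts <- list(group_bursts(seq(0.25, 1.0, by = 0.1), 0.25))
  b <- mark_waveform_bounds(cyc[1, ], tr, rest = -60, tol = 2)
  expect_equal(b$t_begin, 0)
  # crossing of -58: -60 + 30 exp(-dt/0.13) = -58 -> dt = 0.13 log(15)
  expect_equal(b$t_end, 1.0 + 0.13 * log(15), tolerance = 2e-3)
  expect_false(b$unterminated)
  # double-mode arithmetic from the stated rules
  v2 <- rep(-55, length(tt))  # always above rest + tol except the tail
  v2[tt >= 5.3 / 2.5] <- -60  # unused; construct explicit trace below
  tt2 <- seq(0, 6, by = 1e-3)
  v3 <- ifelse(tt2 < 5.3, -40, -60)
  tr2 <- cg_trace("y", 0, 1e-3, v3)
  cyc2 <- data.frame(t_start = 0, t_next = 6, sc_off_time = 2.5,
                     mode = "double", n_lc_bursts = 2)
  cyc2$lc_bursts <- list(group_bursts(c(0.2, 0.8, 1.4, 3.0, 4.0, 5.0), 1.2))
  b2 <- mark_waveform_bounds(cyc2[1, ], tr2, rest = -60, tol = 2)
  # delta_end = 5.3 - 5.0 = 0.3 -> burst-1 end = 1.4 + 0.3 = 1.7
  # delta_begin = 0.2 - 0 = 0.2 -> burst-2 begin = 3.0 - 0.2 = 2.8
  expect_equal(b2$t_end[1], 1.7, tolerance = 2e-3)
  expect_equal(b2$t_begin[2], 2.8, tolerance = 2e-3)
  expect_equal(b2$t_end[2], 5.3, tolerance = 2e-3)
  # never-recovering trace: capped at t_next with the unterminated flag
  tr3 <- cg_trace("z", 0, 1e-3, rep(-30, 6001))
  b3 <- mark_waveform_bounds(cyc[1, ], tr3, rest = -60, tol = 2)
  expect_true(b3$unterminated)
  expect_equal(b3$t_end, 2.5)
})

test_that("segmentation is deterministic and bounds stay inside cycles", {
  rec <- cached_control_rec()
  a1 <- analyze_quiet(rec)
  a2 <- analyze_quiet(rec)
  expect_identical(a1$cycles$t_start, a2$cycles$t_start)
  expect_identical(a1$sync$r2, a2$sync$r2)
  for (k in seq_len(nrow(a1$cycles))) {
    b <- mark_waveform_bounds(a1$cycles[k, ], rec$traces$LC1, a1$rest$rest)
    expect_true(all(b$t_begin >= a1$cycles$t_start[k]))
    expect_true(all(b$t_end <= a1$cycles$t_next[k]))
    if (nrow(b) == 2) expect_lte(b$t_end[1], b$t_begin[2])
  }
})

test_that("every ground-truth LC burst maps to one detected burst", {
  rec <- cached_control_rec()
  gt <- rec$metadata$ground_truth
  det <- detect_spikes(rec$traces$LC1, threshold = -42)
  got <- group_bursts(det$time, 0.25)
  want <- group_bursts(gt$lc_spikes$LC1, 0.25)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$t_first, want$t_first, tolerance = 5e-3)
  expect_equal(got$n_spikes, want$n_spikes)
})
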