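test_that("analytic passive pair matches the hand-solved resistive star", {
  # Rm1 = Rm2 = 5, Rc = 10: hand solution of the two-node star gives
  # Rin = 5*15/20 = 3.75, R12 = 25/20 = 1.25, cc = 5/15 = 1/3
  an <- analytic_passive_pair(passive_pair_spec(Rm1 = 5, Rm2 = 5, Rc = 10))
  expect_equal(an$Rin1, 3.75)
  expect_equal(an$R12, 1.25)
  expect_equal(an$cc12, 1 / 3)
  # uncoupled limit
  an0 <- analytic_passive_pair(passive_pair_spec(Rm1 = 5, Rm2 = 7, Rc = Inf))
  expect_equal(an0$R12, 0)
  expect_equal(an0$cc12, 0)
  expect_equal(an0$Rin1, 5)
  # cc12 -> 1 as Rc/Rm2 -> 0
  an1 <- analytic_passive_pair(passive_pair_spec(Rm1 = 5, Rm2 = 1e9, Rc = 10))
  expect_gt(an1$cc12, 1 - 1e-7)
  expect_error(passive_pair_spec(Rm1 = -1), "positive")
})

test_that("passive-pair simulation converges to the analytic steady state", {
  spec <- passive_pair_spec(Rm1 = 5, Rm2 = 5, Rc = 10)
  an <- analytic_passive_pair(spec)
  # steady-state deflection of a -8 nA step: dV = R * I
  rec <- simulate_passive_pair(spec, seed = 1)
  ep <- rec$epochs[rec$epochs$amplitude == -8 &
                     rec$epochs$injected_cell == "LC4", ]
  d_inj <- measure_deltaV(rec$traces$LC4, ep)
  d_cpl <- measure_deltaV(rec$traces$LC5, ep)
  expect_equal(d_inj$dV, an$Rin1 * -8, tolerance = 1e-3 / 30)  # < 0.1 %
  expect_equal(d_cpl$dV, an$R12 * -8, tolerance = 1e-3 / 10)
  expect_false(d_inj$short_step)
  # the endpoint value after >= 10 tau is exact to near machine precision
  vend <- trace_at(rec$traces$LC4, ep$t_end)
  expect_equal(vend, spec$E_rest + an$Rin1 * -8, tolerance = 1e-10)
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- passive_pair_spec(noise_sd = 0.2)
  r1 <- simulate_passive_pair(spec, seed = 5)
  r2 <- simulate_passive_pair(spec, seed = 5)
  expect_identical(r1$traces$LC4$samples, r2$traces$LC4$samples)
  n1 <- simulate_cg_network(network_spec(seed = 3), duration = 8, seed = 3)
  n2 <- simulate_cg_network(network_spec(seed = 3), duration = 8, seed = 3)
  expect_identical(n1$traces$LC1$samples, n2$traces$LC1$samples)
  expect_identical(n1$traces$extra$samples, n2$traces$extra$samples)
})

test_that("noisy deltaV estimates are unbiased over seeds", {
  spec <- passive_pair_spec(Rm1 = 5, Rm2 = 5, Rc = 10, noise_sd = 0.1)
  an <- analytic_passive_pair(spec)
  ests <- vapply(1:50, function(s) {
    rec <- simulate_passive_pair(spec, seed = s)
    ep <- rec$epochs[rec$epochs$amplitude == -8 &
                       rec$epochs$injected_cell == "LC4", ]
    measure_deltaV(rec$traces$LC4, ep)$dV
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - an$Rin1 * -8), 3 * se + 1e-6)
})

test_that("simulation preconditions are enforced", {
  expect_error(simulate_passive_pair(passive_pair_spec(), dt = 1e-3), "dt")
  expect_error(simulate_cg_network(network_spec(), duration = 3), "periods")
  expect_error(network_spec(gc = -1))
  expect_error(network_spec(sc_amp = 2, lc_amp = 1), "amplitude")
  gcm <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(network_spec(gc = gcm), "symmetric")
})

test_that("halving the integration step leaves the solution unchanged", {
  spec <- network_spec(cv_g = 0.2, noise_nA = 0, noise_mV = 0, seed = 6)
  r1 <- simulate_cg_network(spec, duration = 8, dt = 5e-5, seed = 6)
  r2 <- simulate_cg_network(spec, duration = 8, dt = 2.5e-5, seed = 6)
  s1 <- r1$metadata$ground_truth$lc_spikes$LC1
  s2 <- r2$metadata$ground_truth$lc_spikes$LC1
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 2e-3)
  # away from spikes (where a sub-ms timing shift dominates pointwise
  # differences) the voltages agree closely
  tt <- trace_times(r1$traces$LC1)
  near_spike <- vapply(tt, function(t0) any(abs(s1 - t0) < 0.01), logical(1))
  dv <- abs(r1$traces$LC1$samples - r2$traces$LC1$samples)
  expect_lt(max(dv[!near_spike]), 0.5)
})

test_that("identical cells with strong coupling give near-perfect synchrony", {
  spec <- network_spec(cv_g = 0, gc = 2, seed = 11)
  rec <- simulate_cg_network(spec, duration = 15, seed = 11)
  an <- analyze_recording(rec)
  expect_gt(median(an$sync$r2, na.rm = TRUE), 0.99)
})

test_that("synchrony rises monotonically with gap-junction conductance", {
  gcs <- c(0, 0.1, 0.5, 1.0)
  med <- sapply(gcs, function(g) {
    r2 <- sapply(1:4, function(s) {
      spec <- network_spec(cv_g = 0.3, gc = g, seed = s)
      rec <- simulate_cg_network(spec, duration = 12, seed = s)
      median(sync_for_test(rec)$r2, na.rm = TRUE)
    })
    median(r2)
  })
  expect_gt(cor(gcs, med, method = "spearman"), 0)
  # uncoupled heterogeneous cells are strictly less synchronous than the
  # same seeds with strong coupling
  expect_lt(med[1], med[4])
})

test_that("double-envelope drive yields two bursts with an elevated floor", {
  spec <- apply_modulator(network_spec(seed = 4), "5HT", seed = 4)
  rec <- simulate_cg_network(spec, duration = 15, seed = 4)
  an <- analyze_recording(rec)
  expect_true(all(an$cycles$mode == "double"))
  cy <- an$cycles[2, ]
  lb <- cy$lc_bursts[[1]]
  w <- trace_window(rec$traces$LC1, lb$t_last[1], lb$t_first[2])
  expect_gt(min(w$v), an$rest$rest + an$params$tol)
})

test_that("modulator transforms compose commutatively and reproducibly", {
  spec <- network_spec(seed = 9)
  ab <- apply_modulator(apply_modulator(spec, "DA", seed = 9), "5HT", seed = 9)
  ba <- apply_modulator(apply_modulator(spec, "5HT", seed = 9), "DA", seed = 9)
  for (f in c("fb", "fd", "fw", "fgc")) expect_equal(ab$mod[[f]], ba$mod[[f]])
  once <- apply_modulator(spec, "DA+5HT", seed = 9)
  expect_equal(ab$mod$fb, once$mod$fb)
  expect_equal(ab$mod$fgc, once$mod$fgc)
  # DA with gc_scale 2.5 multiplies every off-diagonal gc entry
  da <- apply_modulator(network_spec(gc = 0.4, seed = 1), "DA")
  expect_equal(da$mod$fgc, 2.5)
  expect_error(apply_modulator(spec, "octopamine"), "unknown")
})
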