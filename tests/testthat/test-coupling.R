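test_that("deltaV extraction averages the step tail minus baseline", {
  tr <- step_trace(v0 = -60, v1 = -75)
  ep <- protocol_epoch("LC4", -4, 1, 2, baseline_window = 0.5)
  m <- measure_deltaV(tr, ep)
  expect_equal(m$dV, -15, tolerance = 1e-3)
  # a spike artifact in the baseline is excised before averaging
  tr2 <- tr
  idx <- which(abs(trace_times(tr2) - 0.8) < 0.005)
  tr2$samples[idx] <- -20
  m2 <- measure_deltaV(tr2, ep)
  expect_equal(m2$dV, -15, tolerance = 0.1)
  expect_error(measure_deltaV(tr, protocol_epoch("LC4", -4, 2.5, 3.5)),
               "outside")
})

test_that("coupling coefficient is the deflection ratio with flags", {
  expect_equal(coupling_coefficient(-0.5, -10)$cc, 0.05)
  expect_equal(coupling_coefficient(0, -10)$cc, 0)
  expect_false(coupling_coefficient(-0.5, -10)$suspect)
  expect_true(coupling_coefficient(-12, -10)$suspect)   # cc > 1
  expect_true(coupling_coefficient(0.5, -10)$suspect)   # negative cc
  expect_error(coupling_coefficient(-1, 0), "zero")
  # passive pair Rm 5/5, Rc 10: cc = Rm2/(Rc + Rm2) = 1/3
  rec <- simulate_passive_pair(passive_pair_spec(5, 5, 10), seed = 1)
  cr <- coupling_from_protocol(rec, c("LC4", "LC5"))
  expect_equal(cr$cc_12, 1 / 3, tolerance = 1e-6)
})

test_that("resistance fits recover exact and simulated slopes", {
  I <- c(-2, -4, -6, -8)
  f <- fit_resistances(I, 3.75 * I, 1.25 * I)
  expect_equal(f$Rin, 3.75, tolerance = 1e-12)
  expect_equal(f$R12, 1.25, tolerance = 1e-12)
  expect_equal(f$se_Rin, 0, tolerance = 1e-10)
  expect_false(f$single_step)
  # single amplitude falls back to the ratio with a flag
  f1 <- fit_resistances(c(-4, -4), c(-15, -15), c(-5, -5))
  expect_true(f1$single_step)
  expect_equal(f1$Rin, 3.75)
  # positive slope from a hyperpolarizing family is flagged
  expect_true(fit_resistances(I, -2 * I, 1.25 * I)$sign_inconsistent)
  # noiseless protocol: Rin, R12 within 0.1 %
  an <- analytic_passive_pair(passive_pair_spec(5, 5, 10))
  cr <- coupling_from_protocol(
    simulate_passive_pair(passive_pair_spec(5, 5, 10), seed = 1),
    c("LC4", "LC5"))
  expect_equal(cr$Rin_1, an$Rin1, tolerance = 1e-3)
  expect_equal(cr$R12_from1, an$R12, tolerance = 1e-3)
})

test_that("noisy resistance estimates are unbiased across seeds", {
  spec <- passive_pair_spec(5, 5, 10, noise_sd = 0.1)
  an <- analytic_passive_pair(spec)
  ests <- vapply(1:40, function(s) {
    cr <- coupling_from_protocol(simulate_passive_pair(spec, seed = s),
                                 c("LC4", "LC5"))
    cr$Rin_1
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - an$Rin1), 3 * se + 1e-4)
})

test_that("Bennett conversion implements the two-compartment formula", {
  b <- bennett_conductance(3.75, 3.75, 1.25)
  expect_equal(b$Rc, 10)
  expect_equal(b$Gc, 0.1)
  expect_error(bennett_conductance(5, 5, 5), "non-physical")
  expect_error(bennett_conductance(5, 5, 0), "transfer")
  expect_error(bennett_conductance(5, 5, -1), "transfer")
  # uncoupled limit: R12 -> 0+ gives Rc -> Inf, Gc -> 0
  b0 <- bennett_conductance(5, 5, 1e-9)
  expect_gt(b0$Rc, 1e9)
  expect_lt(b0$Gc, 1e-9)
})

test_that("end-to-end protocol recovers Gc and is direction-symmetric", {
  for (Rm in c(2, 5, 10)) {
    for (Rc in c(2, 10, 50)) {
      rec <- simulate_passive_pair(passive_pair_spec(Rm, Rm, Rc), seed = 1)
      cr <- coupling_from_protocol(rec, c("LC4", "LC5"))
      expect_equal(cr$Gc_pooled, 1 / Rc, tolerance = 1e-3)
      expect_lt(abs(cr$Gc_dir12 - cr$Gc_dir21) /
                  mean(c(cr$Gc_dir12, cr$Gc_dir21)), 1e-6)
    }
  }
  # halving Rc doubles Gc and raises cc from 1/3 to 1/2
  cr10 <- coupling_from_protocol(
    simulate_passive_pair(passive_pair_spec(5, 5, 10), seed = 1),
    c("LC4", "LC5"))
  cr5 <- coupling_from_protocol(
    simulate_passive_pair(passive_pair_spec(5, 5, 5), seed = 1),
    c("LC4", "LC5"))
  expect_equal(cr5$Gc_pooled / cr10$Gc_pooled, 2, tolerance = 1e-6)
  expect_equal(cr5$cc_12, 0.5, tolerance = 1e-6)
  # uncoupled fixture exercises the no-transfer error path
  rec_inf <- simulate_passive_pair(passive_pair_spec(5, 5, Inf), seed = 1)
  expect_error(coupling_from_protocol(rec_inf, c("LC4", "LC5")),
               "transfer|non-physical")
})

test_that("estimated cc increases strictly as Rc_true decreases", {
  ccs <- vapply(c(50, 20, 10, 5, 2), function(Rc) {
    coupling_from_protocol(
      simulate_passive_pair(passive_pair_spec(5, 5, Rc), seed = 2),
      c("LC4", "LC5"))$cc_12
  }, numeric(1))
  expect_true(all(diff(ccs) > 0))
})

test_that("cc and Gc are invariant to the injected-current sign convention", {
  spec <- passive_pair_spec(5, 5, 10)
  rec <- simulate_passive_pair(spec, seed = 1)
  # flip the recorded deflections as a depolarizing protocol would give
  steps <- coupling_from_protocol(rec, c("LC4", "LC5"))$steps
  f_hyp <- fit_resistances(steps$I[steps$injected_cell == "LC4"],
                           steps$dV_injected[steps$injected_cell == "LC4"],
                           steps$dV_coupled[steps$injected_cell == "LC4"])
  f_dep <- fit_resistances(-steps$I[steps$injected_cell == "LC4"],
                           -steps$dV_injected[steps$injected_cell == "LC4"],
                           -steps$dV_coupled[steps$injected_cell == "LC4"])
  expect_equal(f_hyp$Rin, f_dep$Rin, tolerance = 1e-12)
  expect_equal(f_hyp$R12, f_dep$R12, tolerance = 1e-12)
})

test_that("noisy protocols keep the Gc error small over the grid", {
  errs <- c()
  for (Rm in c(2, 10)) {
    for (Rc in c(2, 50)) {
      for (s in 1:5) {
        spec <- passive_pair_spec(Rm, Rm, Rc, noise_sd = 0.1)
        cr <- coupling_from_protocol(simulate_passive_pair(spec, seed = s),
                                     c("LC4", "LC5"))
        errs <- c(errs, abs(cr$Gc_pooled - 1 / Rc) * Rc)
      }
    }
  }
  expect_lt(median(errs), 0.05)
})
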