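test_that("burst_r2 equals brute-force Pearson squared", {
  # identity and affine invariance
  set.seed(1)
  a <- cg_trace("a", 0, 1e-3, -50 + 10 * sin(seq(0, 20, length.out = 2000)) +
                  rnorm(2000, 0, 0.5))
  b_same <- cg_trace("b", 0, 1e-3, a$samples)
  expect_equal(burst_r2(a, b_same, 0.1, 1.9)$r2, 1.0)
  b_aff <- cg_trace("b", 0, 1e-3, 0.8 * a$samples + 3)
  pt <- burst_r2(a, b_aff, 0.1, 1.9)
  expect_equal(pt$r2, 1.0)
  expect_equal(pt$r, 1.0)
  expect_false(pt$negative_r)
  # hand-checked 4-point case (resampled grid reproduces the samples):
  # A = 0,1,2,3; B = 0,1,1,3 -> sums of squares 5 and 4.75, cross 4.5,
  # so r = 4.5/sqrt(5 * 4.75) = 0.92338, r2 = 0.85263
  a4 <- cg_trace("a", 0, 0.1, c(0, 1, 2, 3, 3, 3, 3, 3, 3, 3, 3, 3))
  b4 <- cg_trace("b", 0, 0.1, c(0, 1, 1, 3, 3, 3, 3, 3, 3, 3, 3, 3))
  g <- common_grid(a4, b4, 0, 0.3)
  r_bf <- pearson_bf(g$va, g$vb)
  expect_equal(r_bf, 4.5 / sqrt(5 * 4.75), tolerance = 1e-12)
  expect_equal(r_bf, 0.9234, tolerance = 1e-4)
  expect_equal(r_bf^2, 0.8527, tolerance = 1e-4)
  # degenerate segment errors
  flat <- cg_trace("f", 0, 1e-3, rep(-60, 2000))
  expect_error(burst_r2(a, flat, 0.1, 1.9), "degenerate")
  expect_error(burst_r2(a, b_same, 0.1, 0.104), "10 samples")
})

test_that("burst_r2 matches an independent Pearson on random segment pairs", {
  set.seed(7)
  for (k in 1:300) {
    n <- sample(10:120, 1)
    dt_a <- sample(c(1e-3, 2e-3), 1)
    dt_b <- sample(c(1e-3, 2.5e-3), 1)
    xa <- cumsum(rnorm(500))
    xb <- cumsum(rnorm(500))
    a <- cg_trace("a", 0, dt_a, xa)
    b <- cg_trace("b", 0, dt_b, xb)
    hi <- min(trace_end(a), trace_end(b))
    pt <- burst_r2(a, b, 0, hi)
    g <- common_grid(a, b, 0, hi)
    expect_equal(pt$r, pearson_bf(g$va, g$vb), tolerance = 1e-12)
    expect_equal(pt$r2, pt$r^2, tolerance = 1e-15)
  }
})

test_that("r2 is invariant to positive affine rescaling of either trace", {
  set.seed(3)
  x <- -50 + cumsum(rnorm(1000, 0, 0.3))
  y <- x + rnorm(1000, 0, 1)
  a <- cg_trace("a", 0, 1e-3, x)
  b <- cg_trace("b", 0, 1e-3, y)
  base <- burst_r2(a, b, 0, 0.99)$r2
  for (gain in c(0.2, 3)) {
    b2 <- cg_trace("b", 0, 1e-3, gain * y - 7)
    expect_equal(burst_r2(a, b2, 0, 0.99)$r2, base, tolerance = 1e-12)
  }
})

test_that("sync_timecourse emits one point per LC-burst slot in time order", {
  rec <- cached_control_rec()
  an <- analyze_quiet(rec)
  expect_equal(nrow(an$sync), sum(an$cycles$n_lc_bursts))
  expect_false(is.unsorted(an$sync$t))
  expect_error(sync_timecourse(rec, an$cycles, c("LC1", "nope")), "nope")
  # double-bursting run: slots 1, 2 alternate within cycles
  spec <- apply_modulator(network_spec(seed = 4), "5HT", seed = 4)
  rec2 <- simulate_cg_network(spec, duration = 15, seed = 4)
  an2 <- analyze_quiet(rec2)
  expect_true(all(tapply(an2$sync$slot, an2$sync$cycle,
                         function(x) identical(sort(x), c(1L, 2L)))))
})

test_that("epoch averaging selects the stated windows", {
  s <- structure(data.frame(cycle = 1:30, slot = 1, t = (1:30) * 2.5,
                            r = sqrt(0.9), r2 = 0.9, n_samples = 100,
                            negative_r = FALSE, skipped = FALSE),
                 class = c("cg_sync", "data.frame"))
  ep <- epoch_mean_r2(s, "ending_at", t = 80, n = 10)
  expect_equal(ep$mean_r2, 0.9)
  expect_equal(ep$sd_r2, 0)
  expect_equal(ep$n_bursts, 10)
  # a dip: at_minimum finds the window with the lowest mean, equal to an
  # exhaustive scan
  s2 <- s
  s2$r2 <- 0.95
  s2$r2[15:22] <- 0.7
  got <- epoch_mean_r2(s2, "at_minimum", t = 10, n = 10)
  idx <- which(s2$t > 10)
  means <- vapply(seq_len(length(idx) - 9), function(i) {
    mean(s2$r2[idx[i]:(idx[i] + 9)])
  }, numeric(1))
  expect_equal(got$mean_r2, min(means), tolerance = 1e-12)
  expect_error(epoch_mean_r2(s, "ending_at", t = 10, n = 10), "have")
})

test_that("acute minimum localisation follows the smoothed argmin", {
  mk <- function(r2) {
    structure(data.frame(cycle = seq_along(r2), slot = 1,
                         t = seq_along(r2) * 2.5, r = sqrt(r2), r2 = r2,
                         n_samples = 100, negative_r = FALSE,
                         skipped = FALSE),
              class = c("cg_sync", "data.frame"))
  }
  # trough at index 25 of 50; the 10-burst smoother may settle one burst
  # to either side of the exact trough
  r2 <- 0.95 - 0.2 * exp(-((1:50) - 25)^2 / 20)
  expect_lt(abs(find_acute_minimum(mk(r2), perfusion_t = 10) - 25 * 2.5), 3)
  # flat series: earliest post-perfusion time wins the tie
  flat <- mk(rep(0.9, 30))
  expect_equal(find_acute_minimum(flat, perfusion_t = 24),
               min(flat$t[flat$t > 24]))
  # programmed desynchronisation onset: exponential decline after 300 s
  # with time constant 120 s, then recovery; cycle period 2.5 s
  tt <- (1:300) * 2.5
  prog <- 0.95 - 0.15 * pmax(0, 1 - exp(-(tt - 300) / 120)) *
    exp(-pmax(0, tt - 550) / 200)
  tmin <- find_acute_minimum(mk(prog), perfusion_t = 300)
  expect_gt(tmin, 450)
  expect_lt(tmin, 650)
  expect_error(find_acute_minimum(mk(rep(0.9, 5)), perfusion_t = 100), "have")
})
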