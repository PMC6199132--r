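#' Specify a synthetic cardiac-ganglion network
#'
#' A generative description of a small motor-neuron (LC) network driven by a
#' pacemaker (SC) burst envelope and coupled by ohmic gap junctions. Each LC
#' is a minimal burster: a leak conductance, a fast exponential spiking
#' mechanism with threshold reset, a slow K-like adaptation current that
#' shapes the intraburst spike pattern, and the excitatory drive
#' conductance. Per-cell parameters (adaptation strength and kinetics,
#' drive conductance) are drawn cell-wise from mean-preserving log-normal
#' distributions with coefficient of variation `cv_g`, emulating the
#' documented cell-to-cell variability of membrane currents in these
#' neurons.
#'
#' The extracellular channel is synthesised from ground-truth spike times by
#' summing stereotyped biphasic kernels: small for SC spikes, large for LC
#' spikes, so amplitude-based unit classification has an exact answer key.
#'
#' @param n_lc Number of LC motor neurons (the analyses use the first two).
#' @param cv_g CV of the per-cell log-normal parameter draws
#'   (0 = identical cells).
#' @param gc Gap-junction conductance, uS: either a scalar (uniform
#'   all-to-all) or a symmetric zero-diagonal matrix.
#' @param period Pacemaker cycle period, s.
#' @param sc_burst_len Pacemaker burst length (single-burst mode), s.
#' @param lc_delay Delay from cycle start to LC drive onset, s.
#' @param lc_drive_len LC drive envelope length (single mode), s.
#' @param double_lobe_len,double_gap,double_floor Double-envelope drive:
#'   length of each lobe (s), gap between lobes (s), and the relative drive
#'   floor maintained between the lobes (keeps the membrane depolarised so
#'   it does not return to rest between the two bursts).
#' @param gd Drive conductance at envelope peak, uS.
#' @param sc_isi Interval between SC spikes within a pacemaker burst, s.
#' @param sc_amp,lc_amp Extracellular kernel amplitudes (a.u.); SC < LC.
#' @param noise_extra SD of extracellular white noise, a.u.
#' @param noise_mV SD of intracellular measurement noise, mV.
#' @param noise_nA,noise_tau Slow per-cell background current noise
#'   (Ornstein-Uhlenbeck): stationary SD in nA and correlation time in s.
#'   This is what makes burst waveforms fluctuate from cycle to cycle, as
#'   they do in real preparations; it is independent across cells, so it
#'   also bounds the attainable synchrony when coupling is weak.
#' @param seed Integer seed used for the conductance draws.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_lc = 2, cv_g = 0.3, gc = 1.25,
                         period = 2.5, sc_burst_len = 0.45,
                         lc_delay = 0.15, lc_drive_len = 0.6,
                         double_lobe_len = 0.45, double_gap = 0.7,
                         double_floor = 0.5,
                         gd = 0.08, sc_isi = 0.025,
                         sc_amp = 0.2, lc_amp = 1.0,
                         noise_extra = 0.01, noise_mV = 0.3,
                         noise_nA = 0.15, noise_tau = 0.1,
                         seed = 1L) {
  stopifnot(n_lc >= 1, cv_g >= 0, period > 0, sc_burst_len > 0)
  if (period <= max(sc_burst_len, lc_delay + lc_drive_len)) {
    stop("period must exceed the burst/drive length")
  }
  if (is.matrix(gc)) {
    if (nrow(gc) != n_lc || ncol(gc) != n_lc) stop("gc matrix must be n_lc x n_lc")
    if (any(gc < 0)) stop("gc must be non-negative")
    if (any(abs(gc - t(gc)) > 1e-12)) stop("gc matrix must be symmetric")
    if (any(diag(gc) != 0)) stop("gc diagonal must be zero")
  } else {
    stopifnot(length(gc) == 1L, gc >= 0)
    gc <- matrix(gc, n_lc, n_lc) - diag(gc, n_lc)
  }
  if (!(sc_amp < lc_amp)) stop("SC kernel amplitude must be below LC amplitude")
  spec <- list(n_lc = n_lc, cv_g = cv_g, gc = gc, period = period,
               sc_burst_len = sc_burst_len, lc_delay = lc_delay,
               lc_drive_len = lc_drive_len,
               double_lobe_len = double_lobe_len, double_gap = double_gap,
               double_floor = double_floor, gd = gd, sc_isi = sc_isi,
               sc_amp = sc_amp, lc_amp = lc_amp,
               noise_extra = noise_extra, noise_mV = noise_mV,
               noise_nA = noise_nA, noise_tau = noise_tau,
               seed = as.integer(seed),
               # modulator state (identity until apply_modulator)
               mod = list(name = "control",
                          fb = rep(1, n_lc), fd = rep(1, n_lc),
                          fw = rep(1, n_lc), fgc = 1,
                          drive_double = FALSE))
  class(spec) <- "network_spec"
  spec
}

# Baseline biophysics (adaptive exponential integrate-and-fire; mV, ms,
# uS, nF, nA). gL gives a resting input resistance of 4 MOhm and a 4 ms
# membrane time constant, in the range of LC somatic recordings; tauw/b set
# the K-like spike-frequency adaptation that shapes the intraburst pattern.
# Vpeak sits only 15 mV above threshold: LC somata record strongly
# attenuated spikes riding the slow burst depolarisation, not full axonal
# action potentials.
adex_constants <- function() {
  list(C = 1, EL = -60, VT = -50, DeltaT = 2, Vr = -52, Vpeak = -35,
       tauw = 200, Ed = 0)
}

adex_base_pars <- function() c(gL = 0.25, a = 0.01, b = 1.0)

# Mean-one log-normal multipliers.
lognormal_factors <- function(n, mean = 1, cv = 0) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Phenomenological neuromodulator transforms
#'
#' Returns a new spec with the modulator's multiplicative conductance scale
#' factors filled in; the generators apply them (optionally ramped in time).
#' The mapping from modulator to parameters is a modelling choice that
#' reproduces the qualitative physiology:
#'
#' * `5HT`: heterogeneous per-cell scaling, drawn log-normally with CV
#'   `cv_mod` and clipped to physiological ranges: the K-like adaptation
#'   strength is reduced (mean x 0.6), the drive efficacy enhanced (mean
#'   x 1.3) and the adaptation kinetics retimed (mean x 1), each by a
#'   different amount in each cell; gap junctions are unchanged and the
#'   pacemaker drive switches to the prolonged double-envelope mode.
#' * `DA`: global gap-junction scale `gc_scale` (default 2.5) plus a mild
#'   uniform excitability increase (drive x 1.2, K-like adaptation x 0.85).
#' * `TEA`: strong block of the K-like adaptation current (mean x 0.35),
#'   mildly heterogeneous across exposed cells, with slowed kinetics.
#' * `DA+5HT`, `DA+TEA`: multiplicative composition of the components (the
#'   composition commutes).
#'
#' Scale-factor draws are seeded from `seed` and the effect name, so
#' composing effects in either order yields identical factors.
#'
#' @param spec A [network_spec()].
#' @param effect One of `"5HT"`, `"DA"`, `"TEA"`, `"DA+5HT"`, `"DA+TEA"`.
#' @param seed Integer seed for the heterogeneous per-cell draws.
#' @param cv_mod CV of the per-cell modulator response (5HT only).
#' @param gc_scale Gap-junction multiplier applied by DA.
#' @return A new `network_spec` with modulator state set.
#' @export
apply_modulator <- function(spec, effect, seed = spec$seed, cv_mod = 0.3,
                            gc_scale = 2.5) {
  stopifnot(inherits(spec, "network_spec"))
  parts <- strsplit(effect, "+", fixed = TRUE)[[1L]]
  known <- c("5HT", "DA", "TEA")
  if (!length(parts) || !all(parts %in% known)) {
    stop("unknown modulator effect: ", effect)
  }
  n <- spec$n_lc
  mod <- spec$mod
  mod$name <- if (mod$name == "control") effect else paste(mod$name, effect, sep = "+")
  for (p in sort(parts)) {  # sorted: composition order-independent
    clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    if (p == "5HT") {
      set.seed(as.integer(seed) + sum(utf8ToInt(p)))
      # heterogeneous per-cell response: K-like adaptation reduced and
      # drive efficacy enhanced by different amounts in each cell, so the
      # cells' intraburst spike patterns diverge
      mod$fb <- mod$fb * clip(lognormal_factors(n, 0.6, cv_mod), 0.3, 1.1)
      mod$fd <- mod$fd * clip(lognormal_factors(n, 1.3, cv_mod), 1.0, 1.8)
      mod$fw <- mod$fw * clip(lognormal_factors(n, 1, cv_mod), 0.6, 1.6)
      mod$drive_double <- TRUE
    } else if (p == "DA") {
      mod$fgc <- mod$fgc * gc_scale
      mod$fd <- mod$fd * 1.2
      mod$fb <- mod$fb * 0.85
    } else if (p == "TEA") {
      set.seed(as.integer(seed) + sum(utf8ToInt(p)))
      # strong block of the K-like adaptation current, heterogeneous across
      # cells: the blockable (TEA-sensitive) fraction of the K current
      # differs from cell to cell, as does the kinetic slowing
      mod$fb <- mod$fb * clip(lognormal_factors(n, 0.3, cv_mod * 2), 0.08, 0.9)
      mod$fw <- mod$fw * clip(lognormal_factors(n, 1.4, cv_mod * 2), 0.6, 2.8)
      mod$fd <- mod$fd * clip(lognormal_factors(n, 1.2, cv_mod), 0.9, 1.7)
    }
  }
  spec$mod <- mod
  spec
}

# Drive envelope value pattern for one cycle, sampled at dt (s), plus the SC
# spike offsets and ground-truth timing for that cycle.
cycle_pattern <- function(spec, double, dt) {
  ramp_s <- 0.01  # 10 ms linear on/off ramps
  n <- round(spec$period / dt)
  tt <- (seq_len(n) - 1) * dt
  lobe <- function(t_on, t_off) {
    pmax(0, pmin(1, pmin((tt - t_on) / ramp_s, (t_off - tt) / ramp_s)))
  }
  if (!double) {
    env <- lobe(spec$lc_delay, spec$lc_delay + spec$lc_drive_len)
    sc_end <- spec$sc_burst_len
  } else {
    l1_on <- spec$lc_delay
    l1_off <- l1_on + spec$double_lobe_len
    l2_on <- l1_off + spec$double_gap
    l2_off <- l2_on + spec$double_lobe_len
    if (l2_off >= spec$period) stop("double envelope does not fit in the period")
    env <- pmax(pmax(lobe(l1_on, l1_off), lobe(l2_on, l2_off)),
                spec$double_floor * lobe(l1_on, l2_off))
    sc_end <- l2_on  # prolonged pacemaker burst drives up to the second lobe
  }
  sc_offsets <- seq(0, sc_end, by = spec$sc_isi)
  list(env = env, sc_offsets = sc_offsets, sc_end = max(sc_offsets),
       double = double)
}

#' Simulate the synthetic cardiac-ganglion network
#'
#' Integrates the coupled burster network with the pacemaker drive envelope
#' and synthesises the extracellular channel. If the spec carries a
#' modulator state (from [apply_modulator()]) the conductance scale factors
#' are ramped in from `perfusion_t` with time constant `ramp_tau`
#' (exponential approach), emulating bath perfusion; with
#' `perfusion_t = NULL` modulated specs are simulated fully transformed from
#' time zero. The drive switches to the double-envelope mode (when the
#' modulator calls for it) for cycles starting after `perfusion_t`.
#'
#' Deterministic given the spec and `seed`.
#'
#' @param spec A [network_spec()] (possibly modulated).
#' @param duration Total simulated time, s; at least 3 pacemaker periods.
#' @param dt Integration step, s (<= 5e-5 for the spiking model).
#' @param dt_out Output sampling interval, s.
#' @param perfusion_t Time perfusion of the modulator begins, s (or `NULL`).
#' @param ramp_tau Time constant of the modulator ramp, s.
#' @param seed Integer seed for the noise channels.
#' @return A [recording()] with one intracellular trace per LC (`LC1`,
#'   `LC2`, ...) and the synthetic extracellular trace `extra`. The
#'   ground truth (true spike times per cell, SC spike times, cycle onsets
#'   and modes, drawn conductances, gc matrix) is in
#'   `metadata$ground_truth`.
#' @export
simulate_cg_network <- function(spec, duration = 30, dt = 5e-5,
                                dt_out = 5e-4, perfusion_t = NULL,
                                ramp_tau = 20, seed = spec$seed) {
  stopifnot(inherits(spec, "network_spec"))
  if (duration < 3 * spec$period) stop("duration must cover >= 3 pacemaker periods")
  if (dt > 5e-5 + 1e-12) stop("dt too large for the spiking model (need <= 5e-5 s)")
  keep <- round(dt_out / dt)
  stopifnot(abs(keep * dt - dt_out) < 1e-12)

  # per-cell parameters: heterogeneous log-normal draws for the K-like
  # adaptation (a, b) and the drive conductance; leak fixed (the apparent
  # input resistance of LC somata varies much less than their K currents)
  set.seed(spec$seed)
  base <- adex_base_pars()
  f_b <- lognormal_factors(spec$n_lc, cv = spec$cv_g)
  f_a <- lognormal_factors(spec$n_lc, cv = spec$cv_g)
  f_d <- lognormal_factors(spec$n_lc, cv = spec$cv_g / 3)
  cellpar <- cbind(gL = rep(base[["gL"]], spec$n_lc),
                   a = base[["a"]] * f_a,
                   b = base[["b"]] * f_b,
                   gd = spec$gd * f_d)

  nt <- round(duration / dt) + 1L
  tt_full <- (seq_len(nt) - 1L) * dt

  # modulator ramp
  modded <- spec$mod$name != "control"
  if (!modded) {
    ramp <- numeric(nt)
    t_on <- Inf
  } else if (is.null(perfusion_t)) {
    ramp <- rep(1, nt)
    t_on <- -Inf
  } else {
    t_on <- perfusion_t
    ramp <- ifelse(tt_full < t_on, 0, 1 - exp(-(tt_full - t_on) / ramp_tau))
  }

  # drive envelope, cycle table, SC ground truth
  onsets <- seq(spec$period / 2, duration - spec$period, by = spec$period)
  env <- numeric(nt)
  sc_times <- numeric(0)
  cyc <- list()
  for (tc in onsets) {
    dbl <- modded && spec$mod$drive_double && tc >= t_on
    pat <- cycle_pattern(spec, dbl, dt)
    i0 <- round(tc / dt) + 1L
    idx <- i0:min(nt, i0 + length(pat$env) - 1L)
    env[idx] <- pat$env[seq_along(idx)]
    sc_times <- c(sc_times, tc + pat$sc_offsets)
    cyc[[length(cyc) + 1L]] <- data.frame(t_onset = tc, double = dbl,
                                          sc_off = tc + pat$sc_end)
  }
  cycles <- do.call(rbind, cyc)

  # slow background current noise, sampled at the output rate and held
  # between output samples (correlation time >> dt_out)
  n_keep <- (nt - 1L) %/% keep + 1L
  set.seed(as.integer(seed) + 2L)
  inoise <- matrix(0, n_keep, spec$n_lc)
  if (spec$noise_nA > 0) {
    a <- exp(-dt_out / spec$noise_tau)
    innov_sd <- spec$noise_nA * sqrt(1 - a^2)
    for (i in seq_len(spec$n_lc)) {
      z <- stats::rnorm(n_keep, 0, innov_sd)
      z[1L] <- stats::rnorm(1, 0, spec$noise_nA)
      inoise[, i] <- stats::filter(z, a, method = "recursive")
    }
  }

  modfac <- cbind(spec$mod$fb, spec$mod$fd, spec$mod$fw)
  out <- simulate_network_cpp(cellpar, spec$gc, env, ramp, modfac,
                              spec$mod$fgc, adex_constants(), inoise,
                              dt * 1000, keep)
  V <- out$V
  spikes <- lapply(out$spikes_ms, function(s) s / 1000)  # s
  n_out <- nrow(V)
  # The sub-millisecond spike upswing falls between output samples;
  # superimpose the stereotyped somatic spikelet (attenuated spike as seen
  # at the LC soma) at the ground-truth spike times so the sampled trace
  # carries the spikes.
  for (i in seq_len(spec$n_lc)) {
    V[, i] <- add_spikelets(V[, i], dt_out, spikes[[i]])
  }
  set.seed(as.integer(seed) + 1L)
  if (spec$noise_mV > 0) {
    V <- V + matrix(stats::rnorm(length(V), 0, spec$noise_mV), n_out)
  }

  # synthetic extracellular trace: kernels at ground-truth spike times
  extra <- stats::rnorm(n_out, 0, spec$noise_extra)
  extra <- add_kernels(extra, dt_out, sc_times, spec$sc_amp)
  for (s in spikes) extra <- add_kernels(extra, dt_out, s, spec$lc_amp)

  traces <- c(
    lapply(seq_len(spec$n_lc), function(i) {
      cg_trace(paste0("LC", i), 0, dt_out, V[, i], "intracellular")
    }),
    list(cg_trace("extra", 0, dt_out, extra, "extracellular")))
  names(traces) <- vapply(traces, function(x) x$cell_id, character(1))
  names(spikes) <- paste0("LC", seq_len(spec$n_lc))

  timeline <- data.frame(time = 0, condition = "control",
                         stringsAsFactors = FALSE)
  if (modded && is.finite(t_on) && t_on > 0) {
    timeline <- rbind(timeline,
                      data.frame(time = t_on, condition = spec$mod$name))
  } else if (modded) {
    timeline$condition <- spec$mod$name
  }
  recording(traces, condition_timeline = timeline,
            metadata = list(
              generator = "simulate_cg_network", seed = as.integer(seed),
              E_rest = adex_constants()$EL,
              ground_truth = list(lc_spikes = spikes, sc_spikes = sc_times,
                                  cycles = cycles, gc = spec$gc,
                                  cellpar = cellpar, mod = spec$mod,
                                  perfusion_t = if (is.finite(t_on)) t_on)))
}

# Somatic spikelet: 22 mV asymmetric bump (1 ms rise, 3 ms fall) added at
# each spike time.
add_spikelets <- function(x, dt, times, amp = 22) {
  if (!length(times)) return(x)
  rise <- 0.001; fall <- 0.003
  kt <- seq(-rise, fall, by = dt)
  kern <- amp * ifelse(kt < 0, cos(pi * kt / (2 * rise))^2,
                       cos(pi * kt / (2 * fall))^2)
  i0 <- round(times / dt) + 1L
  off <- seq_along(kt) - which.max(kern)
  for (i in i0) {
    idx <- i + off
    ok <- idx >= 1L & idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + kern[ok]
  }
  x
}

# Add a biphasic spike kernel (positive lobe then half-amplitude negative
# lobe, ~3 ms total) centred at each event time.
add_kernels <- function(x, dt, times, amp) {
  if (!length(times)) return(x)
  half <- 0.0015
  kt <- seq(-half, half, by = dt)
  kern <- amp * ifelse(kt < 0, cos(pi * kt / (2 * half))^2,
                       cos(pi * kt / (2 * half))^2 -
                         0.5 * sin(pi * kt / half)^2)
  # peak of kern is at kt = 0
  i0 <- round(times / dt) + 1L
  off <- seq_along(kt) - which.max(kern)
  for (i in i0) {
    idx <- i + off
    ok <- idx >= 1L & idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + kern[ok]
  }
  x
}
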