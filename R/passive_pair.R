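#' Specify a passive two-compartment cell pair
#'
#' The circuit the Bennett two-compartment estimator assumes: two passive
#' membranes (resistance `Rm`, capacitance `Cm`, common rest potential)
#' joined by an ohmic junctional resistance `Rc`. Units follow the package
#' convention: MOhm, nF, mV; with currents in nA, MOhm * nA = mV directly.
#'
#' @param Rm1,Rm2 Membrane resistances, MOhm (> 0).
#' @param Rc Junctional (coupling) resistance, MOhm; `Inf` means uncoupled.
#' @param Cm1,Cm2 Membrane capacitances, nF (> 0). The membrane time
#'   constant of cell i is `Rm_i * Cm_i` milliseconds.
#' @param E_rest Resting potential, mV.
#' @param noise_sd SD of additive white measurement noise, mV.
#' @return An object of class `passive_pair_spec`.
#' @export
passive_pair_spec <- function(Rm1 = 5, Rm2 = 5, Rc = 10,
                              Cm1 = 1, Cm2 = 1,
                              E_rest = -60, noise_sd = 0) {
  if (Rm1 <= 0 || Rm2 <= 0) stop("membrane resistances must be positive")
  if (!(Rc > 0)) stop("Rc must be positive (use Inf for uncoupled)")
  if (Cm1 <= 0 || Cm2 <= 0) stop("capacitances must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(Rm1 = Rm1, Rm2 = Rm2, Rc = Rc, Cm1 = Cm1, Cm2 = Cm2,
                 E_rest = E_rest, noise_sd = noise_sd),
            class = "passive_pair_spec")
}

#' Closed-form steady state of the passive pair
#'
#' Solves the two-node resistive star exactly. With current injected into
#' cell 1:
#' `Rin1 = Rm1 (Rc + Rm2) / (Rm1 + Rc + Rm2)`,
#' `R12 = Rm1 Rm2 / (Rm1 + Rc + Rm2)`, and the coupling coefficient
#' `cc12 = Rm2 / (Rc + Rm2)`; symmetrically for direction 2 -> 1. The
#' uncoupled limit `Rc = Inf` gives `R12 = 0`, `cc = 0`, `Rin = Rm`.
#'
#' @param spec A [passive_pair_spec()].
#' @return List with `Rin1`, `Rin2`, `R12`, `cc12`, `cc21` (all MOhm or
#'   dimensionless). `R12` is the same in both directions (reciprocity).
#' @export
analytic_passive_pair <- function(spec) {
  stopifnot(inherits(spec, "passive_pair_spec"))
  with(spec, {
    if (is.infinite(Rc)) {
      list(Rin1 = Rm1, Rin2 = Rm2, R12 = 0, cc12 = 0, cc21 = 0)
    } else {
      S <- Rm1 + Rc + Rm2
      list(Rin1 = Rm1 * (Rc + Rm2) / S,
           Rin2 = Rm2 * (Rc + Rm1) / S,
           R12 = Rm1 * Rm2 / S,
           cc12 = Rm2 / (Rc + Rm2),
           cc21 = Rm1 / (Rc + Rm1))
    }
  })
}

#' Specify a hyperpolarizing current-step protocol
#'
#' Steps are injected alternately into the two cells: for each amplitude,
#' first cell 1, then cell 2.
#'
#' @param amplitudes Step amplitudes in nA, all negative (hyperpolarizing).
#' @param step_duration Step length, seconds.
#' @param inter_step Interval between steps, seconds (also provides the
#'   baseline window).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(amplitudes = c(-2, -4, -6, -8),
                          step_duration = 0.25, inter_step = 0.25) {
  amplitudes <- as.numeric(amplitudes)
  if (!length(amplitudes)) stop("protocol needs at least one amplitude")
  if (any(amplitudes >= 0)) stop("step amplitudes must be hyperpolarizing (< 0)")
  if (step_duration <= 0 || inter_step <= 0) stop("durations must be positive")
  structure(list(amplitudes = amplitudes, step_duration = step_duration,
                 inter_step = inter_step),
            class = "step_protocol")
}

# Epoch table for a protocol run on a pair of cells.
protocol_epochs <- function(protocol, cells = c("LC4", "LC5")) {
  sd <- protocol$step_duration
  gap <- protocol$inter_step
  rows <- list()
  t <- gap
  for (amp in protocol$amplitudes) {
    for (cell in cells) {
      rows[[length(rows) + 1L]] <-
        protocol_epoch(cell, amp, t, t + sd, baseline_window = 0.3 * gap)
      t <- t + sd + gap
    }
  }
  do.call(rbind, rows)
}

#' Simulate the passive pair under a step protocol
#'
#' Integrates the linear two-compartment ODE
#' `Cm_i dV_i/dt = (E - V_i)/Rm_i + (V_j - V_i)/Rc + I_i(t)`
#' exactly: within each constant-input segment the solution is evaluated in
#' closed form from the eigendecomposition of the system matrix, so the only
#' error at the sampled points is measurement noise. With `noise_sd = 0` the
#' deflection at the end of a step of duration `>= 10 tau` matches
#' [analytic_passive_pair()] essentially to machine precision.
#'
#' @param spec A [passive_pair_spec()].
#' @param protocol A [step_protocol()].
#' @param dt Sampling interval, seconds. Must satisfy `dt <= tau/20` where
#'   `tau` is the smaller membrane time constant.
#' @param seed Integer seed for the measurement noise.
#' @param cells Channel names for the two cells.
#' @return A [recording()] with two intracellular traces, two current
#'   traces (`I_<cell>`), and the populated epoch table.
#' @export
simulate_passive_pair <- function(spec, protocol = step_protocol(),
                                  dt = 1e-4, seed = 1L,
                                  cells = c("LC4", "LC5")) {
  stopifnot(inherits(spec, "passive_pair_spec"),
            inherits(protocol, "step_protocol"))
  tau <- with(spec, min(Rm1 * Cm1, Rm2 * Cm2)) / 1000  # s (MOhm*nF = ms)
  if (dt > tau / 20) {
    stop(sprintf("dt = %g s too large for membrane time constant %g s (need dt <= tau/20)",
                 dt, tau))
  }
  epochs <- protocol_epochs(protocol, cells)
  if (nrow(epochs) > 1L &&
      any(epochs$t_start[-1L] < epochs$t_end[-nrow(epochs)])) {
    stop("overlapping epochs")
  }
  t_total <- max(epochs$t_end) + protocol$inter_step
  n <- floor(t_total / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt

  gc <- if (is.infinite(spec$Rc)) 0 else 1 / spec$Rc
  g1 <- 1 / spec$Rm1; g2 <- 1 / spec$Rm2
  # time in ms so that uS / nF -> 1/ms
  A <- matrix(c(-(g1 + gc) / spec$Cm1, gc / spec$Cm1,
                gc / spec$Cm2, -(g2 + gc) / spec$Cm2),
              2, 2, byrow = TRUE)
  eg <- eigen(A)
  P <- eg$vectors; Pinv <- solve(P); lam <- eg$values  # 1/ms

  # piecewise-constant input: build segment boundaries
  bounds <- sort(unique(c(0, epochs$t_start, epochs$t_end, t_total)))
  seg_of <- findInterval(tt, bounds, rightmost.closed = TRUE)
  I1 <- numeric(n); I2 <- numeric(n)  # recorded command currents
  V <- matrix(NA_real_, n, 2)
  v0 <- c(spec$E_rest, spec$E_rest)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    inj <- c(0, 0)
    hit <- which(epochs$t_start <= lo + 1e-12 & epochs$t_end >= hi - 1e-12)
    if (length(hit)) {
      inj[match(epochs$injected_cell[hit[1L]], cells)] <- epochs$amplitude[hit[1L]]
    }
    b <- c((g1 * spec$E_rest + inj[1L]) / spec$Cm1,
           (g2 * spec$E_rest + inj[2L]) / spec$Cm2)
    vinf <- as.numeric(-solve(A, b))
    idx <- which(seg_of == s)
    if (length(idx)) {
      s_ms <- (tt[idx] - lo) * 1000
      coef <- Pinv %*% (v0 - vinf)
      V[idx, ] <- t(vinf + P %*% (coef[, 1L] * exp(outer(lam, s_ms))))
      I1[idx] <- inj[1L]; I2[idx] <- inj[2L]
    }
    # propagate state to segment end
    dms <- (hi - lo) * 1000
    v0 <- as.numeric(vinf + P %*% ((Pinv %*% (v0 - vinf))[, 1L] * exp(lam * dms)))
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    V <- V + matrix(stats::rnorm(2L * n, 0, spec$noise_sd), n, 2)
  }
  traces <- list(
    cg_trace(cells[1L], 0, dt, V[, 1L], "intracellular"),
    cg_trace(cells[2L], 0, dt, V[, 2L], "intracellular"),
    cg_trace(paste0("I_", cells[1L]), 0, dt, I1, "current"),
    cg_trace(paste0("I_", cells[2L]), 0, dt, I2, "current"))
  names(traces) <- vapply(traces, function(x) x$cell_id, character(1))
  recording(traces, epochs = epochs,
            metadata = list(generator = "simulate_passive_pair",
                            Rc_true = spec$Rc, Rm1 = spec$Rm1,
                            Rm2 = spec$Rm2, seed = as.integer(seed)))
}
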