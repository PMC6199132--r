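# Shared fixture builders. Everything is generated in code; no data files.

# A clean step trace: rest at v0, step to v1 over [t_on, t_off).
step_trace <- function(cell = "LC4", v0 = -60, v1 = -75, t_on = 1, t_off = 2,
                       dt = 1e-3, t_total = 3, tau = 0.005) {
  tt <- seq(0, t_total, by = dt)
  v <- ifelse(tt < t_on, v0,
              ifelse(tt < t_off,
                     v1 + (v0 - v1) * exp(-(tt - t_on) / tau),
                     v0 + (v1 - v0) * exp(-(tt - t_off) / tau)))
  cg_trace(cell, 0, dt, v, "intracellular")
}

# A trace with idealised spikes: baseline plus triangular peaks.
spiky_trace <- function(spike_times, amp = 40, base = -55, dt = 1e-3,
                        t_total = NULL, width = 0.004) {
  t_total <- t_total %||% (max(spike_times) + 0.5)
  tt <- seq(0, t_total, by = dt)
  v <- rep(base, length(tt))
  for (ts in spike_times) {
    d <- abs(tt - ts)
    v <- pmax(v, base + amp * pmax(0, 1 - d / (width / 2)))
  }
  cg_trace("cell", 0, dt, v, "intracellular")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Pearson correlation, written independently of stats::cor.
pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Brute-force run splitter for burst grouping.
split_runs_bf <- function(times, max_isi) {
  if (!length(times)) return(list())
  out <- list(times[1])
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] < max_isi) {
      out[[length(out)]] <- c(out[[length(out)]], times[i])
    } else {
      out[[length(out) + 1]] <- times[i]
    }
  }
  out
}

# Full analysis with classifier warnings silenced (weakly separated
# clusters are expected in a few random draws).
analyze_quiet <- function(rec, ...) suppressWarnings(analyze_recording(rec, ...))

sync_for_test <- function(rec) analyze_quiet(rec)$sync

# A tiny default network recording reused across tests (built once).
cached_control_rec <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_cg_network(network_spec(seed = 7), duration = 15,
                                  seed = 7)
    }
    val
  }
})
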