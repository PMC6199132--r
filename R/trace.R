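#' Construct a uniformly sampled voltage/current trace
#'
#' A `cg_trace` is one channel of a recording: a uniformly sampled series with
#' a start time and sampling interval. Sample `i` (1-based) is located at
#' `t0 + (i - 1) * dt`, and covers the half-open interval up to the next
#' sample. Units are millivolts for intracellular channels, nanoamperes for
#' current channels, and arbitrary units for extracellular channels.
#'
#' @param cell_id Channel label, e.g. `"LC3"` or `"extra"`.
#' @param t0 Time of the first sample, seconds.
#' @param dt Sampling interval, seconds (> 0).
#' @param samples Numeric vector of at least two finite values.
#' @param channel_kind One of `"intracellular"`, `"extracellular"`,
#'   `"current"`.
#' @param unit Unit string, by default chosen from `channel_kind`.
#'
#' @return An object of class `cg_trace`.
#' @export
cg_trace <- function(cell_id, t0, dt, samples,
                  channel_kind = c("intracellular", "extracellular", "current"),
                  unit = NULL) {
  channel_kind <- match.arg(channel_kind)
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number (seconds)")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  structure(
    list(cell_id = cell_id, t0 = as.numeric(t0), dt = dt,
         samples = samples, channel_kind = channel_kind,
         unit = unit %||% switch(channel_kind,
                                 intracellular = "mV",
                                 extracellular = "a.u.",
                                 current = "nA")),
    class = "cg_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample times of a trace
#' @param x A `cg_trace`.
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "cg_trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' End time of a trace
#' @param x A `cg_trace`.
#' @return Time of the last sample, seconds.
#' @export
trace_end <- function(x) x$t0 + (length(x$samples) - 1) * x$dt

#' @export
print.cg_trace <- function(x, ...) {
  cat(sprintf("<cg_trace '%s' (%s): %d samples, dt = %g s, t = [%g, %g] s>\n",
              x$cell_id, x$channel_kind, length(x$samples), x$dt,
              x$t0, trace_end(x)))
  invisible(x)
}

#' Extract a window of a trace as (time, value) samples
#'
#' @param x A `cg_trace`.
#' @param t_from,t_to Window in seconds; samples with `t_from <= t <= t_to`
#'   are returned.
#' @return A list with `t` and `v` numeric vectors.
#' @export
trace_window <- function(x, t_from, t_to) {
  tt <- trace_times(x)
  keep <- tt >= t_from & tt <= t_to
  list(t = tt[keep], v = x$samples[keep])
}

#' Linearly interpolate a trace onto arbitrary times
#'
#' Times outside the trace support are an error: pairwise operations must
#' first truncate to the overlap.
#'
#' @param x A `cg_trace`.
#' @param t Times in seconds, within `[t0, trace_end(x)]`.
#' @return Numeric vector of interpolated values.
#' @export
trace_at <- function(x, t) {
  if (any(t < x$t0 - 1e-12 | t > trace_end(x) + 1e-12)) {
    stop("requested times outside trace support")
  }
  stats::approx(trace_times(x), x$samples, xout = t, rule = 2)$y
}

#' Construct an event series (e.g. spike times)
#'
#' @param times Strictly increasing event times, seconds.
#' @param labels Optional per-event character labels (e.g. `"SC"`, `"LC"`).
#' @param amplitudes Optional per-event amplitudes, units of the source trace.
#' @return An object of class `cg_events` (a data.frame with columns
#'   `time`, `label`, `amplitude`).
#' @export
event_series <- function(times, labels = NULL, amplitudes = NULL) {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing")
  }
  n <- length(times)
  labels <- labels %||% rep(NA_character_, n)
  amplitudes <- amplitudes %||% rep(NA_real_, n)
  if (length(labels) != n || length(amplitudes) != n) {
    stop("labels/amplitudes must match length of times")
  }
  structure(data.frame(time = times, label = as.character(labels),
                       amplitude = as.numeric(amplitudes),
                       stringsAsFactors = FALSE),
            class = c("cg_events", "data.frame"))
}

#' Construct a current-injection protocol epoch
#'
#' @param injected_cell Cell id receiving the step.
#' @param amplitude Step amplitude in nA (negative = hyperpolarizing); must be
#'   nonzero.
#' @param t_start,t_end Step window in seconds, `t_start < t_end`.
#' @param baseline_window Seconds before `t_start` used for the pre-step
#'   voltage (> 0).
#' @return A one-row data.frame of class `cg_epoch`.
#' @export
protocol_epoch <- function(injected_cell, amplitude, t_start, t_end,
                           baseline_window = 0.1) {
  if (amplitude == 0) stop("epoch amplitude must be nonzero")
  if (!(t_start < t_end)) stop("epoch must have t_start < t_end")
  if (baseline_window <= 0) stop("baseline_window must be positive")
  structure(data.frame(injected_cell = injected_cell,
                       amplitude = amplitude,
                       t_start = t_start, t_end = t_end,
                       baseline_window = baseline_window,
                       stringsAsFactors = FALSE),
            class = c("cg_epoch", "data.frame"))
}

#' Assemble a multichannel recording
#'
#' A `cg_recording` bundles traces sharing a common time frame, optional
#' per-channel event series, current-step protocol epochs, and a condition
#' timeline (when each perfusion condition begins).
#'
#' @param traces List of `cg_trace`, named by channel. All traces must
#'   overlap in time.
#' @param events Optional named list of `cg_events`.
#' @param epochs Optional data.frame of protocol epochs (rows as from
#'   [protocol_epoch()]).
#' @param condition_timeline Optional data.frame with columns `time` (s,
#'   increasing) and `condition` (label such as `"control"`, `"5HT"`).
#' @param metadata Optional named list of scalar metadata.
#' @return An object of class `cg_recording`.
#' @export
recording <- function(traces, events = NULL, epochs = NULL,
                      condition_timeline = NULL, metadata = list()) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- vapply(traces, function(x) x$cell_id, character(1))
  }
  if (anyDuplicated(names(traces))) stop("duplicate channel names")
  for (tr in traces) stopifnot(inherits(tr, "cg_trace"))
  t0s <- vapply(traces, function(x) x$t0, numeric(1))
  ends <- vapply(traces, function(x) trace_end(x), numeric(1))
  if (max(t0s) >= min(ends)) stop("traces do not overlap in time")
  if (!is.null(condition_timeline)) {
    stopifnot(all(c("time", "condition") %in% names(condition_timeline)))
    if (is.unsorted(condition_timeline$time, strictly = TRUE) &&
        nrow(condition_timeline) > 1L) {
      stop("condition_timeline times must be increasing")
    }
  }
  structure(list(traces = traces, events = events %||% list(),
                 epochs = epochs, condition_timeline = condition_timeline,
                 metadata = metadata),
            class = "cg_recording")
}

#' @export
print.cg_recording <- function(x, ...) {
  cat(sprintf("<cg_recording: %d channel(s)>\n", length(x$traces)))
  for (tr in x$traces) print(tr)
  if (!is.null(x$epochs)) cat(sprintf("  %d protocol epoch(s)\n", nrow(x$epochs)))
  if (!is.null(x$condition_timeline)) {
    cat(sprintf("  timeline: %s\n",
                paste(sprintf("%s@%gs", x$condition_timeline$condition,
                              x$condition_timeline$time), collapse = ", ")))
  }
  invisible(x)
}

#' Resample two traces onto a shared grid over a window
#'
#' Pairwise operations (correlation of two electrodes digitised at possibly
#' different rates) happen on the coarser of the two sampling grids, after
#' truncating to the overlap of the window and both traces. Linear
#' interpolation is used for the finer trace.
#'
#' @param a,b `cg_trace` objects.
#' @param t_from,t_to Window in seconds.
#' @return List with `t` (grid), `va`, `vb`.
#' @export
common_grid <- function(a, b, t_from, t_to) {
  lo <- max(t_from, a$t0, b$t0)
  hi <- min(t_to, trace_end(a), trace_end(b))
  if (hi <= lo) stop("traces do not overlap the requested window")
  dt <- max(a$dt, b$dt)
  t <- seq(lo, hi, by = dt)
  list(t = t, va = trace_at(a, t), vb = trace_at(b, t))
}
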