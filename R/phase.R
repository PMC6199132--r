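#' Phase relationships of SC and LC bursts within each cycle
#'
#' Phases are event latencies from the cycle start divided by the full
#' cycle period (dimensionless, in `[0, 1)`): `sc_off` is the end of the
#' pacemaker burst, `lc_on` the first spike of each LC burst, and `lc_off`
#' its last spike. Double-burst cycles yield two `(lc_on, lc_off)` pairs,
#' ordered by onset.
#'
#' @param cycles A `cg_cycles` table from [segment_cycles()].
#' @return A data.frame with one row per LC burst: `cycle`, `slot`,
#'   `period`, `sc_off`, `lc_on`, `lc_off`.
#' @export
compute_phases <- function(cycles) {
  rows <- list()
  for (k in seq_len(nrow(cycles))) {
    period <- cycles$t_next[k] - cycles$t_start[k]
    if (period <= 0) stop("non-positive cycle period")
    lb <- cycles$lc_bursts[[k]]
    for (j in seq_len(nrow(lb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, slot = j, period = period,
        sc_off = (cycles$sc_off_time[k] - cycles$t_start[k]) / period,
        lc_on = (lb$t_first[j] - cycles$t_start[k]) / period,
        lc_off = (lb$t_last[j] - cycles$t_start[k]) / period)
    }
  }
  do.call(rbind, rows)
}

#' Burst statistics per cycle
#'
#' For each LC burst in each complete cycle: spike count, burst duration
#' (first to last spike), within-burst spike frequency computed from the
#' inter-spike intervals (`(n - 1)/duration`; single-spike bursts get 0 and
#' a flag), duty cycle (duration over cycle period), inter-burst interval
#' (to the next burst's first spike), and the cycle period.
#'
#' @param cycles A `cg_cycles` table from [segment_cycles()].
#' @return A data.frame with one row per LC burst: `cycle`, `slot`,
#'   `n_spikes`, `burst_duration`, `spike_freq`, `duty_cycle`,
#'   `interburst_interval`, `cycle_period`, `single_spike`.
#' @export
compute_burst_stats <- function(cycles) {
  rows <- list()
  for (k in seq_len(nrow(cycles))) {
    period <- cycles$t_next[k] - cycles$t_start[k]
    lb <- cycles$lc_bursts[[k]]
    for (j in seq_len(nrow(lb))) {
      dur <- lb$t_last[j] - lb$t_first[j]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, slot = j, n_spikes = lb$n_spikes[j],
        burst_duration = dur,
        spike_freq = if (lb$n_spikes[j] >= 2L) (lb$n_spikes[j] - 1L) / dur else 0,
        duty_cycle = dur / period,
        interburst_interval = NA_real_,
        cycle_period = period,
        single_spike = lb$n_spikes[j] < 2L)
    }
  }
  out <- do.call(rbind, rows)
  # interburst interval: next burst onset minus this burst end, in time order
  firsts <- unlist(lapply(seq_len(nrow(cycles)),
                          function(k) cycles$lc_bursts[[k]]$t_first))
  lasts <- unlist(lapply(seq_len(nrow(cycles)),
                         function(k) cycles$lc_bursts[[k]]$t_last))
  if (length(firsts) > 1L) {
    out$interburst_interval <- c(firsts[-1L] - lasts[-length(lasts)], NA_real_)
  }
  out
}

#' Mean and SD over n consecutive cycles preceding a time point
#'
#' The standard reporting rule: each quantity is averaged over the `n`
#' consecutive cycles immediately preceding a condition time point (sample
#' SD, n - 1 denominator).
#'
#' @param values Per-cycle values, in cycle order.
#' @param times Per-cycle reference times (s), same length.
#' @param at Condition time point, s.
#' @param n Number of consecutive cycles.
#' @return A one-row data.frame: `mean`, `sd`, `n`.
#' @export
average_over_cycles <- function(values, times, at, n = 10) {
  stopifnot(length(values) == length(times))
  ord <- order(times)
  values <- values[ord]; times <- times[ord]
  idx <- which(times <= at)
  if (length(idx) < n) {
    stop(sprintf("need %d cycles at/before t = %g, have %d", n, at, length(idx)))
  }
  sel <- utils::tail(idx, n)
  data.frame(mean = mean(values[sel]), sd = stats::sd(values[sel]), n = n)
}
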