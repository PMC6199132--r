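#' Segment the rhythm into pacemaker-anchored cycles
#'
#' Each cycle begins with the start of a pacemaker (SC) burst and ends at
#' the start of the next pacemaker burst. LC bursts are assigned to the
#' cycle containing their first spike; a cycle holding two distinct LC
#' bursts is in `double` mode. The final SC burst (with no successor) and
#' any LC bursts outside complete cycles are discarded.
#'
#' @param sc_events A [event_series()] of SC spike times (or an events table
#'   with labels, from which rows labelled `"SC"` are taken).
#' @param lc_events LC spike times for the reference cell, same formats.
#' @param sc_max_isi Maximum within-burst ISI for SC spikes, s.
#' @param lc_max_isi Maximum within-burst ISI for LC spikes, s.
#' @return A data.frame of class `cg_cycles`, one row per complete cycle:
#'   `t_start`, `t_next`, `sc_off_time`, `mode`, `n_lc_bursts`, plus
#'   list-column `lc_bursts` (each a data.frame as from [group_bursts()]).
#' @export
segment_cycles <- function(sc_events, lc_events,
                           sc_max_isi = 0.5, lc_max_isi = 0.25) {
  pick <- function(ev, lab) {
    if (inherits(ev, "cg_events") || is.data.frame(ev)) {
      tt <- ev$time
      if (!all(is.na(ev$label))) tt <- ev$time[ev$label == lab]
      tt
    } else as.numeric(ev)
  }
  sc <- pick(sc_events, "SC")
  lc <- pick(lc_events, "LC")
  if (!length(sc) || !length(lc)) stop("need non-empty SC and LC event sets")
  scb <- group_bursts(sc, sc_max_isi)
  lcb <- group_bursts(lc, lc_max_isi)
  if (nrow(scb) < 2L) stop("zero complete cycles (need >= 2 pacemaker bursts)")
  rows <- list()
  for (k in seq_len(nrow(scb) - 1L)) {
    t_start <- scb$t_first[k]
    t_next <- scb$t_first[k + 1L]
    inb <- which(lcb$t_first >= t_start & lcb$t_first < t_next)
    if (!length(inb)) next
    if (length(inb) > 2L) inb <- inb[order(-lcb$n_spikes[inb])[1:2]]
    inb <- sort(inb)
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = t_start, t_next = t_next,
      sc_off_time = scb$t_last[k],
      mode = if (length(inb) == 2L) "double" else "single",
      n_lc_bursts = length(inb), stringsAsFactors = FALSE)
    rows[[length(rows)]]$lc_bursts <- list(lcb[inb, , drop = FALSE])
  }
  if (!length(rows)) stop("zero complete cycles containing LC bursts")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cg_cycles", "data.frame")
  out
}

#' Estimate the resting membrane potential
#'
#' The operational resting value is the 10th percentile of the voltage over
#' the inter-burst windows, each running from 100 ms after the last LC spike
#' of a cycle to the start of the next cycle. Windows exclude the
#' depolarised floor between double-burst lobes by construction.
#'
#' @param tr Intracellular `cg_trace`.
#' @param cycles A `cg_cycles` table from [segment_cycles()].
#' @return A list with `rest` (mV) and `mad` (robust spread, mV).
#' @export
estimate_baseline <- function(tr, cycles) {
  stopifnot(inherits(tr, "cg_trace"))
  vals <- numeric(0)
  for (k in seq_len(nrow(cycles))) {
    lb <- cycles$lc_bursts[[k]]
    lo <- max(lb$t_last) + 0.1
    hi <- cycles$t_next[k]
    if (hi > lo) {
      w <- trace_window(tr, lo, hi)
      vals <- c(vals, w$v)
    }
  }
  if (!length(vals)) stop("no inter-burst samples available")
  list(rest = unname(stats::quantile(vals, 0.1)), mad = stats::mad(vals))
}

#' Mark intracellular burst-waveform boundaries for one cycle
#'
#' Single-burst cycles: the waveform begins at the cycle start (first
#' pacemaker spike) and ends at the first time after the last LC spike where
#' the voltage returns to rest (`V <= rest + tol`), capped at the next cycle
#' start (flag `unterminated` if the cap is hit).
#'
#' Double-burst cycles (the membrane does not return to rest between the
#' two bursts): the start of burst 1 and the end of burst 2 are marked as
#' above. The delay from the last spike of burst 2 to its return to rest is
#' then applied after the last spike of burst 1 to set a comparable
#' end-point; the delay from the cycle start to the first spike of burst 1
#' is applied before the first spike of burst 2 to set a comparable start.
#' Segments are clipped to the cycle and to non-overlap (the earlier
#' segment wins ties).
#'
#' @param cycle One row of a `cg_cycles` table.
#' @param tr Intracellular `cg_trace` of the reference cell.
#' @param rest Resting potential, mV (see [estimate_baseline()]).
#' @param tol Return-to-rest tolerance, mV (> 0).
#' @return A data.frame with one row per LC burst in the cycle: `slot`,
#'   `t_begin`, `t_end`, `unterminated`.
#' @export
mark_waveform_bounds <- function(cycle, tr, rest, tol = 2) {
  stopifnot(tol > 0)
  lb <- cycle$lc_bursts[[1L]]
  t_start <- cycle$t_start
  t_next <- cycle$t_next
  return_to_rest <- function(after) {
    w <- trace_window(tr, after, t_next)
    hit <- which(w$v <= rest + tol)
    if (length(hit)) list(t = w$t[hit[1L]], flag = FALSE)
    else list(t = t_next, flag = TRUE)
  }
  if (cycle$mode == "single") {
    rr <- return_to_rest(lb$t_last[1L])
    out <- data.frame(slot = 1L, t_begin = t_start, t_end = rr$t,
                      unterminated = rr$flag)
  } else {
    rr2 <- return_to_rest(lb$t_last[2L])
    delta_end <- rr2$t - lb$t_last[2L]
    delta_begin <- lb$t_first[1L] - t_start
    b1_end <- lb$t_last[1L] + delta_end
    b2_begin <- lb$t_first[2L] - delta_begin
    # clip to the cycle and to non-overlap (earlier segment wins)
    b1_end <- min(b1_end, t_next)
    b2_begin <- max(b2_begin, b1_end)
    out <- data.frame(slot = c(1L, 2L),
                      t_begin = c(t_start, b2_begin),
                      t_end = c(b1_end, rr2$t),
                      unterminated = c(FALSE, rr2$flag))
  }
  out
}
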