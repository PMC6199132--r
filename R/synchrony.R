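#' Waveform synchrony of one burst (squared Pearson correlation)
#'
#' The two intracellular segments delimited by the waveform bounds are
#' resampled onto their common grid (the coarser of the two sampling
#' intervals, truncated to the overlap) and correlated at zero lag. The
#' coefficient of determination `r2 = r^2` quantifies how accurately the
#' voltage of one cell predicts the voltage of the other during the burst.
#'
#' The synchrony statistic itself is always computed at zero lag: the two
#' electrodes sample the same moments, and the question is how well one
#' voltage predicts the other *now*. A diagnostic lag scan is available via
#' `max_lag` (seconds); it reports the lag maximising `|r|` in an extra
#' `best_lag` column but never feeds the returned `r`/`r2`.
#'
#' @param trace_a,trace_b Intracellular `cg_trace` objects covering the
#'   segment.
#' @param t_begin,t_end Segment bounds, s (from [mark_waveform_bounds()]).
#' @param max_lag Optional maximum lag (s) for the diagnostic scan.
#' @return A one-row data.frame: `t` (segment midpoint), `r`, `r2`,
#'   `n_samples`, `negative_r` (and `best_lag` when `max_lag` is given).
#' @export
burst_r2 <- function(trace_a, trace_b, t_begin, t_end, max_lag = NULL) {
  g <- common_grid(trace_a, trace_b, t_begin, t_end)
  if (length(g$t) < 10L) stop("fewer than 10 samples in segment after resampling")
  if (stats::sd(g$va) == 0 || stats::sd(g$vb) == 0) {
    stop("degenerate segment: zero variance")
  }
  r <- stats::cor(g$va, g$vb)
  out <- data.frame(t = (t_begin + t_end) / 2, r = r, r2 = r^2,
                    n_samples = length(g$t), negative_r = r < 0)
  if (!is.null(max_lag)) {
    dt <- g$t[2L] - g$t[1L]
    lags <- seq(-round(max_lag / dt), round(max_lag / dt))
    rl <- vapply(lags, function(l) {
      n <- length(g$va)
      if (l >= 0) ia <- (1 + l):n else ia <- 1:(n + l)
      ib <- ia - l
      if (length(ia) < 10L) return(NA_real_)
      stats::cor(g$va[ia], g$vb[ib])
    }, numeric(1))
    out$best_lag <- lags[which.max(abs(rl))] * dt
  }
  out
}

#' Per-burst synchrony across a whole experiment
#'
#' Computes one synchrony point per LC-burst slot per cycle, in time order.
#' Waveform bounds are marked on the reference cell (`cells[1]`) and applied
#' to both traces. Degenerate segments are skipped with a flag rather than
#' failing the run.
#'
#' @param rec A [recording()].
#' @param cycles A `cg_cycles` table from [segment_cycles()].
#' @param cells Character vector of two intracellular channel names.
#' @param rest Resting potential for bound marking; by default estimated
#'   from the reference trace via [estimate_baseline()].
#' @param tol Return-to-rest tolerance, mV.
#' @return A data.frame of class `cg_sync`: `cycle`, `slot`, `t`, `r`,
#'   `r2`, `n_samples`, `negative_r`, `skipped`.
#' @export
sync_timecourse <- function(rec, cycles, cells, rest = NULL, tol = 2) {
  stopifnot(inherits(rec, "cg_recording"), length(cells) == 2L)
  if (!all(cells %in% names(rec$traces))) {
    stop("cells not found in recording: ",
         paste(setdiff(cells, names(rec$traces)), collapse = ", "))
  }
  ta <- rec$traces[[cells[1L]]]
  tb <- rec$traces[[cells[2L]]]
  if (is.null(rest)) rest <- estimate_baseline(ta, cycles)$rest
  rows <- list()
  for (k in seq_len(nrow(cycles))) {
    bounds <- mark_waveform_bounds(cycles[k, ], ta, rest, tol)
    for (j in seq_len(nrow(bounds))) {
      pt <- tryCatch(
        burst_r2(ta, tb, bounds$t_begin[j], bounds$t_end[j]),
        error = function(e) NULL)
      if (is.null(pt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cycle = k, slot = bounds$slot[j],
          t = (bounds$t_begin[j] + bounds$t_end[j]) / 2,
          r = NA_real_, r2 = NA_real_, n_samples = 0L,
          negative_r = FALSE, skipped = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(cycle = k, slot = bounds$slot[j]), pt,
          data.frame(skipped = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cg_sync", "data.frame")
  out
}

#' Average synchrony over n consecutive bursts
#'
#' The epoch rule mirrors the reporting convention: `ending_at` takes the
#' `n` bursts immediately preceding a time point (the control epoch, e.g. 5
#' min before perfusion); `centered_at` takes the `n` bursts whose window
#' centre is nearest the time point; `at_minimum` scans every window of `n`
#' consecutive bursts after `t` and keeps the one with the lowest mean
#' (the acute, maximally desynchronised epoch).
#'
#' @param series A `cg_sync` table (double-burst slots are pooled).
#' @param selection One of `"ending_at"`, `"centered_at"`, `"at_minimum"`.
#' @param t Reference time, s (perfusion start for `"at_minimum"`).
#' @param n Number of consecutive bursts to average.
#' @return A one-row data.frame: `t_center`, `mean_r2`, `sd_r2`, `n_bursts`.
#' @export
epoch_mean_r2 <- function(series,
                          selection = c("ending_at", "centered_at", "at_minimum"),
                          t, n = 10) {
  selection <- match.arg(selection)
  s <- series[!series$skipped, , drop = FALSE]
  s <- s[order(s$t), , drop = FALSE]
  pick <- switch(selection,
    ending_at = {
      idx <- which(s$t <= t)
      if (length(idx) < n) stop(sprintf(
        "need %d bursts at/before t = %g, have %d", n, t, length(idx)))
      utils::tail(idx, n)
    },
    centered_at = {
      if (nrow(s) < n) stop(sprintf("need %d bursts, have %d", n, nrow(s)))
      starts <- seq_len(nrow(s) - n + 1L)
      ctr <- vapply(starts, function(i) mean(s$t[i:(i + n - 1L)]), numeric(1))
      i <- starts[which.min(abs(ctr - t))]
      i:(i + n - 1L)
    },
    at_minimum = {
      idx <- which(s$t > t)  # contiguous tail of the sorted series
      if (length(idx) < n) stop(sprintf(
        "need %d bursts after t = %g, have %d", n, t, length(idx)))
      starts <- idx[seq_len(length(idx) - n + 1L)]
      means <- vapply(starts, function(i) mean(s$r2[i:(i + n - 1L)]),
                      numeric(1))
      i0 <- starts[which.min(means)]
      i0:(i0 + n - 1L)
    })
  data.frame(t_center = mean(s$t[pick]),
             mean_r2 = mean(s$r2[pick]),
             sd_r2 = stats::sd(s$r2[pick]),
             n_bursts = n)
}

#' Locate the acute synchrony minimum after perfusion
#'
#' Returns the time at which the centred moving average (window `smooth_n`
#' bursts) of the per-burst synchrony is lowest, restricted to bursts after
#' the perfusion start; the earliest such time wins ties.
#'
#' @param series A `cg_sync` table.
#' @param perfusion_t Perfusion start, s.
#' @param smooth_n Moving-average window, bursts.
#' @return Time of the minimum, s.
#' @export
find_acute_minimum <- function(series, perfusion_t, smooth_n = 10) {
  s <- series[!series$skipped, , drop = FALSE]
  s <- s[order(s$t), , drop = FALSE]
  n <- nrow(s)
  if (sum(s$t > perfusion_t) < smooth_n) {
    stop(sprintf("need %d bursts after perfusion, have %d",
                 smooth_n, sum(s$t > perfusion_t)))
  }
  half_lo <- floor((smooth_n - 1) / 2)
  half_hi <- smooth_n - 1 - half_lo
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo); hi <- min(n, i + half_hi)
    mean(s$r2[lo:hi])
  }, numeric(1))
  post <- which(s$t > perfusion_t)
  i <- post[which.min(sm[post])]  # which.min returns the first minimum
  s$t[i]
}
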