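#' Detect spikes on a trace
#'
#' Events are local maxima exceeding a threshold, separated by at least the
#' refractory interval (when two suprathreshold maxima fall closer than
#' that, the larger is kept). Event amplitude is the peak value minus the
#' local baseline (median of the trace within +/- `baseline_halfwidth` of
#' the peak).
#'
#' @param tr A `cg_trace`.
#' @param threshold Numeric threshold in trace units, or `"auto"`: baseline
#'   (global median) plus `k_mad` robust standard deviations
#'   (`mad`, which scales the median absolute deviation to be consistent
#'   with the SD for normal data).
#' @param refractory Minimum separation between events, s (> 0).
#' @param k_mad Multiplier for the `"auto"` threshold.
#' @param baseline_halfwidth Half-width of the local-baseline window, s.
#' @return A [event_series()] with times and amplitudes.
#' @export
detect_spikes <- function(tr, threshold = "auto", refractory = 0.002,
                          k_mad = 5, baseline_halfwidth = 0.2) {
  stopifnot(inherits(tr, "cg_trace"), refractory > 0)
  v <- tr$samples
  if (identical(threshold, "auto")) {
    s <- stats::mad(v)
    if (s == 0) stop("flat trace: cannot set automatic threshold (MAD = 0)")
    threshold <- stats::median(v) + k_mad * s
  }
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  idx <- which(is_max & v > threshold)
  if (!length(idx)) return(event_series(numeric(0)))
  # enforce refractory: greedy, keep the larger of any conflicting pair
  ord <- idx[order(-v[idx])]
  keep <- logical(n)
  taken <- rep(FALSE, n)
  ref_n <- max(1L, round(refractory / tr$dt))
  for (i in ord) {
    lo <- max(1L, i - ref_n); hi <- min(n, i + ref_n)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[i] <- TRUE
    }
  }
  idx <- which(keep)
  tt <- trace_times(tr)[idx]
  half_n <- max(1L, round(baseline_halfwidth / tr$dt))
  amps <- vapply(idx, function(i) {
    lo <- max(1L, i - half_n); hi <- min(n, i + half_n)
    v[i] - stats::median(v[lo:hi])
  }, numeric(1))
  event_series(tt, amplitudes = amps)
}

#' Classify detected units as SC or LC by spike amplitude
#'
#' Pacemaker (SC) and motor-neuron (LC) spikes on the extracellular trunk
#' recording are distinguished by their relative amplitudes. A deterministic
#' 1-D 2-means split (centers initialised at the minimum and maximum)
#' assigns the lower-mean class the label `SC`. Amplitudes are ratio-scale,
#' so when all are positive the clustering runs on log-amplitude; this
#' keeps near-coincident LC spikes that superpose into double-amplitude
#' events inside the LC class. When the between-class gap is less than
#' twice the within-class spread the result carries the attribute
#' `ambiguous = TRUE` (labels are still returned).
#'
#' @param events A [event_series()] with amplitudes; at least 4 events.
#' @return The event series with `label` filled in (`"SC"`/`"LC"`) and an
#'   `ambiguous` attribute.
#' @export
classify_units <- function(events) {
  stopifnot(inherits(events, "cg_events"))
  if (nrow(events) < 4L) stop("need at least 4 events to classify")
  a <- events$amplitude
  if (all(a > 0)) a <- log(a)
  c1 <- min(a); c2 <- max(a)
  assign <- NULL
  for (it in 1:100) {
    newassign <- ifelse(abs(a - c1) <= abs(a - c2), 1L, 2L)
    if (identical(newassign, assign)) break
    assign <- newassign
    if (any(assign == 1L)) c1 <- mean(a[assign == 1L])
    if (any(assign == 2L)) c2 <- mean(a[assign == 2L])
  }
  lower <- if (c1 <= c2) 1L else 2L
  events$label <- ifelse(assign == lower, "SC", "LC")
  spread <- stats::sd(a[assign == 1L]) + stats::sd(a[assign == 2L])
  gap <- abs(c2 - c1)
  ambiguous <- !is.finite(spread) || spread == 0 || gap / spread < 2
  if (all(a == a[1L])) ambiguous <- TRUE
  attr(events, "ambiguous") <- ambiguous
  if (ambiguous) warning("ambiguous classification: amplitude clusters overlap")
  events
}

#' Group spike times into bursts
#'
#' A burst is a maximal run of spikes whose consecutive inter-spike
#' intervals are all below `max_isi`. Singleton bursts are allowed.
#'
#' @param spike_times Sorted spike times, s.
#' @param max_isi Maximum within-burst inter-spike interval, s (> 0).
#' @param cell_id Optional label attached to each burst.
#' @return A data.frame with one row per burst: `cell_id`, `t_first`,
#'   `t_last`, `n_spikes`, and a list-column `spike_times`.
#' @export
group_bursts <- function(spike_times, max_isi, cell_id = NA_character_) {
  stopifnot(max_isi > 0)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) == 0L) {
    return(data.frame(cell_id = character(0), t_first = numeric(0),
                      t_last = numeric(0), n_spikes = integer(0)))
  }
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  grp <- cumsum(c(1, diff(spike_times) >= max_isi))
  sp <- split(spike_times, grp)
  out <- data.frame(
    cell_id = cell_id,
    t_first = vapply(sp, function(x) x[1L], numeric(1)),
    t_last = vapply(sp, function(x) x[length(x)], numeric(1)),
    n_spikes = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$spike_times <- unname(sp)
  rownames(out) <- NULL
  out
}
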