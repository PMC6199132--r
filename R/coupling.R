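#' Steady-state voltage deflection of a current step
#'
#' `dV` is the mean voltage over the last 20% of the step minus the mean
#' over the baseline window immediately preceding it. Spikes inside either
#' window (excursions more than 10 mV above the window median) are excised
#' before averaging. Steps shorter than 5 estimated membrane time constants
#' get a `short_step` flag.
#'
#' @param tr Intracellular `cg_trace`.
#' @param epoch One row as from [protocol_epoch()].
#' @param spike_excursion Excision threshold above the window median, mV.
#' @return A list: `dV` (mV), `short_step` flag.
#' @export
measure_deltaV <- function(tr, epoch, spike_excursion = 10) {
  stopifnot(inherits(tr, "cg_trace"))
  if (epoch$t_start < tr$t0 || epoch$t_end > trace_end(tr)) {
    stop("epoch outside trace")
  }
  clean_mean <- function(w) {
    med <- stats::median(w$v)
    keep <- w$v <= med + spike_excursion
    if (!any(keep)) stop("all samples in window excised as spikes")
    mean(w$v[keep])
  }
  step_len <- epoch$t_end - epoch$t_start
  base <- trace_window(tr, epoch$t_start - epoch$baseline_window, epoch$t_start)
  tail_w <- trace_window(tr, epoch$t_end - 0.2 * step_len, epoch$t_end)
  if (!length(base$t) || !length(tail_w$t)) stop("empty measurement window")
  v_base <- clean_mean(base)
  v_step <- clean_mean(tail_w)
  # crude tau estimate: time to reach 1-1/e of the deflection
  w <- trace_window(tr, epoch$t_start, epoch$t_end)
  dv <- v_step - v_base
  short <- FALSE
  if (abs(dv) > 0) {
    crossed <- which(abs(w$v - v_base) >= (1 - exp(-1)) * abs(dv))
    tau_est <- if (length(crossed)) w$t[crossed[1L]] - epoch$t_start else step_len
    short <- step_len < 5 * tau_est
  }
  list(dV = dv, short_step = short)
}

#' Coupling coefficient from paired deflections
#'
#' The ratio of the steady-state deflection in the coupled cell to the
#' deflection in the injected cell. Returned signed; values outside `[0, 1]`
#' are physically suspect for passive spread and get a flag.
#'
#' @param dV_coupled,dV_injected Deflections, mV; `dV_injected` nonzero.
#' @return List: `cc`, `suspect` flag.
#' @export
coupling_coefficient <- function(dV_coupled, dV_injected) {
  if (dV_injected == 0) stop("zero deflection in injected cell")
  cc <- dV_coupled / dV_injected
  list(cc = cc, suspect = cc < 0 || cc > 1)
}

#' Input and transfer resistance from a family of current steps
#'
#' Fits `dV = R * I` through the origin by least squares across the step
#' amplitudes (MOhm, since mV/nA). With a single distinct amplitude the
#' ratio `dV/I` is used and flagged. A positive-voltage response to a
#' hyperpolarizing family (negative slope) is flagged as sign-inconsistent.
#'
#' @param I Injected amplitudes, nA.
#' @param dV_injected Deflections in the injected cell, mV.
#' @param dV_coupled Deflections in the coupled cell, mV.
#' @return List: `Rin`, `R12` (MOhm), `se_Rin`, `se_R12` (slope standard
#'   errors, NA for single-step), `single_step`, `sign_inconsistent`.
#' @export
fit_resistances <- function(I, dV_injected, dV_coupled) {
  stopifnot(length(I) == length(dV_injected), length(I) == length(dV_coupled))
  if (length(unique(I)) < 2L) {
    Rin <- mean(dV_injected / I)
    R12 <- mean(dV_coupled / I)
    return(list(Rin = Rin, R12 = R12, se_Rin = NA_real_, se_R12 = NA_real_,
                single_step = TRUE, sign_inconsistent = Rin < 0))
  }
  fit1 <- stats::lm(dV_injected ~ 0 + I)
  fit2 <- stats::lm(dV_coupled ~ 0 + I)
  # noiseless fixtures fit exactly; the perfect-fit warning is expected
  s1 <- suppressWarnings(summary(fit1))$coefficients
  s2 <- suppressWarnings(summary(fit2))$coefficients
  list(Rin = unname(stats::coef(fit1)[1L]),
       R12 = unname(stats::coef(fit2)[1L]),
       se_Rin = s1[1L, 2L], se_R12 = s2[1L, 2L],
       single_step = FALSE,
       sign_inconsistent = unname(stats::coef(fit1)[1L]) < 0)
}

#' Bennett two-compartment coupling resistance and conductance
#'
#' For an electrotonically compact two-cell system,
#' `Rc = (Rin1 * Rin2 - R12^2) / R12` and `Gc = 1/Rc`. Requires a positive
#' transfer resistance and `Rin1 * Rin2 > R12^2` (otherwise the estimate is
#' non-physical).
#'
#' @param Rin1,Rin2 Apparent input resistances, MOhm.
#' @param R12 Transfer resistance, MOhm.
#' @return List: `Rc` (MOhm), `Gc` (uS).
#' @export
bennett_conductance <- function(Rin1, Rin2, R12) {
  if (R12 <= 0) stop("no measurable transfer (R12 <= 0)")
  num <- Rin1 * Rin2 - R12^2
  if (num <= 0) stop("non-physical estimate: Rin1*Rin2 <= R12^2")
  Rc <- num / R12
  list(Rc = Rc, Gc = 1 / Rc)
}

#' Full coupling estimate from a step-protocol recording
#'
#' Runs the whole chain for a pair of cells: deflection extraction per
#' epoch, per-step coupling coefficients (averaged per direction),
#' origin-free resistance fits per direction, and the Bennett conductance
#' per direction (direction `1->2` uses `Rin` of both cells with the
#' transfer resistance measured when injecting into cell 1). A pooled
#' symmetric estimate using the mean of the two transfer resistances is
#' also reported.
#'
#' @param rec A [recording()] with epochs for both injection directions.
#' @param cells Character vector: the two intracellular channel names.
#' @return A list of class `coupling_result`: `cc_12`, `cc_21`, `Rin_1`,
#'   `Rin_2`, `R12_from1`, `R12_from2`, `Rc_dir12`, `Rc_dir21`, `Gc_dir12`,
#'   `Gc_dir21`, `Rc_pooled`, `Gc_pooled`, `n_steps`, `steps` (per-step
#'   table), `flags`.
#' @export
coupling_from_protocol <- function(rec, cells) {
  stopifnot(inherits(rec, "cg_recording"), length(cells) == 2L)
  ep <- rec$epochs
  if (is.null(ep) || !nrow(ep)) stop("recording has no protocol epochs")
  ep <- ep[ep$injected_cell %in% cells, , drop = FALSE]
  if (!nrow(ep)) stop("no epochs for the requested cells")
  rows <- list()
  for (i in seq_len(nrow(ep))) {
    inj <- ep$injected_cell[i]
    oth <- setdiff(cells, inj)
    mi <- measure_deltaV(rec$traces[[inj]], ep[i, ])
    mo <- measure_deltaV(rec$traces[[oth]], ep[i, ])
    rows[[i]] <- data.frame(
      injected_cell = inj, I = ep$amplitude[i],
      dV_injected = mi$dV, dV_coupled = mo$dV,
      cc = coupling_coefficient(mo$dV, mi$dV)$cc,
      short_step = mi$short_step)
  }
  steps <- do.call(rbind, rows)
  flags <- character(0)
  res <- list(steps = steps, n_steps = nrow(steps))
  dirs <- list(`1` = cells[1L], `2` = cells[2L])
  fits <- list()
  for (d in 1:2) {
    sub <- steps[steps$injected_cell == cells[d], , drop = FALSE]
    if (!nrow(sub)) {
      flags <- c(flags, sprintf("missing direction: no injections into %s", cells[d]))
      fits[[d]] <- NULL
      next
    }
    fits[[d]] <- fit_resistances(sub$I, sub$dV_injected, sub$dV_coupled)
    if (fits[[d]]$single_step) flags <- c(flags, sprintf("single-step fit for %s", cells[d]))
    if (fits[[d]]$sign_inconsistent) flags <- c(flags, sprintf("sign-inconsistent slope for %s", cells[d]))
    res[[paste0("cc_", d, c(2, 1)[d])]] <-
      mean(sub$cc)
    res[[paste0("Rin_", d)]] <- fits[[d]]$Rin
    res[[paste0("R12_from", d)]] <- fits[[d]]$R12
    res[[paste0("se_Rin_", d)]] <- fits[[d]]$se_Rin
    res[[paste0("se_R12_from", d)]] <- fits[[d]]$se_R12
  }
  if (!is.null(fits[[1L]]) && !is.null(fits[[2L]])) {
    b12 <- bennett_conductance(res$Rin_1, res$Rin_2, res$R12_from1)
    b21 <- bennett_conductance(res$Rin_1, res$Rin_2, res$R12_from2)
    bp <- bennett_conductance(res$Rin_1, res$Rin_2,
                              mean(c(res$R12_from1, res$R12_from2)))
    res$Rc_dir12 <- b12$Rc; res$Gc_dir12 <- b12$Gc
    res$Rc_dir21 <- b21$Rc; res$Gc_dir21 <- b21$Gc
    res$Rc_pooled <- bp$Rc; res$Gc_pooled <- bp$Gc
  } else {
    flags <- c(flags, "partial result: only one direction available")
  }
  res$flags <- flags
  class(res) <- "coupling_result"
  res
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result>\n")
  fmt <- function(nm) if (!is.null(x[[nm]])) sprintf("%.4g", x[[nm]]) else "NA"
  cat(sprintf("  cc:  1->2 %s, 2->1 %s\n", fmt("cc_12"), fmt("cc_21")))
  cat(sprintf("  Rin: %s / %s MOhm; R12: %s / %s MOhm\n",
              fmt("Rin_1"), fmt("Rin_2"), fmt("R12_from1"), fmt("R12_from2")))
  cat(sprintf("  Gc:  1->2 %s, 2->1 %s uS (pooled %s)\n",
              fmt("Gc_dir12"), fmt("Gc_dir21"), fmt("Gc_pooled")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
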