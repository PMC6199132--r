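#' Read a recording from CSV (+ optional YAML sidecar)
#'
#' The CSV dialect is one `time` column in seconds plus one column per
#' channel; the header row names the channels. Channel kinds, protocol
#' epochs, the condition timeline and metadata live in a YAML sidecar file
#' (same path with extension `.yaml`), which is optional: without it every
#' channel is taken as intracellular.
#'
#' Timestamps must be uniform; jitter below `dt/100` is tolerated and
#' regularised to the nominal `dt` (median of the first differences). A
#' single missing sample is repaired by linear interpolation; longer NaN runs
#' are an error naming the channel and sample index.
#'
#' @param path Path to the CSV file.
#' @param sidecar Optional explicit path to the YAML sidecar.
#' @return A [recording()].
#' @export
read_recording <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must have a 'time' column (seconds)")
  chans <- setdiff(names(df), "time")
  if (length(chans) == 0L) stop("CSV has no channel columns")
  if (anyDuplicated(chans)) stop("duplicate channel names in header")
  tt <- df$time
  if (length(tt) < 2L) stop("need at least 2 samples")
  if (is.unsorted(tt, strictly = TRUE)) stop("non-monotonic time column")
  d <- diff(tt)
  dt <- stats::median(d)
  if (max(abs(d - dt)) > dt / 100) stop("non-uniform sampling in time column")
  t0 <- tt[1L]

  side <- NULL
  sidecar <- sidecar %||% paste0(tools::file_path_sans_ext(path), ".yaml")
  if (file.exists(sidecar)) side <- yaml::read_yaml(sidecar)

  kinds <- side$channel_kinds %||% list()
  traces <- lapply(chans, function(ch) {
    v <- as.numeric(df[[ch]])
    bad <- which(!is.finite(v))
    if (length(bad)) {
      runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
      long <- runs[vapply(runs, length, integer(1)) > 1L]
      if (length(long)) {
        stop(sprintf("channel '%s': NaN run longer than 1 sample at index %d",
                     ch, long[[1L]][1L]))
      }
      ok <- which(is.finite(v))
      v[bad] <- stats::approx(ok, v[ok], xout = bad, rule = 2)$y
    }
    cg_trace(ch, t0, dt, v, channel_kind = kinds[[ch]] %||% "intracellular")
  })
  names(traces) <- chans

  epochs <- NULL
  if (!is.null(side$epochs)) {
    epochs <- do.call(rbind, lapply(side$epochs, function(e) {
      protocol_epoch(e$injected_cell, e$amplitude, e$t_start, e$t_end,
                     e$baseline_window %||% 0.1)
    }))
  }
  timeline <- NULL
  if (!is.null(side$condition_timeline)) {
    timeline <- do.call(rbind, lapply(side$condition_timeline, function(e) {
      data.frame(time = e$time, condition = e$condition,
                 stringsAsFactors = FALSE)
    }))
  }
  recording(traces, epochs = epochs, condition_timeline = timeline,
            metadata = side$metadata %||% list())
}

#' Write a recording to CSV (+ YAML sidecar)
#'
#' Inverse of [read_recording()]. All traces are written on the grid of the
#' first trace; traces with a different `dt` are an error (write them
#' separately). Numeric values keep full double precision (15 significant
#' digits).
#'
#' @param rec A [recording()].
#' @param path Output CSV path; the sidecar goes to the same path with
#'   extension `.yaml`.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "cg_recording"))
  tr1 <- rec$traces[[1L]]
  for (tr in rec$traces) {
    if (abs(tr$dt - tr1$dt) > 1e-15 || abs(tr$t0 - tr1$t0) > 1e-15 ||
        length(tr$samples) != length(tr1$samples)) {
      stop("write_recording requires all traces on a common grid")
    }
  }
  df <- data.frame(time = trace_times(tr1))
  for (nm in names(rec$traces)) df[[nm]] <- rec$traces[[nm]]$samples
  write_table_csv(df, path)

  side <- list(
    channel_kinds = lapply(rec$traces, function(x) x$channel_kind),
    metadata = rec$metadata
  )
  if (!is.null(rec$epochs) && nrow(rec$epochs)) {
    side$epochs <- lapply(seq_len(nrow(rec$epochs)), function(i) {
      as.list(rec$epochs[i, , drop = FALSE])
    })
  }
  if (!is.null(rec$condition_timeline) && nrow(rec$condition_timeline)) {
    side$condition_timeline <-
      lapply(seq_len(nrow(rec$condition_timeline)), function(i) {
        as.list(rec$condition_timeline[i, , drop = FALSE])
      })
  }
  yaml::write_yaml(side, paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

# CSV writer preserving >= 15 significant digits for numeric columns.
write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write named result tables to disk
#'
#' @param tables Named list of data.frames (may be empty data.frames:
#'   header-only files are written without error).
#' @param dir Output directory, created if needed.
#' @param format `"csv"` (one file per table, >= 12 significant digits kept)
#'   or `"json"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_results <- function(tables, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (format == "csv") {
      p <- file.path(dir, paste0(nm, ".csv"))
      write_table_csv(tab, p)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(tab, p, digits = NA, auto_unbox = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
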