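## Shared plain-text I/O: cohort tables with a units row, current traces,
## trajectories and event tables. All formats are CSV/JSON; 1-based indices
## and SI-with-prefix units throughout.

#' Read / write a cohort table with a units row
#'
#' The on-disk format is CSV whose second line is a units row: its first
#' cell is \code{#units} and the remaining cells give the unit of each
#' column. A UTF-8 byte-order mark is tolerated on input. A missing units
#' row, or a missing required column, is an explicit error.
#'
#' @param path CSV file path.
#' @param requiredColumns columns that must be present (default
#'   \code{c("sample_id", "group")}).
#' @return \code{readCohortTable} returns a \linkS4class{CohortTable};
#'   \code{writeCohortTable} returns \code{path} invisibly.
#' @export
readCohortTable <- function(path, requiredColumns = c("sample_id", "group")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines)) lines[1] <- sub("^﻿", "", lines[1])
  if (length(lines) < 2L || !startsWith(lines[2], "#units"))
    stop("missing units header row (second line must start with '#units')")
  tab <- utils::read.csv(text = paste(lines[-2], collapse = "\n"),
                         stringsAsFactors = FALSE)
  miss <- setdiff(requiredColumns, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ucells <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  u <- rep("", ncol(tab))
  k <- min(length(ucells), ncol(tab))
  u[seq_len(k)] <- ucells[seq_len(k)]
  u[1] <- ""  # the '#units' marker cell carries no unit
  CohortTable(tab, setNames(u, names(tab)))
}

#' @rdname readCohortTable
#' @param cohort a \linkS4class{CohortTable}.
#' @export
writeCohortTable <- function(cohort, path) {
  validObject(cohort)
  d <- cohort@data
  u <- vapply(names(d), function(nm)
    if (nm %in% names(cohort@units)) cohort@units[[nm]] else "", character(1))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(d, con, row.names = FALSE)
  close(con)
  writeLines(c(out[1],
               paste(c("#units", u[-1]), collapse = ","),
               out[-1]), path)
  invisible(path)
}

#' Read / write a nanopore current trace as CSV
#'
#' Columns \code{time_s}, \code{current_pa}; the sampling rate is inferred
#' from the (uniform) time step on read.
#'
#' @param path CSV file path.
#' @return \code{readTraceCSV} returns a \linkS4class{CurrentTrace}.
#' @export
readTraceCSV <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "current_pa") %in% names(tab)))
    stop("trace CSV needs time_s and current_pa columns")
  dt <- diff(tab$time_s)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("non-uniform sampling in trace CSV")
  CurrentTrace(tab$current_pa, 1 / dt[1])
}

#' @rdname readTraceCSV
#' @param trace a \linkS4class{CurrentTrace}.
#' @export
writeTraceCSV <- function(trace, path) {
  validObject(trace)
  utils::write.csv(
    data.frame(time_s = (seq_along(trace@current) - 1) / trace@sampleRate,
               current_pa = trace@current),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a detected-event table as CSV
#'
#' Columns: start_s, duration_us, ecd_fc, mw_kda, extrapolated.
#'
#' @param events event data.frame from \code{\link{detectEvents}}.
#' @param calib an \linkS4class{ECDCalibration} for the MW column.
#' @param sampleRate the trace sampling rate, Hz.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEventsCSV <- function(events, calib, sampleRate, path) {
  conv <- ecdToMW(events$ecd_pas, calib)
  utils::write.csv(
    data.frame(start_s = (events$start - 1) / sampleRate,
               duration_us = events$duration_s * 1e6,
               ecd_fc = events$ecd_fc, mw_kda = conv$mw_kda,
               extrapolated = conv$extrapolated),
    path, row.names = FALSE)
  invisible(path)
}

#' Read bead trajectories from CSV
#'
#' Expects columns \code{track_id}, \code{frame}, \code{x_um}, \code{y_um}
#' (optional \code{video}, \code{time_s}). The frame rate is taken from
#' \code{time_s} when present, otherwise from the \code{fps} argument.
#'
#' @param path CSV file path.
#' @param fps frame rate fallback (default 16 Hz).
#' @return A \linkS4class{TrackSet}.
#' @export
readTrajectories <- function(path, fps = 16) {
  tab <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if ("time_s" %in% names(tab)) {
    t1 <- tab[tab$track_id == tab$track_id[1], ]
    dt <- diff(sort(t1$time_s))
    if (length(dt) && all(is.finite(dt)) && dt[1] > 0) fps <- 1 / dt[1]
  }
  TrackSet(tab[need], fps)
}
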