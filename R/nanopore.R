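## Solid-state nanopore sizing: filtering, robust baseline, 5-sigma event
## detection with duration gating, ECD integration and calibration against
## quasi-monodisperse standards.

#' Zero-phase low-pass filter for a current trace
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (\code{signal::filtfilt}), so the filter is zero-phase and has unit DC
#' gain; event timing is not shifted. The standard analysis cutoff is 5 kHz.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param cutoffHz cutoff frequency (default 5000); must be below Nyquist.
#' @param order filter order (default 4).
#' @return The filtered \linkS4class{CurrentTrace}.
#' @export
lowpassFilter <- function(trace, cutoffHz = 5000, order = 4) {
  validObject(trace)
  nyq <- trace@sampleRate / 2
  if (!is.finite(cutoffHz) || cutoffHz <= 0 || cutoffHz >= nyq)
    stop(sprintf("cutoff must lie in (0, Nyquist = %g Hz)", nyq))
  bf <- signal::butter(order, cutoffHz / nyq, type = "low")
  # reflect-pad both ends so the IIR start-up transient stays outside the
  # trace (transient length ~ a few filter time constants)
  x <- trace@current
  n <- length(x)
  np <- min(n - 1L, as.integer(ceiling(20 * trace@sampleRate / cutoffHz)))
  padded <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- signal::filtfilt(bf, padded)[(np + 1L):(np + n)]
  CurrentTrace(y, trace@sampleRate, trace@metadata)
}

#' Robust baseline and noise estimate
#'
#' Median and scaled MAD (consistency constant 1.4826) of the trace. Robust
#' estimators are used rather than mean/SD so that blockade events, which can
#' occupy a few percent of the samples, barely perturb the baseline.
#'
#' @param trace a \linkS4class{CurrentTrace} with at least 1000 samples.
#' @return list with \code{baseline_pa} and \code{sigma_pa}.
#' @export
estimateBaselineSigma <- function(trace) {
  validObject(trace)
  if (length(trace@current) < 1000L)
    stop("trace too short for baseline estimation (need >= 1000 samples)")
  list(baseline_pa = stats::median(trace@current),
       sigma_pa = stats::mad(trace@current))
}

#' Detect blockade events by threshold crossing
#'
#' Flags maximal runs of consecutive samples deviating from baseline by at
#' least \code{k} standard deviations (default 5), in the configured
#' direction (default: blockades, i.e. current below baseline), then
#' discards runs whose duration falls outside the gate (default 25 us to
#' 2.5 ms). Each retained event's charge deficit (ECD) is integrated over
#' its above-threshold samples.
#'
#' Indices are 1-based and inclusive; \code{duration_s = n_samples / rate}.
#'
#' A zero-phase low-pass filter ringing at cutoff fc can push the current
#' briefly back above threshold inside a single deep translocation, with
#' rebounds of order 1/(2 fc); threshold runs separated by less than
#' \code{mergeGapS} (default 200 us, about 1/fc for the 5-kHz analysis
#' filter) are therefore merged before duration gating. Physical inter-event
#' intervals at the rates measured here are milliseconds, far above the
#' merge window. Set \code{mergeGapS = 0} to disable.
#'
#' @param trace a \linkS4class{CurrentTrace} (normally low-pass filtered).
#' @param baseline,sigma baseline current and noise SD in pA; if NULL they
#'   are estimated with \code{\link{estimateBaselineSigma}}.
#' @param k threshold in units of sigma (default 5).
#' @param dminS,dmaxS duration gate in seconds (defaults 25e-6, 2.5e-3).
#' @param mergeGapS merge threshold runs separated by less than this many
#'   seconds (default 200e-6).
#' @param direction \code{"below"} (blockade, default), \code{"above"}, or
#'   \code{"both"} (absolute deviation).
#' @return data.frame with one row per event: \code{start}, \code{end}
#'   (sample indices), \code{n_samples}, \code{duration_s}, \code{ecd_pas},
#'   \code{ecd_fc}, \code{mean_depth_pa}; sorted by start.
#' @export
detectEvents <- function(trace, baseline = NULL, sigma = NULL, k = 5,
                         dminS = 25e-6, dmaxS = 2.5e-3, mergeGapS = 200e-6,
                         direction = c("below", "above", "both")) {
  validObject(trace)
  direction <- match.arg(direction)
  if (is.null(baseline) || is.null(sigma)) {
    bs <- estimateBaselineSigma(trace)
    if (is.null(baseline)) baseline <- bs$baseline_pa
    if (is.null(sigma)) sigma <- bs$sigma_pa
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  dev <- switch(direction,
                below = baseline - trace@current,
                above = trace@current - baseline,
                both = abs(trace@current - baseline))
  over <- dev >= k * sigma
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) > 1L && mergeGapS > 0) {
    gapN <- as.integer(round(mergeGapS * trace@sampleRate))
    grp <- cumsum(c(1L, as.integer(starts[-1] - ends[-length(ends)] > gapN)))
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }
  n <- ends - starts + 1L
  dur <- n / trace@sampleRate
  ok <- dur >= dminS & dur <= dmaxS
  starts <- starts[ok]; ends <- ends[ok]; n <- n[ok]; dur <- dur[ok]
  dt <- 1 / trace@sampleRate
  ecd <- vapply(seq_along(starts), function(i)
    sum(dev[starts[i]:ends[i]]) * dt, numeric(1))
  data.frame(start = starts, end = ends, n_samples = n, duration_s = dur,
             ecd_pas = ecd, ecd_fc = ecd * 1000,
             mean_depth_pa = ifelse(n > 0, ecd / dt / n, 0))
}

#' Event charge deficit
#'
#' Integral of the absolute current deviation from baseline over the event's
#' samples: sum(|i - baseline|) * dt, in pA s (1 pA s = 1000 fC). Adding the
#' same constant to trace and baseline leaves the ECD unchanged.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param start,end 1-based inclusive sample indices of the event.
#' @param baseline baseline current in pA.
#' @return ECD in pA s.
#' @export
eventECD <- function(trace, start, end, baseline) {
  validObject(trace)
  if (start < 1L || end > length(trace@current) || start > end)
    stop("event indices outside the trace")
  sum(abs(trace@current[start:end] - baseline)) / trace@sampleRate
}

#' Fit an ECD-to-MW calibration
#'
#' Least-squares line in log-log space through the per-standard mean ECDs of
#' quasi-monodisperse standards (the reference set spans 54-2384 kDa). ECD
#' must increase strictly with MW.
#'
#' @param standards data.frame with columns \code{mw_kda} and
#'   \code{mean_ecd} (pA s).
#' @return An \linkS4class{ECDCalibration}.
#' @export
fitECDCalibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("mw_kda", "mean_ecd") %in% names(standards)))
    names(standards)[1:2] <- c("mw_kda", "mean_ecd")
  if (nrow(standards) < 2L) stop("need at least 2 calibration standards")
  if (any(standards$mw_kda <= 0) || any(standards$mean_ecd <= 0))
    stop("standards must have positive MW and ECD")
  o <- order(standards$mw_kda)
  standards <- standards[o, , drop = FALSE]
  if (any(diff(standards$mean_ecd) <= 0))
    stop("ECD must increase strictly with MW across standards")
  fit <- stats::lm(log(mw_kda) ~ log(mean_ecd), data = standards)
  new("ECDCalibration", standards = standards,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      ecdRange = range(standards$mean_ecd),
      residuals = unname(stats::residuals(fit)))
}

#' Convert ECD to molecular weight
#'
#' Applies the fitted log-log calibration line. ECDs outside the range
#' spanned by the standards are converted anyway but flagged as
#' extrapolated.
#'
#' @param ecd numeric ECD values, pA s, > 0.
#' @param calib an \linkS4class{ECDCalibration}.
#' @return data.frame with \code{mw_kda} and logical \code{extrapolated}.
#' @export
ecdToMW <- function(ecd, calib) {
  if (any(!is.finite(ecd)) || any(ecd <= 0)) stop("ECD must be positive")
  data.frame(
    mw_kda = exp(calib@intercept + calib@slope * log(ecd)),
    extrapolated = ecd < calib@ecdRange[1] | ecd > calib@ecdRange[2])
}

#' Forward calibration: expected mean ECD for a molecular weight
#'
#' Inverse of \code{\link{ecdToMW}} on the fitted line; used by the trace
#' simulator to realize events of a target MW.
#'
#' @param mwKda molecular weight in kDa.
#' @param calib an \linkS4class{ECDCalibration}.
#' @return ECD in pA s.
#' @export
mwToECD <- function(mwKda, calib) {
  exp((log(mwKda) - calib@intercept) / calib@slope)
}

#' Molecular-weight summary from detected events
#'
#' Each retained event contributes one molecule (number weighting):
#' Mn = mean(M), Mw = sum(M^2)/sum(M), PDI = Mw/Mn. The returned
#' distribution is converted to mass weighting so that
#' \code{\link{weightAverageMW}} etc. agree with these sample statistics.
#'
#' @param events event data.frame from \code{\link{detectEvents}}.
#' @param calib an \linkS4class{ECDCalibration}.
#' @return list with \code{distribution} (mass-weighted
#'   \linkS4class{MWDistribution}), \code{Mw}, \code{Mn}, \code{PDI},
#'   \code{n_events}, \code{n_extrapolated}.
#' @export
eventsToMWSummary <- function(events, calib) {
  if (is.null(events) || nrow(events) == 0L)
    stop("no retained events to summarize")
  conv <- ecdToMW(events$ecd_pas, calib)
  m <- conv$mw_kda
  mn <- mean(m)
  mw <- sum(m^2) / sum(m)
  grid <- sort(unique(m))
  counts <- as.numeric(table(factor(m, levels = grid)))
  d <- numberToMassWeights(
    MWDistribution(grid, counts, weighting = "number"))
  list(distribution = d, Mw = mw, Mn = mn, PDI = mw / mn,
       n_events = length(m), n_extrapolated = sum(conv$extrapolated))
}

#' Full nanopore sizing chain for one trace
#'
#' Low-pass filters the trace, estimates baseline and noise on the filtered
#' data, detects 5-sigma duration-gated events, and summarizes their
#' calibrated molecular weights.
#'
#' @inheritParams detectEvents
#' @param calib an \linkS4class{ECDCalibration}.
#' @param cutoffHz analysis filter cutoff (default 5000 Hz); NULL to skip
#'   filtering.
#' @return list combining the event table and the MW summary, plus the
#'   baseline estimates used.
#' @export
nanoporeMWSummary <- function(trace, calib, cutoffHz = 5000, k = 5,
                              dminS = 25e-6, dmaxS = 2.5e-3,
                              mergeGapS = 200e-6, direction = "below") {
  if (!is.null(cutoffHz)) trace <- lowpassFilter(trace, cutoffHz)
  bs <- estimateBaselineSigma(trace)
  ev <- detectEvents(trace, bs$baseline_pa, bs$sigma_pa, k = k,
                     dminS = dminS, dmaxS = dmaxS, mergeGapS = mergeGapS,
                     direction = direction)
  c(list(events = ev, baseline_pa = bs$baseline_pa, sigma_pa = bs$sigma_pa),
    eventsToMWSummary(ev, calib))
}
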