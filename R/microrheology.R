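## Passive particle-tracking microrheology: MSD, diffusion fit and
## Stokes-Einstein viscosity.

.kB <- 1.380649e-23  # J/K

#' Time- and ensemble-averaged mean-squared displacement
#'
#' For each lag, averages (dx^2 + dy^2) over all start frames of all tracks
#' (overlapping windows), weighting tracks by their number of displacement
#' pairs. Tracks must share a uniform frame interval.
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param maxLagFrames largest lag, in frames (default 20).
#' @return An \linkS4class{MSDCurve}.
#' @export
computeMSD <- function(tracks, maxLagFrames = 20) {
  validObject(tracks)
  tr <- tracks@tracks
  dt <- 1 / tracks@frameRate
  maxLagFrames <- as.integer(maxLagFrames)
  ss <- numeric(maxLagFrames)   # sum of squared displacements per lag
  np <- integer(maxLagFrames)
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, , drop = FALSE]
    t1 <- t1[order(t1$frame), , drop = FALSE]
    if (nrow(t1) < 2L) next
    if (any(diff(t1$frame) != 1L))
      stop(sprintf("track %s has missing frames", id))
    n <- nrow(t1)
    for (lag in seq_len(min(maxLagFrames, n - 1L))) {
      dx <- t1$x_um[(1L + lag):n] - t1$x_um[1:(n - lag)]
      dy <- t1$y_um[(1L + lag):n] - t1$y_um[1:(n - lag)]
      ss[lag] <- ss[lag] + sum(dx^2 + dy^2)
      np[lag] <- np[lag] + (n - lag)
    }
  }
  keep <- np > 0L
  if (!any(keep)) stop("no displacement pairs available")
  new("MSDCurve", lagS = (seq_len(maxLagFrames) * dt)[keep],
      msdUm2 = (ss / pmax(np, 1L))[keep], nPairs = np[keep])
}

#' Fit a diffusion coefficient from an MSD curve
#'
#' Weighted least-squares line msd = 4 D tau + b over the configured lags,
#' weights proportional to the pair count per lag. The intercept b absorbs
#' static localization noise. A non-positive fitted D is flagged and no
#' viscosity should be derived from it.
#'
#' @param msd an \linkS4class{MSDCurve}.
#' @param cfg a \linkS4class{RheologyConfig}; its \code{fitLags} selects the
#'   lag indices used.
#' @return list with \code{D_um2_per_s}, \code{intercept_um2}, \code{ok}
#'   (FALSE when D <= 0 or the fit is degenerate) and \code{n_lags}.
#' @export
fitDiffusion <- function(msd, cfg = RheologyConfig()) {
  validObject(msd); validObject(cfg)
  idx <- cfg@fitLags[cfg@fitLags <= length(msd@lagS)]
  if (length(idx) < 2L)
    return(list(D_um2_per_s = NA_real_, intercept_um2 = NA_real_,
                ok = FALSE, n_lags = length(idx)))
  x <- msd@lagS[idx]; y <- msd@msdUm2[idx]; w <- as.numeric(msd@nPairs[idx])
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  list(D_um2_per_s = slope / 4, intercept_um2 = unname(stats::coef(fit)[1]),
       ok = is.finite(slope) && slope > 0, n_lags = length(idx))
}

#' Viscosity from a diffusion coefficient (Stokes-Einstein)
#'
#' eta = kB T / (6 pi r D) for a sphere of radius r; returned in centipoise
#' (1 cP = 1 mPa s). Halving D exactly doubles eta.
#'
#' @param D diffusion coefficient in um^2/s, > 0.
#' @param cfg a \linkS4class{RheologyConfig} supplying T and bead radius.
#' @return viscosity in cP.
#' @examples
#' viscosityFromDiffusion(0.864)  # ~1 cP: water at 22 C, 0.5-um bead
#' @export
viscosityFromDiffusion <- function(D, cfg = RheologyConfig()) {
  validObject(cfg)
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be > 0")
  etaPaS <- .kB * cfg@temperatureK /
    (6 * pi * cfg@beadRadiusUm * 1e-6 * D * 1e-12)
  etaPaS * 1000
}

#' Synovial-fluid viscosity pipeline
#'
#' Runs MSD -> diffusion -> Stokes-Einstein per video (if a \code{video}
#' column is present) and pooled across all tracks, with a QC report of
#' track counts and fit diagnostics. The standard acquisition is three 30-s
#' videos per sample at 16 Hz with roughly 15 beads in frame.
#'
#' @param tracks a \linkS4class{TrackSet} or a data.frame of track points.
#' @param cfg a \linkS4class{RheologyConfig}.
#' @param maxLagFrames largest MSD lag in frames (default 20).
#' @return list with \code{viscosity_cp} (pooled estimate, NA when the fit
#'   failed), \code{D_um2_per_s}, \code{perVideo} data.frame, and \code{qc}
#'   (track/point counts, intercept, flags). Samples with a single short
#'   track still run but carry a wide-uncertainty flag.
#' @export
sfViscosityPipeline <- function(tracks, cfg = RheologyConfig(),
                                maxLagFrames = 20) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  validObject(tracks)
  tr <- tracks@tracks
  runOne <- function(sub) {
    ts <- TrackSet(sub, tracks@frameRate)
    msd <- computeMSD(ts, maxLagFrames)
    fit <- fitDiffusion(msd, cfg)
    eta <- if (fit$ok) viscosityFromDiffusion(fit$D_um2_per_s, cfg) else NA_real_
    list(eta = eta, fit = fit, msd = msd)
  }
  pooled <- runOne(tr)
  perVideo <- NULL
  if ("video" %in% names(tr)) {
    perVideo <- do.call(rbind, lapply(split(tr, tr$video), function(sub) {
      r <- tryCatch(runOne(sub), error = function(e) NULL)
      data.frame(video = sub$video[1],
                 n_tracks = length(unique(sub$track_id)),
                 D_um2_per_s = if (is.null(r)) NA_real_ else r$fit$D_um2_per_s,
                 viscosity_cp = if (is.null(r)) NA_real_ else r$eta)
    }))
    rownames(perVideo) <- NULL
  }
  nTracks <- length(unique(tr$track_id))
  nPairs <- sum(pooled$msd@nPairs)
  flags <- character()
  if (!pooled$fit$ok) flags <- c(flags, "nonpositive_D")
  if (nTracks < 5L || nPairs < 200L) flags <- c(flags, "wide_uncertainty")
  list(viscosity_cp = pooled$eta, D_um2_per_s = pooled$fit$D_um2_per_s,
       perVideo = perVideo,
       qc = list(n_tracks = nTracks, n_points = nrow(tr),
                 n_pairs = nPairs,
                 intercept_um2 = pooled$fit$intercept_um2,
                 fit_ok = pooled$fit$ok, flags = flags))
}
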