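## Gel densitometry: background subtraction, ladder calibration and
## conversion of lane profiles to molecular-weight distributions.

#' Rolling-ball background subtraction for a lane profile
#'
#' Estimates the baseline as a morphological opening of the intensity profile
#' (grey erosion followed by dilation) and subtracts it. The default
#' structuring element is the classical ball of the given radius; a flat
#' element (plain min/max filtering) is also available. The opening never
#' exceeds the signal, so the subtracted profile is non-negative, and a
#' constant offset added to the input leaves the output unchanged.
#'
#' @param profile a \linkS4class{LaneProfile}. Distances are assumed to be on
#'   a unit pixel grid; the radius is in pixels.
#' @param radius ball radius in pixels (default 50).
#' @param shape \code{"ball"} (default) or \code{"flat"} structuring element.
#' @return A background-subtracted \linkS4class{LaneProfile}.
#' @export
rollingBallBackground <- function(profile, radius = 50,
                                  shape = c("ball", "flat")) {
  validObject(profile)
  shape <- match.arg(shape)
  if (!is.finite(radius) || radius < 1) stop("radius must be >= 1 pixel")
  x <- profile@intensity
  n <- length(x)
  r <- as.integer(round(radius))
  js <- seq.int(-r, r)
  s <- if (shape == "ball") sqrt(pmax(0, radius^2 - js^2)) else rep(0, length(js))

  shiftVec <- function(v, j, fill) {
    # v[i + j] with out-of-range positions set to fill
    if (j == 0L) return(v)
    if (abs(j) >= n) return(rep(fill, n))
    if (j > 0L) c(v[(1L + j):n], rep(fill, j)) else c(rep(fill, -j), v[1:(n + j)])
  }
  ero <- rep(Inf, n)
  for (k in seq_along(js))
    ero <- pmin(ero, shiftVec(x, js[k], Inf) - s[k])
  opened <- rep(-Inf, n)
  for (k in seq_along(js))
    opened <- pmax(opened, shiftVec(ero, -js[k], -Inf) + s[k])
  LaneProfile(profile@distancePx, pmax(0, x - opened))
}

#' Extract a lane profile from a grayscale gel image
#'
#' Aggregates the lane's columns row-wise (mean by default) into a 1-D
#' densitometric profile. The distance axis is the row index relative to the
#' configured well row (0 at the well, increasing toward the gel front).
#' Images follow the dark-background convention (signal = high intensity);
#' set \code{invert = TRUE} for light-background scans.
#'
#' @param image numeric matrix (rows = migration direction).
#' @param laneBounds integer length-2, first and last column of the lane.
#' @param wellRow row index of the well (default 1).
#' @param aggregate \code{"mean"} (default) or \code{"sum"} across columns.
#' @param invert logical; if TRUE intensities are flipped (max - value).
#' @return A \linkS4class{LaneProfile}.
#' @export
extractLaneProfile <- function(image, laneBounds, wellRow = 1,
                               aggregate = c("mean", "sum"), invert = FALSE) {
  aggregate <- match.arg(aggregate)
  if (!is.matrix(image) || !nrow(image) || !ncol(image))
    stop("image must be a non-empty matrix")
  lb <- as.integer(laneBounds)
  if (length(lb) != 2L || lb[1] > lb[2] || lb[1] < 1L || lb[2] > ncol(image))
    stop("lane bounds outside image")
  if (wellRow < 1L || wellRow > nrow(image)) stop("well row outside image")
  sub <- image[wellRow:nrow(image), lb[1]:lb[2], drop = FALSE]
  if (invert) sub <- max(sub) - sub
  prof <- if (aggregate == "mean") rowMeans(sub) else rowSums(sub)
  LaneProfile(seq_len(nrow(sub)) - 1, prof)
}

#' Read a grayscale gel image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path image file path.
#' @return numeric matrix of intensities.
#' @export
readGelImage <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else stop("unsupported image format (use TIFF or PNG): ", path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Fit a gel ladder calibration
#'
#' Piecewise-linear interpolation of log10(MW) versus migration distance
#' through the ladder anchors; exact at every anchor and monotone by
#' construction. MW must be strictly decreasing with distance (larger chains
#' migrate less), otherwise an error names the offending anchor pair.
#'
#' @param anchors data.frame with columns \code{band_px} and \code{mw_kda}
#'   (or a 2-column matrix in that order).
#' @return A \linkS4class{GelCalibration}.
#' @examples
#' cal <- fitGelCalibration(data.frame(band_px = c(100, 200),
#'                                     mw_kda = c(1000, 100)))
#' predictMW(cal, 150)  # 10^2.5 = 316.2 kDa
#' @export
fitGelCalibration <- function(anchors) {
  anchors <- as.data.frame(anchors)
  if (ncol(anchors) < 2L) stop("anchors need band_px and mw_kda columns")
  if (!all(c("band_px", "mw_kda") %in% names(anchors)))
    names(anchors)[1:2] <- c("band_px", "mw_kda")
  if (nrow(anchors) < 2L) stop("need at least 2 ladder anchors")
  o <- order(anchors$band_px)
  new("GelCalibration", anchorPx = as.numeric(anchors$band_px[o]),
      anchorKda = as.numeric(anchors$mw_kda[o]))
}

#' Map migration distance to molecular weight
#'
#' Interpolates the fitted calibration; queries outside the anchor range
#' return NA (extrapolated MW beyond the ladder is unreliable and such
#' pixels are excluded downstream).
#'
#' @param calib a \linkS4class{GelCalibration}.
#' @param px numeric migration distances in pixels.
#' @return numeric MW in kDa, NA outside the calibrated range.
#' @export
predictMW <- function(calib, px) {
  validObject(calib)
  10^stats::approx(calib@anchorPx, log10(calib@anchorKda), xout = px,
                   rule = 1)$y
}

#' Inverse calibration: molecular weight to migration distance
#'
#' @param calib a \linkS4class{GelCalibration}.
#' @param mwKda numeric MW in kDa.
#' @return migration distance in pixels, NA outside the anchor MW range.
#' @export
predictMigration <- function(calib, mwKda) {
  validObject(calib)
  # log10(MW) is strictly decreasing in px, so the inverse is single-valued
  stats::approx(log10(calib@anchorKda), calib@anchorPx, xout = log10(mwKda),
                rule = 1)$y
}

#' Convert a background-subtracted lane profile to an MW distribution
#'
#' Each pixel inside the calibrated range contributes its intensity as mass
#' weight at the calibrated MW. Pixels outside the ladder range are excluded
#' and their intensity fraction reported rather than extrapolated.
#'
#' @param profile a background-subtracted \linkS4class{LaneProfile}.
#' @param calib a \linkS4class{GelCalibration}.
#' @return list with \code{distribution} (mass-weighted
#'   \linkS4class{MWDistribution}) and \code{excludedFraction} (intensity
#'   fraction outside the calibrated range).
#' @export
laneToMWDist <- function(profile, calib) {
  validObject(profile); validObject(calib)
  mw <- predictMW(calib, profile@distancePx)
  inRange <- !is.na(mw)
  total <- sum(profile@intensity)
  if (total <= 0) stop("lane has zero total intensity")
  inTotal <- sum(profile@intensity[inRange])
  if (inTotal <= 0) stop("zero total intensity inside the calibrated range")
  keep <- inRange & profile@intensity > 0
  o <- order(mw[keep])
  list(distribution = MWDistribution(mw[keep][o], profile@intensity[keep][o],
                                     weighting = "mass"),
       excludedFraction = 1 - inTotal / total)
}

#' Gel molecular-weight summary
#'
#' Full densitometric chain for one lane: optional rolling-ball background
#' subtraction, calibration mapping, and Mw/Mn/PDI summary.
#'
#' @param profile a \linkS4class{LaneProfile} (raw, or already
#'   background-subtracted if \code{ballRadius = NULL}).
#' @param calib a \linkS4class{GelCalibration}.
#' @param ballRadius rolling-ball radius in px, or NULL to skip background
#'   subtraction.
#' @param noiseFloor absolute intensity below which pixels are zeroed after
#'   background subtraction (default 0). Residual read noise spread along
#'   the whole lane otherwise leaks weight into the extreme MW bins. Note
#'   that an opening-type background estimate rides along the lower envelope
#'   of the noise, so after subtraction the noise floor sits several noise
#'   SDs above zero; a floor near 6x the per-pixel noise SD suppresses it.
#' @return list with \code{Mw}, \code{Mn}, \code{PDI} (kDa, kDa,
#'   dimensionless) and \code{excludedFraction}.
#' @export
gelMWSummary <- function(profile, calib, ballRadius = NULL, noiseFloor = 0) {
  if (!is.null(ballRadius))
    profile <- rollingBallBackground(profile, ballRadius)
  if (noiseFloor > 0) {
    int <- profile@intensity
    int[int < noiseFloor] <- 0
    profile <- LaneProfile(profile@distancePx, int)
  }
  res <- laneToMWDist(profile, calib)
  d <- res$distribution
  list(Mw = weightAverageMW(d), Mn = numberAverageMW(d),
       PDI = polydispersity(d), excludedFraction = res$excludedFraction)
}
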