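#' @import methods
NULL

#' Discretized molecular-weight distribution
#'
#' Container for a polymer molecular-weight distribution sampled on a discrete
#' mass grid. Weights are abundances per grid point; the \code{weighting} slot
#' records whether they are mass-proportional (stain intensity, mass per grid
#' slice) or number-proportional (molecule counts, e.g. one per nanopore
#' event). All summary statistics (\code{\link{weightAverageMW}},
#' \code{\link{numberAverageMW}}, \code{\link{polydispersity}}) require mass
#' weighting; convert number-weighted data first with
#' \code{\link{numberToMassWeights}}.
#'
#' @slot masses numeric, kDa, strictly positive and strictly ascending.
#' @slot weights numeric, non-negative, same length as \code{masses}, at
#'   least one positive entry.
#' @slot weighting character, \code{"mass"} or \code{"number"}.
#'
#' @seealso [MWDistribution()] for the constructor.
#' @exportClass MWDistribution
setClass("MWDistribution",
  representation(masses = "numeric", weights = "numeric",
                 weighting = "character"),
  prototype(weighting = "mass"))

setValidity("MWDistribution", function(object) {
  m <- object@masses; w <- object@weights
  if (length(m) == 0L) return("empty mass grid")
  if (length(m) != length(w)) return("masses and weights differ in length")
  if (!all(is.finite(m)) || !all(is.finite(w)))
    return("masses and weights must be finite")
  if (any(m <= 0)) return("all masses must be > 0")
  if (is.unsorted(m, strictly = TRUE)) return("masses must be strictly ascending")
  if (any(w < 0)) return("weights must be non-negative")
  if (sum(w) <= 0) return("at least one weight must be positive")
  if (!object@weighting %in% c("mass", "number"))
    return("weighting must be 'mass' or 'number'")
  TRUE
})

#' Construct an MWDistribution
#'
#' @param masses numeric vector of molecular weights, ascending. Interpreted
#'   in kDa by default; set \code{units = "Da"} to convert on input.
#' @param weights numeric vector of abundances (mass- or number-proportional).
#' @param weighting \code{"mass"} (default) or \code{"number"}.
#' @param units \code{"kDa"} (default) or \code{"Da"}; masses are stored in kDa.
#' @return An \linkS4class{MWDistribution}.
#' @examples
#' d <- MWDistribution(c(100, 300), c(1, 1))
#' weightAverageMW(d)   # 200
#' polydispersity(d)    # 4/3
#' @export
MWDistribution <- function(masses, weights, weighting = c("mass", "number"),
                           units = c("kDa", "Da")) {
  weighting <- match.arg(weighting)
  units <- match.arg(units)
  if (units == "Da") masses <- masses / 1000
  new("MWDistribution", masses = as.numeric(masses),
      weights = as.numeric(weights), weighting = weighting)
}

setMethod("show", "MWDistribution", function(object) {
  cat(sprintf("MWDistribution (%s-weighted), %d grid points, %.3g-%.3g kDa\n",
              object@weighting, length(object@masses),
              min(object@masses), max(object@masses)))
  if (object@weighting == "mass") {
    cat(sprintf("  Mw = %.4g kDa, Mn = %.4g kDa, PDI = %.3f\n",
                weightAverageMW(object), numberAverageMW(object),
                polydispersity(object)))
  }
})

#' Densitometric lane profile
#'
#' One-dimensional stain intensity versus migration distance for a single gel
#' lane, distances in pixels from the well, increasing toward the gel front.
#'
#' @slot distancePx numeric, pixels from the well, strictly ascending, >= 0.
#' @slot intensity numeric, arbitrary absorbance units, same length.
#' @exportClass LaneProfile
setClass("LaneProfile",
  representation(distancePx = "numeric", intensity = "numeric"))

setValidity("LaneProfile", function(object) {
  d <- object@distancePx; i <- object@intensity
  if (length(d) == 0L) return("empty profile")
  if (length(d) != length(i)) return("distance and intensity differ in length")
  if (any(!is.finite(d)) || any(!is.finite(i))) return("non-finite values")
  if (any(d < 0)) return("distances must be >= 0")
  if (is.unsorted(d, strictly = TRUE))
    return("distances must be strictly ascending")
  TRUE
})

#' @rdname LaneProfile-class
#' @param distancePx,intensity numeric vectors of equal length.
#' @return A \linkS4class{LaneProfile}.
#' @export
LaneProfile <- function(distancePx, intensity) {
  new("LaneProfile", distancePx = as.numeric(distancePx),
      intensity = as.numeric(intensity))
}

setMethod("show", "LaneProfile", function(object) {
  cat(sprintf("LaneProfile: %d px (%g-%g), total intensity %.4g\n",
              length(object@distancePx), min(object@distancePx),
              max(object@distancePx), sum(object@intensity)))
})

#' Gel ladder calibration
#'
#' Monotone map from migration distance (px) to log10 molecular weight (kDa),
#' piecewise linear through the ladder anchors. Molecular weight must be
#' strictly decreasing with migration distance.
#'
#' @slot anchorPx numeric, ladder band migration distances, ascending.
#' @slot anchorKda numeric, ladder band molecular weights, strictly
#'   decreasing along \code{anchorPx}.
#' @exportClass GelCalibration
setClass("GelCalibration",
  representation(anchorPx = "numeric", anchorKda = "numeric"))

setValidity("GelCalibration", function(object) {
  px <- object@anchorPx; mw <- object@anchorKda
  if (length(px) < 2L) return("need at least 2 ladder anchors")
  if (length(px) != length(mw)) return("anchor vectors differ in length")
  if (any(mw <= 0)) return("anchor MW must be > 0")
  if (is.unsorted(px, strictly = TRUE))
    return("anchor distances must be strictly ascending")
  bad <- which(diff(mw) >= 0)
  if (length(bad))
    return(sprintf(
      "MW must decrease with migration distance; violated between anchors %d (%g kDa at %g px) and %d (%g kDa at %g px)",
      bad[1], mw[bad[1]], px[bad[1]], bad[1] + 1L, mw[bad[1] + 1L],
      px[bad[1] + 1L]))
  TRUE
})

setMethod("show", "GelCalibration", function(object) {
  cat(sprintf("GelCalibration: %d anchors, %g-%g px, %.4g-%.4g kDa\n",
              length(object@anchorPx), min(object@anchorPx),
              max(object@anchorPx), max(object@anchorKda),
              min(object@anchorKda)))
})

#' Nanopore current trace
#'
#' Uniformly sampled ionic-current recording from a solid-state nanopore, in
#' pA, with its sampling rate.
#'
#' @slot current numeric, pA per sample, finite.
#' @slot sampleRate numeric, Hz (> 0); 200 kHz is the standard acquisition
#'   rate for these measurements.
#' @slot metadata list, free-form (e.g. applied-voltage polarity note).
#' @exportClass CurrentTrace
setClass("CurrentTrace",
  representation(current = "numeric", sampleRate = "numeric",
                 metadata = "list"),
  prototype(sampleRate = 2e5, metadata = list()))

setValidity("CurrentTrace", function(object) {
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    return("sampleRate must be a single positive number")
  if (length(object@current) == 0L) return("empty trace")
  if (any(!is.finite(object@current))) return("trace contains non-finite samples")
  TRUE
})

#' @rdname CurrentTrace-class
#' @param current numeric vector of samples (pA).
#' @param sampleRate sampling rate in Hz.
#' @param metadata optional list of acquisition notes.
#' @return A \linkS4class{CurrentTrace}.
#' @export
CurrentTrace <- function(current, sampleRate = 2e5, metadata = list()) {
  new("CurrentTrace", current = as.numeric(current),
      sampleRate = as.numeric(sampleRate), metadata = metadata)
}

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples @ %g kHz (%.3f s)\n",
              length(object@current), object@sampleRate / 1000,
              length(object@current) / object@sampleRate))
})

#' ECD-to-molecular-weight calibration
#'
#' Log-log linear map between event charge deficit (ECD, pA s) and molecular
#' weight (kDa), least-squares fitted to quasi-monodisperse standards. ECD
#' must increase strictly with MW across the standards.
#'
#' @slot standards data.frame with columns \code{mw_kda}, \code{mean_ecd}.
#' @slot intercept,slope numeric; log(MW) = intercept + slope * log(ECD).
#' @slot ecdRange numeric length-2, ECD range spanned by the standards;
#'   conversions outside it are flagged as extrapolated.
#' @slot residuals numeric, log-MW fit residuals per standard.
#' @exportClass ECDCalibration
setClass("ECDCalibration",
  representation(standards = "data.frame", intercept = "numeric",
                 slope = "numeric", ecdRange = "numeric",
                 residuals = "numeric"))

setMethod("show", "ECDCalibration", function(object) {
  cat(sprintf(
    "ECDCalibration: %d standards, log(MW) = %.4g + %.4g log(ECD), ECD range [%.3g, %.3g] pA s\n",
    nrow(object@standards), object@intercept, object@slope,
    object@ecdRange[1], object@ecdRange[2]))
})

#' Bead trajectory set
#'
#' Two-dimensional tracer-bead trajectories at a uniform frame rate, as used
#' in passive particle-tracking microrheology. Positions in micrometres.
#'
#' @slot tracks data.frame with columns \code{track_id}, \code{frame}
#'   (integer, consecutive within a track), \code{x_um}, \code{y_um}, and
#'   optionally \code{video}.
#' @slot frameRate numeric, frames per second (default 16).
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "data.frame", frameRate = "numeric"),
  prototype(frameRate = 16))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tr))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(tr) == 0L) return("no track points")
  if (object@frameRate <= 0) return("frameRate must be > 0")
  n <- tapply(tr$frame, tr$track_id, length)
  if (all(n < 2L)) return("no track has >= 2 points")
  TRUE
})

#' @rdname TrackSet-class
#' @param tracks data.frame of track points (see slots).
#' @param frameRate acquisition rate, Hz.
#' @return A \linkS4class{TrackSet}.
#' @export
TrackSet <- function(tracks, frameRate = 16) {
  new("TrackSet", tracks = as.data.frame(tracks), frameRate = frameRate)
}

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks, %d points @ %g Hz\n",
              length(unique(object@tracks$track_id)), nrow(object@tracks),
              object@frameRate))
})

#' Mean-squared displacement curve
#'
#' Time- and ensemble-averaged 2-D MSD versus lag time, with the number of
#' displacement pairs contributing at each lag.
#'
#' @slot lagS numeric, lag times in seconds, ascending.
#' @slot msdUm2 numeric, MSD in um^2, >= 0.
#' @slot nPairs integer, displacement pairs per lag, > 0.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(lagS = "numeric", msdUm2 = "numeric", nPairs = "integer"))

setValidity("MSDCurve", function(object) {
  if (length(object@lagS) == 0L) return("empty MSD curve")
  if (length(object@lagS) != length(object@msdUm2) ||
      length(object@lagS) != length(object@nPairs))
    return("slot lengths differ")
  if (is.unsorted(object@lagS, strictly = TRUE)) return("lags must ascend")
  if (any(object@msdUm2 < 0)) return("MSD must be >= 0")
  if (any(object@nPairs <= 0L)) return("pair counts must be > 0")
  TRUE
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags, %.4g-%.4g s\n", length(object@lagS),
              min(object@lagS), max(object@lagS)))
})

#' Microrheology configuration
#'
#' Physical constants and fit settings for converting bead diffusion into
#' viscosity via Stokes-Einstein.
#'
#' @slot temperatureK numeric, absolute temperature (default 295.15 K, 22 C).
#' @slot beadRadiusUm numeric, tracer bead radius (default 0.25 um, i.e. the
#'   0.5-um FluoSpheres product).
#' @slot fitLags integer, MSD lag indices used in the diffusion fit
#'   (default 1:8, i.e. 0.0625-0.5 s at 16 Hz).
#' @exportClass RheologyConfig
setClass("RheologyConfig",
  representation(temperatureK = "numeric", beadRadiusUm = "numeric",
                 fitLags = "integer"),
  prototype(temperatureK = 295.15, beadRadiusUm = 0.25, fitLags = 1:8))

setValidity("RheologyConfig", function(object) {
  if (object@temperatureK <= 0) return("temperature must be > 0 K")
  if (object@beadRadiusUm <= 0) return("bead radius must be > 0")
  if (length(object@fitLags) < 2L) return("need >= 2 fit lags")
  TRUE
})

#' @rdname RheologyConfig-class
#' @param temperatureK absolute temperature, K.
#' @param beadRadiusUm bead radius, um.
#' @param fitLags lag indices for the MSD line fit.
#' @return A \linkS4class{RheologyConfig}.
#' @export
RheologyConfig <- function(temperatureK = 295.15, beadRadiusUm = 0.25,
                           fitLags = 1:8) {
  new("RheologyConfig", temperatureK = temperatureK,
      beadRadiusUm = beadRadiusUm, fitLags = as.integer(fitLags))
}

#' Five-parameter logistic standard curve
#'
#' The immunoassay calibration model y = a + b / (1 + (x/c)^d)^f, as used for
#' multiplex bead-assay standard curves.
#'
#' @slot coefficients named numeric (a, b, c, d, f); c > 0.
#' @slot convergence list of fit diagnostics (residual sum of squares,
#'   iterations, convergence message).
#' @exportClass FiveParamLogistic
setClass("FiveParamLogistic",
  representation(coefficients = "numeric", convergence = "list"))

setValidity("FiveParamLogistic", function(object) {
  cf <- object@coefficients
  if (!all(c("a", "b", "c", "d", "f") %in% names(cf)))
    return("coefficients must be named a, b, c, d, f")
  if (cf[["c"]] <= 0) return("c must be > 0")
  TRUE
})

setMethod("show", "FiveParamLogistic", function(object) {
  cf <- object@coefficients
  cat(sprintf("5PL curve: y = %.4g + %.4g / (1 + (x/%.4g)^%.4g)^%.4g\n",
              cf["a"], cf["b"], cf["c"], cf["d"], cf["f"]))
})

#' Cohort measurement table
#'
#' Per-sample, per-group measurements with recorded units, consumed by the
#' statistical stage.
#'
#' @slot data data.frame with \code{sample_id}, \code{group} and numeric
#'   measurement columns.
#' @slot units named character, unit per measurement column.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(data = "data.frame", units = "character"))

setValidity("CohortTable", function(object) {
  d <- object@data
  if (!all(c("sample_id", "group") %in% names(d)))
    return("data needs sample_id and group columns")
  if (nrow(d) == 0L) return("empty cohort table")
  TRUE
})

#' @rdname CohortTable-class
#' @param data data.frame of per-sample measurements.
#' @param units named character vector of units, one per measurement column
#'   (missing columns get "").
#' @return A \linkS4class{CohortTable}.
#' @export
CohortTable <- function(data, units = character()) {
  meas <- setdiff(names(data), c("sample_id", "group"))
  u <- setNames(rep("", length(meas)), meas)
  u[names(units)[names(units) %in% meas]] <-
    units[names(units) %in% meas]
  new("CohortTable", data = as.data.frame(data), units = u)
}

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d samples (%s), %d measurement columns\n",
              nrow(object@data),
              paste(sprintf("%s n=%d", names(table(object@data$group)),
                            as.integer(table(object@data$group))),
                    collapse = ", "),
              length(object@units)))
})
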