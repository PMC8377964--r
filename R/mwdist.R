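## Molecular-weight distribution summaries.
##
## Weights are interpreted as mass per grid slice (stain intensity is
## mass-proportional); no Jacobian correction is applied when the slices are
## pixels — the analysis treats each pixel's intensity as the mass it carries.

.assertMassWeighted <- function(d) {
  validObject(d)
  if (d@weighting != "mass")
    stop("distribution is number-weighted; convert with numberToMassWeights() first")
  invisible(d)
}

#' @describeIn weightAverageMW Mw of a mass-weighted distribution:
#'   sum(w*M)/sum(w). Invariant to uniform rescaling of the weights.
#' @export
setMethod("weightAverageMW", "MWDistribution", function(x, ...) {
  .assertMassWeighted(x)
  sum(x@weights * x@masses) / sum(x@weights)
})

#' @describeIn numberAverageMW Mn of a mass-weighted distribution:
#'   sum(w)/sum(w/M).
#' @export
setMethod("numberAverageMW", "MWDistribution", function(x, ...) {
  .assertMassWeighted(x)
  sum(x@weights) / sum(x@weights / x@masses)
})

#' @describeIn polydispersity PDI = Mw/Mn; >= 1 by the Cauchy-Schwarz
#'   inequality, with equality iff a single mass carries all weight.
#' @export
setMethod("polydispersity", "MWDistribution", function(x, ...) {
  weightAverageMW(x) / numberAverageMW(x)
})

#' @export
setMethod("massGrid", "MWDistribution", function(x) x@masses)

#' @export
setMethod("distWeights", "MWDistribution", function(x) x@weights)

#' @export
setMethod("weighting", "MWDistribution", function(x) x@weighting)

#' Convert a number-weighted distribution to mass weighting
#'
#' Nanopore events are counted per molecule (number weighting); stain
#' intensity is proportional to mass. The conversion is w_i = n_i * M_i up to
#' normalization, so Mw/Mn computed from the converted distribution equal the
#' event-sample statistics sum(M^2)/sum(M) and mean(M).
#'
#' @param d a number-weighted \linkS4class{MWDistribution}.
#' @return The mass-weighted equivalent.
#' @export
numberToMassWeights <- function(d) {
  validObject(d)
  if (d@weighting == "mass") return(d)
  MWDistribution(d@masses, d@weights * d@masses, weighting = "mass")
}

#' Mass of a molecular complex
#'
#' Sum of component masses, e.g. one heavy chain (75 kDa) plus a 150-kDa HA
#' chain gives the 225-kDa HC-HA complex.
#'
#' @param componentMasses numeric vector of positive masses (kDa).
#' @return total mass in kDa.
#' @examples
#' complexMass(c(75, 150))  # 225
#' @export
complexMass <- function(componentMasses) {
  if (length(componentMasses) == 0L) stop("no component masses given")
  if (any(!is.finite(componentMasses)) || any(componentMasses <= 0))
    stop("component masses must be positive and finite")
  sum(componentMasses)
}

#' Write / read an MWDistribution as CSV
#'
#' Plain CSV with columns \code{mass_kda}, \code{weight}, preceded by a
#' comment line recording the weighting mode
#' (\code{# weighting: mass}).
#'
#' @param d an \linkS4class{MWDistribution}.
#' @param path file path.
#' @return \code{writeMWDistribution} returns \code{path} invisibly;
#'   \code{readMWDistribution} returns the \linkS4class{MWDistribution}.
#' @export
writeMWDistribution <- function(d, path) {
  validObject(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weighting: %s", d@weighting), con)
  utils::write.csv(data.frame(mass_kda = d@masses, weight = d@weights),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMWDistribution
#' @export
readMWDistribution <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- "mass"
  if (grepl("^#\\s*weighting:", first))
    mode <- trimws(sub("^#\\s*weighting:", "", first))
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("mass_kda", "weight") %in% names(tab)))
    stop("expected columns mass_kda and weight")
  MWDistribution(tab$mass_kda, tab$weight, weighting = mode)
}
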