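#' Weight-average molecular weight
#'
#' @param x an object holding a molecular-weight distribution.
#' @param ... further arguments for methods.
#' @return Mw in kDa.
#' @export
setGeneric("weightAverageMW", function(x, ...) standardGeneric("weightAverageMW"))

#' Number-average molecular weight
#'
#' @inheritParams weightAverageMW
#' @return Mn in kDa.
#' @export
setGeneric("numberAverageMW", function(x, ...) standardGeneric("numberAverageMW"))

#' Polydispersity index (Mw/Mn)
#'
#' @inheritParams weightAverageMW
#' @return dimensionless PDI, always >= 1 for a valid distribution.
#' @export
setGeneric("polydispersity", function(x, ...) standardGeneric("polydispersity"))

#' Mass grid accessor
#' @param x an \linkS4class{MWDistribution}.
#' @return numeric vector of masses (kDa).
#' @export
setGeneric("massGrid", function(x) standardGeneric("massGrid"))

#' Distribution weights accessor
#' @param x an \linkS4class{MWDistribution}.
#' @return numeric vector of weights.
#' @export
setGeneric("distWeights", function(x) standardGeneric("distWeights"))

#' Weighting mode accessor
#' @param x an \linkS4class{MWDistribution}.
#' @return \code{"mass"} or \code{"number"}.
#' @export
setGeneric("weighting", function(x) standardGeneric("weighting"))
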