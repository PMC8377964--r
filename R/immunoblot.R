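## HC-HA quantification from paired immunoblot band densities.
##
## Each sample is run undigested (lane "-", endogenous free HC) and
## hyaluronidase-digested (lane "+", endogenous HC plus HA-bound HC released
## by digestion). HC bands are normalized to the Pre-IaI band of the SAME
## lane; the HA-bound fraction is the difference of the two normalized
## values.

#' HC-HA relative absorbance for one lane pair
#'
#' a.u. = HC(+)/PreIaI(+) - HC(-)/PreIaI(-). Negative values (digestion or
#' loading noise) are retained, not clamped; group summaries use medians,
#' which are robust to them.
#'
#' @param hcMinus,preiaiMinus band densities in the undigested lane.
#' @param hcPlus,preiaiPlus band densities in the digested lane.
#' @return HC-HA relative absorbance (a.u.).
#' @examples
#' hchaAU(0.3, 1, 0.8, 1)        # 0.5
#' hchaAU(0.2, 0.5, 0.9, 0.6)    # 1.5 - 0.4 = 1.1
#' @export
hchaAU <- function(hcMinus, preiaiMinus, hcPlus, preiaiPlus) {
  vals <- c(hcMinus, preiaiMinus, hcPlus, preiaiPlus)
  if (any(!is.finite(vals))) stop("band densities must be finite")
  if (any(c(hcMinus, hcPlus) < 0)) stop("HC densities must be >= 0")
  if (preiaiMinus <= 0)
    stop("non-positive Pre-IaI density in the undigested ('-') lane")
  if (preiaiPlus <= 0)
    stop("non-positive Pre-IaI density in the digested ('+') lane")
  hcPlus / preiaiPlus - hcMinus / preiaiMinus
}

#' Batch HC-HA quantification with group summaries
#'
#' Applies \code{\link{hchaAU}} per row; rows that fail (e.g. a zero Pre-IaI
#' band) are flagged with the error message and get NA rather than aborting
#' the batch. Group medians and IQRs are computed on the valid rows.
#'
#' @param pairs data.frame with columns \code{sample_id}, \code{group},
#'   \code{hc_minus}, \code{preiai_minus}, \code{hc_plus}, \code{preiai_plus}.
#' @return list with \code{perSample} (input + \code{hcha_au},
#'   \code{negative}, \code{flag}) and \code{groupSummary} (median, IQR, n
#'   per group).
#' @export
batchHCHA <- function(pairs) {
  need <- c("sample_id", "hc_minus", "preiai_minus", "hc_plus", "preiai_plus")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  au <- rep(NA_real_, nrow(pairs))
  flag <- rep("", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- tryCatch(
      hchaAU(pairs$hc_minus[i], pairs$preiai_minus[i],
             pairs$hc_plus[i], pairs$preiai_plus[i]),
      error = function(e) e)
    if (inherits(r, "error")) flag[i] <- conditionMessage(r) else au[i] <- r
  }
  out <- cbind(pairs, hcha_au = au, negative = !is.na(au) & au < 0,
               flag = flag)
  gs <- NULL
  if ("group" %in% names(pairs)) {
    ok <- !is.na(au)
    gs <- do.call(rbind, lapply(split(au[ok], pairs$group[ok]), function(v)
      data.frame(median_au = stats::median(v), iqr_au = stats::IQR(v),
                 n = length(v))))
    gs <- cbind(group = rownames(gs), gs)
    rownames(gs) <- NULL
  }
  list(perSample = out, groupSummary = gs)
}
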