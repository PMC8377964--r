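## Cohort statistical layer: normality-gated two-group comparisons with
## skew-directed transforms, qPCR fold changes, 5PL immunoassay calibration,
## correlation, constrained quadratic fits and assay QC helpers.

#' Normality-gated two-group comparison
#'
#' Implements the study's testing policy. Shapiro-Wilk normality is checked
#' in both groups (alpha = 0.05). If the raw data pass, an unpaired t-test is
#' used and means +/- SEM reported. Otherwise a skew-directed transform is
#' applied — cube root for right-skewed data, log for left-skewed — and the
#' t-test is used on the transformed scale if normality is then achieved in
#' both groups. If not, the Wilcoxon rank-sum test is used and medians +/-
#' IQR reported. The rank test is exact for small tie-free samples and uses
#' the tie-corrected normal approximation otherwise. The report records the
#' path taken.
#'
#' @param values numeric measurements.
#' @param groups factor/character of the same length, exactly 2 levels
#'   needed for a test.
#' @param skewPolicy \code{"auto"} (sign of sample skewness decides),
#'   \code{"cube_root"}, \code{"log"}, or \code{"none"}.
#' @param alpha normality-gate significance level (default 0.05).
#' @return list with \code{path} (\code{"t_raw"}, \code{"t_cube_root"},
#'   \code{"t_log"} or \code{"wilcoxon"}), \code{p_value}, \code{transform},
#'   \code{summary} (per-group mean, sem, median, iqr, n) and
#'   \code{shapiro_p}.
#' @export
normalityGatedTest <- function(values, groups,
                               skewPolicy = c("auto", "cube_root", "log",
                                              "none"),
                               alpha = 0.05) {
  skewPolicy <- match.arg(skewPolicy)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly 2 groups")
  g1 <- values[groups == lv[1]]; g2 <- values[groups == lv[2]]
  if (length(g1) < 3L || length(g2) < 3L)
    stop("need >= 3 observations per group")

  summarize <- function(v) c(mean = mean(v),
                             sem = stats::sd(v) / sqrt(length(v)),
                             median = stats::median(v), iqr = stats::IQR(v),
                             n = length(v))
  summ <- rbind(summarize(g1), summarize(g2))
  rownames(summ) <- lv

  shap <- function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  cubeRoot <- function(v) sign(v) * abs(v)^(1/3)

  runT <- function(a, b) stats::t.test(a, b, var.equal = FALSE)$p.value
  runW <- function(a, b) {
    n <- length(a) + length(b)
    hasTies <- anyDuplicated(c(a, b)) > 0L
    suppressWarnings(stats::wilcox.test(
      a, b, exact = (n <= 40L && !hasTies), correct = TRUE)$p.value)
  }

  sp1 <- shap(g1); sp2 <- shap(g2)
  if (sp1 > alpha && sp2 > alpha && skewPolicy != "none") {
    return(list(path = "t_raw", p_value = runT(g1, g2), transform = "none",
                summary = summ, shapiro_p = c(sp1, sp2)))
  }
  transform <- switch(skewPolicy,
    auto = {
      sk <- e1071::skewness(values, type = 2)
      if (!is.finite(sk) || sk >= 0) "cube_root" else "log"
    },
    cube_root = "cube_root", log = "log", none = "none")
  if (transform == "log" && any(values <= 0)) transform <- "cube_root"
  if (transform != "none") {
    f <- if (transform == "cube_root") cubeRoot else log
    t1 <- f(g1); t2 <- f(g2)
    tp1 <- shap(t1); tp2 <- shap(t2)
    if (tp1 > alpha && tp2 > alpha) {
      return(list(path = paste0("t_", transform), p_value = runT(t1, t2),
                  transform = transform, summary = summ,
                  shapiro_p = c(tp1, tp2)))
    }
  }
  list(path = "wilcoxon", p_value = runW(g1, g2), transform = "none",
       summary = summ, shapiro_p = c(sp1, sp2))
}

#' Floor undetectable assay values
#'
#' Samples reported as 0 (below the detection limit) are assigned an
#' arbitrary small value — 1 by default, which must lie below the assay's
#' lowest detectable concentration — so that rank tests can include them.
#'
#' @param values numeric, >= 0.
#' @param floor replacement for zeros (default 1).
#' @return values with zeros replaced by \code{floor}.
#' @export
floorUndetectable <- function(values, floor = 1) {
  if (any(values < 0, na.rm = TRUE))
    stop("negative concentrations are not valid assay values")
  values[!is.na(values) & values == 0] <- floor
  values
}

#' Relative gene expression by the 2^-ddCt method
#'
#' dCt = Ct(gene) - Ct(reference); ddCt = dCt - center(healthy dCt);
#' fold = 2^-ddCt. The center is the healthy-group median by default (so the
#' healthy median fold change is exactly 1.0); the healthy mean is also
#' available.
#'
#' @param ctGene,ctRef cycle thresholds for the gene of interest and the
#'   reference (housekeeping) gene, paired per sample.
#' @param groups group labels; \code{healthyLabel} identifies the reference
#'   group.
#' @param healthyLabel label of the control group (default "healthy").
#' @param center \code{"median"} (default) or \code{"mean"} of healthy dCt.
#' @return data.frame with \code{dct}, \code{ddct}, \code{fold} and
#'   \code{flag} ("missing_ref" where the reference Ct is NA).
#' @export
ddctFoldChange <- function(ctGene, ctRef, groups, healthyLabel = "healthy",
                           center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(ctGene) != length(ctRef) || length(ctGene) != length(groups))
    stop("ctGene, ctRef and groups must have equal length")
  flag <- ifelse(is.na(ctRef), "missing_ref", "")
  dct <- ctGene - ctRef
  hd <- dct[groups == healthyLabel & flag == ""]
  if (!length(hd)) stop("healthy group is empty")
  ctr <- if (center == "median") stats::median(hd, na.rm = TRUE)
         else mean(hd, na.rm = TRUE)
  ddct <- dct - ctr
  data.frame(dct = dct, ddct = ddct, fold = 2^(-ddct), flag = flag)
}

#' Evaluate the 5PL model
#'
#' y = a + b / (1 + (x/c)^d)^f.
#'
#' @param x concentrations (> 0; x = 0 evaluates to the a + b asymptote for
#'   d > 0).
#' @param params an \linkS4class{FiveParamLogistic} or named numeric
#'   (a, b, c, d, f).
#' @return fitted responses.
#' @export
predict5PL <- function(x, params) {
  cf <- if (is(params, "FiveParamLogistic")) params@coefficients else params
  cf[["a"]] + cf[["b"]] / (1 + (x / cf[["c"]])^cf[["d"]])^cf[["f"]]
}

#' Fit a five-parameter logistic standard curve
#'
#' Levenberg-Marquardt least squares of the 5PL model to standard-curve
#' points (the multiplex assay uses 5-fold serial dilutions of a standard
#' mix). c, d and f are constrained positive; the curve direction is carried
#' by the sign of b.
#'
#' @param conc standard concentrations, > 0, at least 5 points.
#' @param response measured responses (e.g. median fluorescence intensity).
#' @return An \linkS4class{FiveParamLogistic}.
#' @export
fit5PL <- function(conc, response) {
  if (length(conc) != length(response)) stop("conc/response length mismatch")
  if (length(conc) < 5L) stop("need >= 5 standard points for a 5PL fit")
  if (any(conc <= 0)) stop("standard concentrations must be > 0")
  if (stats::sd(response) == 0)
    stop("degenerate standard curve: all responses are equal")
  a0 <- response[which.max(conc)]
  b0 <- response[which.min(conc)] - a0
  if (b0 == 0) b0 <- diff(range(response))
  start <- list(a = a0, b = b0, c = exp(mean(log(conc))), d = 1, f = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ a + b / (1 + (conc / c)^d)^f,
      start = start,
      lower = c(a = -Inf, b = -Inf, c = 1e-12, d = 1e-6, f = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("5PL fit did not converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  new("FiveParamLogistic", coefficients = cf,
      convergence = list(rss = rss, iterations = fit$convInfo$finIter,
                         message = fit$convInfo$stopMessage))
}

#' Invert a 5PL standard curve
#'
#' x = c * ((b/(y-a))^(1/f) - 1)^(1/d). Responses at or beyond the model
#' asymptotes (a and a + b) cannot be inverted and are censored with a
#' below-/above-range flag instead.
#'
#' @param y responses to invert.
#' @param params an \linkS4class{FiveParamLogistic} or named numeric.
#' @return data.frame with \code{conc} (NA when censored) and \code{censored}
#'   ("ok", "below_range", "above_range").
#' @export
invert5PL <- function(y, params) {
  cf <- if (is(params, "FiveParamLogistic")) params@coefficients else params
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]; d <- cf[["d"]]; f <- cf[["f"]]
  # with d > 0 the x -> 0 asymptote is a + b and the x -> Inf asymptote is a
  lowAsym <- a + b   # response at zero concentration
  conc <- rep(NA_real_, length(y))
  cens <- rep("ok", length(y))
  for (i in seq_along(y)) {
    ratio <- b / (y[i] - a)
    invertible <- is.finite(ratio) && ratio > 1
    if (!invertible) {
      # censoring side depends on curve direction (sign of b)
      belowSide <- if (b > 0) y[i] >= lowAsym else y[i] <= lowAsym
      cens[i] <- if (belowSide) "below_range" else "above_range"
    } else {
      conc[i] <- cc * (ratio^(1 / f) - 1)^(1 / d)
    }
  }
  data.frame(conc = conc, censored = cens)
}

#' Constrained quadratic viscosity-concentration fit
#'
#' Least squares for y = B0 + B1 x + B2 x^2 under the constraints B0 = 1,
#' B1 = 0 (relative viscosity 1 at zero polymer concentration), which has
#' the closed form B2 = sum(x^2 (y-1)) / sum(x^4). R^2 = 1 - SSres/SStot may
#' be <= 0 for a poorly explained relationship and is reported as-is.
#'
#' @param x concentrations (not all zero).
#' @param y viscosities (relative units: 1 at x = 0).
#' @return list with \code{B2}, \code{R2}, \code{n} and the constraint
#'   record.
#' @export
constrainedQuadFit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need >= 2 points")
  s4 <- sum(x^4)
  if (s4 == 0) stop("all concentrations are zero; B2 is unidentifiable")
  B2 <- sum(x^2 * (y - 1)) / s4
  res <- y - (1 + B2 * x^2)
  sst <- sum((y - mean(y))^2)
  R2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(B2 = B2, R2 = R2, n = length(x),
       constraint = c(B0 = 1, B1 = 0))
}

#' Spearman rank correlation
#'
#' Average-rank tie handling with a two-sided p-value (tie-corrected normal
#' approximation when ties are present). A constant input vector has no
#' defined rank correlation and is flagged instead of erroring.
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs.
#' @return list with \code{rho}, \code{p_value}, \code{n} and \code{flag}.
#' @export
spearmanRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                flag = "constant_vector"))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       flag = "")
}

#' Average intra-assay coefficient of variation
#'
#' Per-sample CV = 100 * sd/mean over within-plate replicates (sample sd,
#' n - 1 denominator), averaged across samples (and plates when a plate
#' column is present). Samples with zero mean are flagged and excluded from
#' the average.
#'
#' @param replicates data.frame with columns \code{sample_id}, \code{value}
#'   and optionally \code{plate}.
#' @return list with \code{mean_cv_pct} and \code{perSample} data.frame.
#' @export
intraAssayCV <- function(replicates) {
  if (!all(c("sample_id", "value") %in% names(replicates)))
    stop("replicates need sample_id and value columns")
  key <- if ("plate" %in% names(replicates))
    interaction(replicates$plate, replicates$sample_id, drop = TRUE)
  else factor(replicates$sample_id)
  per <- do.call(rbind, lapply(split(replicates$value, key), function(v) {
    if (length(v) < 2L)
      return(data.frame(n = length(v), mean = mean(v), cv_pct = NA_real_,
                        flag = "single_replicate"))
    m <- mean(v)
    if (m == 0)
      return(data.frame(n = length(v), mean = 0, cv_pct = NA_real_,
                        flag = "zero_mean"))
    data.frame(n = length(v), mean = m, cv_pct = 100 * stats::sd(v) / m,
               flag = "")
  }))
  per <- cbind(key = rownames(per), per); rownames(per) <- NULL
  list(mean_cv_pct = mean(per$cv_pct, na.rm = TRUE), perSample = per)
}

#' Viscometer replicate filter
#'
#' Microfluidic viscometry runs 7 test segments over 4 flow rates (2 x 50,
#' 2 x 75, 2 x 100, 1 x 125 uL/min); the lowest flow rate (apparent shear
#' rate 950 1/s) is excessively variable and is excluded, leaving 5
#' technical replicates.
#'
#' @param segments data.frame with columns \code{flow_rate} and
#'   \code{viscosity}.
#' @return list with \code{retained} (data.frame, input order preserved),
#'   \code{removed}, and \code{flag} ("all_segments_removed" when only one
#'   flow rate was present).
#' @export
viscometerReplicateFilter <- function(segments) {
  if (!nrow(segments)) stop("empty segment list")
  if (!all(c("flow_rate", "viscosity") %in% names(segments)))
    stop("segments need flow_rate and viscosity columns")
  lowest <- min(segments$flow_rate)
  drop <- segments$flow_rate == lowest
  list(retained = segments[!drop, , drop = FALSE],
       removed = segments[drop, , drop = FALSE],
       flag = if (all(drop)) "all_segments_removed" else "")
}

#' Combined serial dilution factor
#'
#' Product of successive dilution factors, e.g. a 1:20 reconstitution
#' followed by a 1:100 dilution gives a final 2000-fold dilution.
#'
#' @param factors numeric vector of per-step dilution factors, > 0.
#' @return the overall dilution factor.
#' @examples
#' serialDilutionFactor(c(20, 100))  # 2000
#' @export
serialDilutionFactor <- function(factors) {
  if (!length(factors)) stop("no dilution factors given")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("dilution factors must be positive")
  prod(factors)
}

#' Run the full cohort analysis
#'
#' For every numeric measurement column: per-group summaries and (with two
#' groups) the normality-gated comparison. Optionally a Spearman correlation
#' for each configured variable pair and a constrained quadratic
#' viscosity-concentration fit per group.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param variables columns to test (default: all numeric measurement
#'   columns).
#' @param spearmanPairs list of character 2-vectors naming column pairs.
#' @param quadPair character 2-vector \code{c(x, y)} naming the
#'   concentration and viscosity columns for the constrained fit (NULL to
#'   skip).
#' @return list with \code{tests} (per variable), \code{spearman},
#'   \code{quadFits} (per group) and \code{skipped}.
#' @export
runCohortAnalysis <- function(cohort, variables = NULL,
                              spearmanPairs = NULL, quadPair = NULL) {
  validObject(cohort)
  d <- cohort@data
  if (is.null(variables))
    variables <- names(d)[vapply(d, is.numeric, logical(1))]
  variables <- setdiff(variables, c("sample_id", "group"))
  nGroups <- length(unique(d$group))
  tests <- list(); skipped <- character()
  for (v in variables) {
    vals <- d[[v]]
    if (is.null(vals) || all(is.na(vals))) {
      warning("column ", v, " is empty; skipped")
      skipped <- c(skipped, v)
      next
    }
    if (nGroups == 2L) {
      r <- tryCatch(normalityGatedTest(vals, d$group),
                    error = function(e) list(error = conditionMessage(e)))
      tests[[v]] <- r
    } else {
      tests[[v]] <- list(
        path = "summary_only", p_value = NA_real_,
        summary = do.call(rbind, lapply(split(vals, d$group), function(g)
          c(mean = mean(g, na.rm = TRUE),
            sem = stats::sd(g, na.rm = TRUE) / sqrt(sum(!is.na(g))),
            median = stats::median(g, na.rm = TRUE),
            iqr = stats::IQR(g, na.rm = TRUE), n = sum(!is.na(g))))))
    }
  }
  sp <- NULL
  if (!is.null(spearmanPairs)) {
    sp <- do.call(rbind, lapply(spearmanPairs, function(pr) {
      r <- spearmanRho(d[[pr[1]]], d[[pr[2]]])
      data.frame(x = pr[1], y = pr[2], rho = r$rho, p_value = r$p_value,
                 n = r$n, flag = r$flag)
    }))
  }
  qf <- NULL
  if (!is.null(quadPair)) {
    qf <- lapply(split(d, d$group), function(sub)
      tryCatch(constrainedQuadFit(sub[[quadPair[1]]], sub[[quadPair[2]]]),
               error = function(e) list(error = conditionMessage(e))))
  }
  list(tests = tests, spearman = sp, quadFits = qf, skipped = skipped)
}
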