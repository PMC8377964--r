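## Seeded synthetic-data generators for every input modality. Each generator
## returns the simulated input together with a machine-readable truth record
## so the analysis stages can be tested end to end without external data.
## All randomness is local to the call: a given seed gives bit-identical
## output and never touches the caller's RNG state.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Log-normal molecular-weight distribution with exact target moments
#'
#' Builds a mass-weighted log-normal distribution on a geometric grid whose
#' analytic Mw and PDI equal the targets. For a mass-weighted log-normal
#' density LN(mu, sigma^2): Mw = exp(mu + sigma^2/2), Mn = exp(mu -
#' sigma^2/2), so PDI = exp(sigma^2) and the parameters follow in closed
#' form. The defaults correspond to healthy equine synovial-fluid HA as
#' measured on gels (Mw 3660 kDa, PDI 2.26).
#'
#' @param mwTargetKda target weight-average MW (default 3660).
#' @param pdiTarget target polydispersity (default 2.26, >= 1).
#' @param nGrid number of grid points (default 600).
#' @param tailProb probability mass trimmed off each tail of the grid
#'   (default 1e-4).
#' @return list with \code{distribution} (mass-weighted
#'   \linkS4class{MWDistribution}) and \code{truth} (Mw, Mn, PDI, mu,
#'   sigma).
#' @export
simMWLognormal <- function(mwTargetKda = 3660, pdiTarget = 2.26,
                           nGrid = 600, tailProb = 1e-4) {
  if (!is.finite(pdiTarget) || pdiTarget < 1) stop("PDI target must be >= 1")
  if (mwTargetKda <= 0) stop("Mw target must be > 0")
  sig2 <- log(pdiTarget)
  mu <- log(mwTargetKda) - sig2 / 2
  truth <- list(Mw = mwTargetKda, Mn = mwTargetKda / pdiTarget,
                PDI = pdiTarget, mu = mu, sigma = sqrt(sig2))
  if (sig2 == 0) {
    return(list(distribution = MWDistribution(mwTargetKda, 1), truth = truth))
  }
  s <- sqrt(sig2)
  edges <- exp(seq(stats::qnorm(tailProb, mu, s),
                   stats::qnorm(1 - tailProb, mu, s),
                   length.out = nGrid + 1L))
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  w <- diff(stats::plnorm(edges, mu, s))
  list(distribution = MWDistribution(centers, w), truth = truth)
}

#' Synthetic gel lane from a known distribution
#'
#' Deposits each grid point's mass weight at its calibrated migration pixel,
#' then adds a smooth baseline and Gaussian noise. Mass outside the
#' calibration range is truncated and the truncated fraction recorded.
#'
#' @param dist a mass-weighted \linkS4class{MWDistribution} (the truth).
#' @param calib a \linkS4class{GelCalibration}.
#' @param noiseSd Gaussian noise SD: in intensity units for
#'   \code{noiseType = "additive"} (the typical test setting is 1\% of the
#'   peak intensity), or as a relative factor for
#'   \code{noiseType = "multiplicative"} (intensity is scaled by
#'   \code{1 + N(0, noiseSd)}).
#' @param baseline constant baseline offset (default 0), or a function of
#'   the pixel vector returning the baseline profile.
#' @param noiseType \code{"additive"} (default) or \code{"multiplicative"}.
#' @param seed integer seed; NULL uses (and advances) the caller's RNG.
#' @return list with \code{profile} (a \linkS4class{LaneProfile}),
#'   \code{truth} (the input distribution and its summaries) and
#'   \code{truncatedFraction}.
#' @export
simGelLane <- function(dist, calib, noiseSd = 0, baseline = 0,
                       noiseType = c("additive", "multiplicative"),
                       seed = NULL) {
  noiseType <- match.arg(noiseType)
  validObject(dist); validObject(calib)
  px <- predictMigration(calib, dist@masses)
  inR <- !is.na(px)
  truncated <- 1 - sum(dist@weights[inR]) / sum(dist@weights)
  if (truncated > 1e-3)
    warning(sprintf("%.2f%% of mass lies outside the calibrated range",
                    100 * truncated))
  grid <- seq(floor(min(calib@anchorPx)), ceiling(max(calib@anchorPx)))
  intensity <- numeric(length(grid))
  bins <- round(px[inR]) - grid[1] + 1L
  ok <- bins >= 1L & bins <= length(grid)
  for (i in which(ok))
    intensity[bins[i]] <- intensity[bins[i]] + dist@weights[inR][i]
  base <- if (is.function(baseline)) baseline(grid) else rep(baseline, length(grid))
  intensity <- .withSeed(seed, {
    out <- intensity + base
    if (noiseSd > 0) {
      out <- if (noiseType == "multiplicative")
        out * (1 + stats::rnorm(length(out), 0, noiseSd))
      else out + stats::rnorm(length(out), 0, noiseSd)
    }
    out
  })
  list(profile = LaneProfile(grid, pmax(0, intensity)),
       truth = list(distribution = dist, Mw = weightAverageMW(dist),
                    Mn = numberAverageMW(dist), PDI = polydispersity(dist)),
       truncatedFraction = truncated)
}

#' Synthetic two-lane gel image (ladder + sample)
#'
#' Small grayscale image in the dark-background convention: lane 1 carries
#' delta bands at the ladder anchors, lane 2 the sample lane built with
#' \code{\link{simGelLane}}.
#'
#' @inheritParams simGelLane
#' @param laneWidth width of each lane in columns (default 10).
#' @return list with \code{image} (matrix), \code{laneBounds} (list with
#'   \code{ladder} and \code{sample} column ranges), and the
#'   \code{\link{simGelLane}} output for the sample lane.
#' @export
simGelImage <- function(dist, calib, noiseSd = 0, baseline = 0,
                        laneWidth = 10, seed = NULL) {
  lane <- simGelLane(dist, calib, noiseSd, baseline, seed = seed)
  nRow <- length(lane$profile@distancePx)
  img <- matrix(0, nRow, 2L * laneWidth + 4L)
  ladderRows <- round(calib@anchorPx) - lane$profile@distancePx[1] + 1L
  peak <- max(lane$profile@intensity)
  img[ladderRows, 2L + seq_len(laneWidth)] <- peak
  img[, laneWidth + 4L + seq_len(laneWidth) - 1L] <- lane$profile@intensity
  list(image = img,
       laneBounds = list(ladder = c(3L, 2L + laneWidth),
                         sample = c(laneWidth + 3L, 2L * laneWidth + 2L)),
       lane = lane)
}

#' Default ECD calibration for simulations
#'
#' Synthetic power-law calibration ECD = A * MW^B anchored at the seven
#' quasi-monodisperse HA standard masses (54-2384 kDa). The coefficients are
#' a simulation convention, not measured values.
#'
#' @param A prefactor in pA s at 1 kDa (default 2e-5).
#' @param B exponent (default 1.2).
#' @return An \linkS4class{ECDCalibration}.
#' @export
simECDCalibration <- function(A = 2e-5, B = 1.2) {
  mw <- c(54, 81, 130, 237, 545, 1076, 2384)
  fitECDCalibration(data.frame(mw_kda = mw, mean_ecd = A * mw^B))
}

#' Synthetic nanopore current trace with known events
#'
#' Gaussian baseline noise with Poisson-arriving rectangular blockade
#' events. Each event's MW is drawn number-weighted from the supplied
#' distribution, its ECD set by the forward calibration, its duration drawn
#' uniformly (default 50 us - 2 ms) and its depth = ECD / duration.
#' Durations are resampled when the implied depth would fall below
#' \code{minDepthSigma} noise SDs (or a warning is issued, configurable);
#' overlapping events are re-placed.
#'
#' @param dist an \linkS4class{MWDistribution} (mass- or number-weighted).
#' @param calib an \linkS4class{ECDCalibration} used as the forward model.
#' @param eventRateHz mean event rate (default 20/s).
#' @param sigmaPa baseline noise SD in pA (0 gives a noiseless trace).
#' @param durationS trace length in seconds (default 10).
#' @param sampleRate sampling rate (default 200 kHz).
#' @param baselinePa open-pore current (default 4000 pA).
#' @param durRange uniform duration range in seconds (default c(50e-6, 2e-3)).
#' @param minDepthSigma minimum event depth in units of sigmaPa (default 6).
#' @param shallowAction \code{"resample"} (shorten the duration, default) or
#'   \code{"warn"}.
#' @param seed integer seed.
#' @return list with \code{trace} (a \linkS4class{CurrentTrace}) and
#'   \code{truth} (data.frame: start, end, n_samples, duration_s, depth_pa,
#'   ecd_pas, mw_kda).
#' @export
simNanoporeTrace <- function(dist, calib = simECDCalibration(),
                             eventRateHz = 20, sigmaPa = 2, durationS = 10,
                             sampleRate = 2e5, baselinePa = 4000,
                             durRange = c(50e-6, 2e-3), minDepthSigma = 6,
                             shallowAction = c("resample", "warn"),
                             seed = NULL) {
  validObject(dist)
  shallowAction <- match.arg(shallowAction)
  n <- as.integer(round(durationS * sampleRate))
  .withSeed(seed, {
    cur <- rep(baselinePa, n)
    if (sigmaPa > 0) cur <- cur + stats::rnorm(n, 0, sigmaPa)
    nEv <- stats::rpois(1, eventRateHz * durationS)
    numberW <- if (dist@weighting == "number") dist@weights
               else dist@weights / dist@masses
    mws <- dist@masses[sample.int(length(dist@masses), nEv, replace = TRUE,
                                  prob = numberW)]
    ecds <- mwToECD(mws, calib)
    occupied <- rep(FALSE, n)
    gap <- as.integer(round(250e-6 * sampleRate))  # enforced event spacing
    rows <- vector("list", nEv)
    for (i in seq_len(nEv)) {
      dur <- stats::runif(1, durRange[1], durRange[2])
      if (sigmaPa > 0) {
        maxDur <- ecds[i] / (minDepthSigma * sigmaPa)
        if (maxDur < durRange[1]) {
          if (shallowAction == "warn")
            warning(sprintf("event %d depth below %g sigma at minimum duration",
                            i, minDepthSigma))
          dur <- durRange[1]
        } else if (dur > maxDur) {
          dur <- stats::runif(1, durRange[1], min(maxDur, durRange[2]))
        }
      }
      nv <- max(1L, as.integer(round(dur * sampleRate)))
      depth <- ecds[i] / (nv / sampleRate)
      placed <- FALSE
      for (try in 1:200) {
        st <- sample.int(n - nv - 2L * gap, 1) + gap
        span <- max(1L, st - gap):min(n, st + nv - 1L + gap)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          cur[st:(st + nv - 1L)] <- cur[st:(st + nv - 1L)] - depth
          rows[[i]] <- data.frame(start = st, end = st + nv - 1L,
                                  n_samples = nv,
                                  duration_s = nv / sampleRate,
                                  depth_pa = depth,
                                  ecd_pas = depth * nv / sampleRate,
                                  mw_kda = mws[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) warning("could not place event ", i, "; dropped")
    }
    truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(truth)) truth <- truth[order(truth$start), , drop = FALSE]
    list(trace = CurrentTrace(cur, sampleRate), truth = truth)
  })
}

#' Synthetic Brownian bead trajectories
#'
#' Independent 2-D random walks with per-axis step SD sqrt(2 D dt), where
#' D = kB T / (6 pi r eta) (Stokes-Einstein). The defaults emulate the
#' standard acquisition: three 30-s videos at 16 Hz with 15 beads each (45
#' tracks of 480 frames). Optional i.i.d. Gaussian localization noise is
#' added to the positions.
#'
#' @param etaCp true viscosity in cP.
#' @param temperatureK temperature (default 295.15 K).
#' @param beadRadiusUm bead radius (default 0.25 um).
#' @param fps frame rate (default 16 Hz).
#' @param durationS video length (default 30 s).
#' @param nTracks number of tracks (default 45, split over 3 videos).
#' @param locNoiseUm localization noise SD (default 0).
#' @param seed integer seed.
#' @return list with \code{tracks} (a \linkS4class{TrackSet}) and
#'   \code{truth} (D in um^2/s and the generating parameters).
#' @export
simBrownianTracks <- function(etaCp = 1, temperatureK = 295.15,
                              beadRadiusUm = 0.25, fps = 16, durationS = 30,
                              nTracks = 45, locNoiseUm = 0, seed = NULL) {
  if (etaCp <= 0 || temperatureK <= 0 || beadRadiusUm <= 0 || fps <= 0)
    stop("nonphysical parameters")
  D <- .kB * temperatureK / (6 * pi * beadRadiusUm * 1e-6 * etaCp * 1e-3) * 1e12
  dt <- 1 / fps
  nFrames <- as.integer(round(durationS * fps))
  stepSd <- sqrt(2 * D * dt)
  .withSeed(seed, {
    tracks <- do.call(rbind, lapply(seq_len(nTracks), function(id) {
      x <- cumsum(c(0, stats::rnorm(nFrames - 1L, 0, stepSd)))
      y <- cumsum(c(0, stats::rnorm(nFrames - 1L, 0, stepSd)))
      if (locNoiseUm > 0) {
        x <- x + stats::rnorm(nFrames, 0, locNoiseUm)
        y <- y + stats::rnorm(nFrames, 0, locNoiseUm)
      }
      data.frame(track_id = id, frame = seq_len(nFrames), x_um = x, y_um = y,
                 video = ((id - 1L) %% 3L) + 1L)
    }))
    list(tracks = TrackSet(tracks, fps),
         truth = list(D_um2_per_s = D, eta_cp = etaCp,
                      temperatureK = temperatureK,
                      beadRadiusUm = beadRadiusUm))
  })
}

.lnFromMedianIQR <- function(n, medianV, iqrV) {
  # log-normal with the requested median and IQR:
  # IQR = median * 2 sinh(z75 * sigma), z75 = qnorm(0.75)
  if (medianV == 0) return(rep(0, n))
  z75 <- stats::qnorm(0.75)
  sigma <- asinh(iqrV / (2 * medianV)) / z75
  medianV * exp(stats::rnorm(n, 0, sigma))
}

#' Default cohort effect configuration
#'
#' Group medians and IQRs for each simulated measurement, taken from the
#' reference cohort (gels, cytokines, immunoblots), plus the
#' viscosity-concentration coefficients. Override any entry to change the
#' simulated effect structure; set healthy and OA entries equal for a null
#' configuration.
#'
#' @return nested list of \code{c(median, iqr)} per group per variable, and
#'   \code{visc_B2} per group.
#' @export
defaultCohortEffects <- function() {
  list(
    ha_conc_mgml = list(healthy = c(0.35, 0.3), oa = c(0.29, 0.3)),
    mw_kda = list(healthy = c(3660, 1000), oa = c(3070, 740)),
    mn_kda = list(healthy = c(1520, 680), oa = c(1260, 410)),
    pdi = list(healthy = c(2.26, 0.4), oa = c(2.38, 0.4)),
    tnfa_ngml = list(healthy = c(4.97, 11.7), oa = c(15.6, 22.7)),
    ccl2_ngml = list(healthy = c(1.61, 7.0), oa = c(1.78, 6.6)),
    ccl11_ngml = list(healthy = c(0.86, 0.6), oa = c(0.53, 0.4)),
    hcha_au = list(healthy = c(0.10, 0.1), oa = c(0.38, 0.6)),
    visc_B2 = list(healthy = 256, oa = 434),
    visc_noise_sdlog = 0.2,
    tsg6_dct = list(healthy = c(12, 1), oa = c(10.8, 1))  # mean, sd
  )
}

#' Synthetic two-group cohort table
#'
#' Draws every measurement from shifted log-normals matched to the
#' configured group medians and IQRs; viscosity is generated from the HA
#' concentration through the constrained quadratic law y = 1 + B2 x^2 with
#' multiplicative log-normal noise; TSG6/18S cycle thresholds are generated
#' so OA has higher TSG6 expression.
#'
#' @param nHealthy,nOa group sizes (defaults 25 and 61, the reference cohort).
#' @param effects configuration list (see \code{\link{defaultCohortEffects}}).
#' @param seed integer seed.
#' @return list with \code{cohort} (a \linkS4class{CohortTable}) and
#'   \code{truth} (the effect configuration used).
#' @export
simCohort <- function(nHealthy = 25, nOa = 61,
                      effects = defaultCohortEffects(), seed = NULL) {
  need <- c("ha_conc_mgml", "visc_B2", "visc_noise_sdlog", "tsg6_dct")
  if (!all(need %in% names(effects)))
    stop("invalid effect config: missing ", paste(setdiff(need, names(effects)),
                                                  collapse = ", "))
  n <- nHealthy + nOa
  grp <- c(rep("healthy", nHealthy), rep("OA", nOa))
  .withSeed(seed, {
    d <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = grp)
    lnVars <- setdiff(names(effects),
                      c("visc_B2", "visc_noise_sdlog", "tsg6_dct"))
    for (v in lnVars) {
      cfg <- effects[[v]]
      d[[v]] <- NA_real_
      d[[v]][grp == "healthy"] <-
        .lnFromMedianIQR(nHealthy, cfg$healthy[1], cfg$healthy[2])
      d[[v]][grp == "OA"] <- .lnFromMedianIQR(nOa, cfg$oa[1], cfg$oa[2])
    }
    b2 <- ifelse(grp == "healthy", effects$visc_B2$healthy,
                 effects$visc_B2$oa)
    d$viscosity_cp <- (1 + b2 * d$ha_conc_mgml^2) *
      exp(stats::rnorm(n, 0, effects$visc_noise_sdlog))
    dctCfg <- effects$tsg6_dct
    dct <- ifelse(grp == "healthy",
                  stats::rnorm(n, dctCfg$healthy[1], dctCfg$healthy[2]),
                  stats::rnorm(n, dctCfg$oa[1], dctCfg$oa[2]))
    d$ct_18s <- stats::rnorm(n, 15, 0.3)
    d$ct_tsg6 <- d$ct_18s + dct
    units <- c(ha_conc_mgml = "mg/mL", mw_kda = "kDa", mn_kda = "kDa",
               pdi = "", tnfa_ngml = "ng/mL", ccl2_ngml = "ng/mL",
               ccl11_ngml = "ng/mL", hcha_au = "a.u.",
               viscosity_cp = "cP", ct_18s = "cycles", ct_tsg6 = "cycles")
    list(cohort = CohortTable(d, units), truth = effects)
  })
}

#' Synthetic immunoblot lane pairs
#'
#' Builds paired-lane band densities whose true HC-HA a.u. follows a
#' log-normal with the configured group medians/IQRs (defaults 0.10/0.1
#' healthy, 0.38/0.6 OA). Pre-IaI bands are near 1, the undigested HC ratio
#' near 0.3, and the digested-lane HC band carries the HA-bound excess.
#' Optional multiplicative density noise perturbs all four bands (the
#' recovered a.u. then deviates from truth).
#'
#' @param nHealthy,nOa group sizes (defaults 25, 61).
#' @param groupMedians named list with \code{healthy} and \code{oa}
#'   \code{c(median, iqr)} entries for the true a.u.
#' @param noiseCV multiplicative band-density noise CV (default 0).
#' @param seed integer seed.
#' @return list with \code{pairs} (data.frame for \code{\link{batchHCHA}})
#'   and \code{truth} (per-sample true a.u.).
#' @export
simBlotPairs <- function(nHealthy = 25, nOa = 61,
                         groupMedians = list(healthy = c(0.10, 0.1),
                                             oa = c(0.38, 0.6)),
                         noiseCV = 0, seed = NULL) {
  if (any(c(groupMedians$healthy[1], groupMedians$oa[1]) < 0))
    stop("group medians must be >= 0")
  n <- nHealthy + nOa
  grp <- c(rep("healthy", nHealthy), rep("OA", nOa))
  .withSeed(seed, {
    au <- numeric(n)
    au[grp == "healthy"] <- .lnFromMedianIQR(nHealthy, groupMedians$healthy[1],
                                             groupMedians$healthy[2])
    au[grp == "OA"] <- .lnFromMedianIQR(nOa, groupMedians$oa[1],
                                        groupMedians$oa[2])
    if (groupMedians$healthy[1] == 0) au[grp == "healthy"] <- 0
    if (groupMedians$oa[1] == 0) au[grp == "OA"] <- 0
    baseRatio <- 0.3
    pairs <- data.frame(sample_id = sprintf("B%03d", seq_len(n)), group = grp,
                        hc_minus = baseRatio, preiai_minus = 1,
                        hc_plus = baseRatio + au, preiai_plus = 1)
    if (noiseCV > 0) {
      for (col in c("hc_minus", "preiai_minus", "hc_plus", "preiai_plus"))
        pairs[[col]] <- pairs[[col]] *
          exp(stats::rnorm(n, 0, sqrt(log(1 + noiseCV^2))))
    }
    list(pairs = pairs, truth = data.frame(sample_id = pairs$sample_id,
                                           group = grp, hcha_au = au))
  })
}
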