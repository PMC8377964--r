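test_that("low-pass filter preserves DC and the passband, attenuates far bands", {
  fs <- 2e5
  const <- CurrentTrace(rep(120, 4000), fs)
  expect_equal(lowpassFilter(const)@current, rep(120, 4000), tolerance = 1e-8)

  t <- seq(0, 0.05, by = 1 / fs)
  hi <- CurrentTrace(sin(2 * pi * 5e4 * t), fs)
  out <- lowpassFilter(hi, 5000)
  mid <- seq(2000, length(t) - 2000)  # avoid edge transients
  atten <- max(abs(out@current[mid]))
  expect_lt(atten, 10^(-20 / 20))  # >= 20 dB down

  lo <- CurrentTrace(sin(2 * pi * 100 * t), fs)
  outLo <- lowpassFilter(lo, 5000)
  expect_equal(max(abs(outLo@current[mid])), 1, tolerance = 0.01)

  expect_error(lowpassFilter(const, 1.5e5), "Nyquist")
})

test_that("baseline and sigma are estimated robustly", {
  expect_equal(estimateBaselineSigma(CurrentTrace(rep(7, 2000))),
               list(baseline_pa = 7, sigma_pa = 0))
  expect_error(estimateBaselineSigma(CurrentTrace(rep(7, 100))), "short")

  withr::with_seed(13, {
    x <- stats::rnorm(1e6, 100, 2)
    est <- estimateBaselineSigma(CurrentTrace(x))
    expect_equal(est$sigma_pa, 2, tolerance = 0.05)
    expect_equal(est$baseline_pa, 100, tolerance = 0.01)
    # 1% of samples replaced by deep blockades barely moves the estimates
    xc <- x
    idx <- sample(length(x), 0.01 * length(x))
    xc[idx] <- xc[idx] - 100
    estc <- estimateBaselineSigma(CurrentTrace(xc))
    expect_lt(abs(estc$baseline_pa - est$baseline_pa) / est$baseline_pa, 0.02)
    expect_lt(abs(estc$sigma_pa - est$sigma_pa) / est$sigma_pa, 0.02)
  })
})

test_that("event detection applies the 5-sigma and duration rules", {
  fs <- 2e5
  mkPulse <- function(depth, durS, at = 5000, n = 20000, base = 1000) {
    cur <- rep(base, n)
    nv <- round(durS * fs)
    cur[at:(at + nv - 1)] <- base - depth
    CurrentTrace(cur, fs)
  }
  sigma <- 2
  ev <- detectEvents(mkPulse(10 * sigma, 100e-6), 1000, sigma)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 100e-6)
  expect_equal(ev$start, 5000L)
  expect_equal(ev$n_samples, 20L)

  expect_equal(nrow(detectEvents(mkPulse(3 * sigma, 100e-6), 1000, sigma)), 0L)
  expect_equal(nrow(detectEvents(mkPulse(10 * sigma, 10e-6), 1000, sigma)), 0L)
  expect_equal(nrow(detectEvents(mkPulse(10 * sigma, 5e-3, n = 4e4),
                                 1000, sigma)), 0L)
  expect_error(detectEvents(mkPulse(10, 1e-4), 1000, 0), "sigma")
})

test_that("detection and ECD are invariant to a constant trace shift", {
  withr::with_seed(99, {
    d <- simMWLognormal(545, 1.02)
    sim <- simNanoporeTrace(d$distribution, eventRateHz = 30, sigmaPa = 2,
                            durationS = 2, seed = 4)
    ev1 <- detectEvents(sim$trace)
    shifted <- CurrentTrace(sim$trace@current + 250, sim$trace@sampleRate)
    ev2 <- detectEvents(shifted)
    expect_equal(ev1, ev2)
  })
})

test_that("rectangular-event ECD equals depth times duration", {
  fs <- 2e5
  cur <- rep(500, 10000)
  cur[2001:2020] <- 400  # 100 pA deep, 20 samples = 100 us
  tr <- CurrentTrace(cur, fs)
  expect_equal(eventECD(tr, 2001, 2020, 500), 0.01)  # pA s
  expect_equal(0.01 * 1000, 10)                      # = 10 fC
  expect_equal(eventECD(tr, 100, 150, 500), 0)       # zero-deviation span
  # offset invariance
  tr2 <- CurrentTrace(cur + 123, fs)
  expect_equal(eventECD(tr2, 2001, 2020, 623), 0.01)
  expect_error(eventECD(tr, 9990, 10050, 500), "indices")
})

test_that("ECD calibration recovers a power law and rejects bad standards", {
  mw <- c(54, 81, 130, 237, 545, 1076, 2384)
  std <- data.frame(mw_kda = mw, mean_ecd = 3e-5 * mw^1.4)
  cal <- fitECDCalibration(std)
  expect_equal(cal@slope, 1 / 1.4, tolerance = 1e-10)
  expect_equal(ecdToMW(std$mean_ecd, cal)$mw_kda, mw, tolerance = 1e-8)
  expect_false(any(ecdToMW(std$mean_ecd, cal)$extrapolated))

  two <- fitECDCalibration(data.frame(mw_kda = c(100, 1000),
                                      mean_ecd = c(0.01, 0.3)))
  expect_equal(ecdToMW(c(0.01, 0.3), two)$mw_kda, c(100, 1000))
  # geometric-mean interpolation under log-linearity
  expect_equal(ecdToMW(sqrt(0.01 * 0.3), two)$mw_kda, sqrt(100 * 1000))
  expect_true(ecdToMW(0.001, two)$extrapolated)

  expect_error(fitECDCalibration(data.frame(mw_kda = c(100, 200, 300),
                                            mean_ecd = c(0.1, 0.3, 0.2))),
               "increase")
  expect_error(ecdToMW(-1, two), "positive")
})

test_that("event summaries use number weighting and convert correctly", {
  cal <- fitECDCalibration(data.frame(mw_kda = c(10, 3000),
                                      mean_ecd = 1e-4 * c(10, 3000)))
  # events at exactly 100 and 300 kDa (ECD = 1e-4 * MW on this calibration)
  ev <- data.frame(ecd_pas = 1e-4 * c(100, 300))
  s <- eventsToMWSummary(ev, cal)
  expect_equal(s$Mn, 200, tolerance = 1e-8)
  expect_equal(s$Mw, 250, tolerance = 1e-8)
  expect_equal(s$PDI, 1.25, tolerance = 1e-8)
  expect_equal(weightAverageMW(s$distribution), s$Mw)
  expect_equal(numberAverageMW(s$distribution), s$Mn)

  same <- eventsToMWSummary(data.frame(ecd_pas = rep(1e-2, 5)), cal)
  expect_equal(same$PDI, 1)
  expect_error(eventsToMWSummary(data.frame(ecd_pas = numeric(0)), cal),
               "no retained events")
})

test_that("inflating every ECD by a common factor strictly increases Mw", {
  cal <- simECDCalibration()
  withr::with_seed(31, {
    ev <- data.frame(ecd_pas = stats::rlnorm(200, log(0.02), 0.5))
    base <- eventsToMWSummary(ev, cal)$Mw
    up <- eventsToMWSummary(transform(ev, ecd_pas = ecd_pas * 1.5), cal)$Mw
    expect_gt(up, base)
  })
})

test_that("noiseless synthetic traces are recovered exactly", {
  d <- simMWLognormal(545, 1.05)
  sim <- simNanoporeTrace(d$distribution, eventRateHz = 20, sigmaPa = 0,
                          durationS = 5, seed = 7)
  ev <- detectEvents(sim$trace, baseline = 4000, sigma = 0.01, mergeGapS = 0)
  expect_equal(nrow(ev), nrow(sim$truth))
  expect_equal(ev$start, sim$truth$start)
  expect_equal(ev$end, sim$truth$end)
  expect_equal(ev$ecd_pas, sim$truth$ecd_pas, tolerance = 1e-12)
})

test_that("high-SNR simulated traces give near-perfect precision and recall", {
  d <- simMWLognormal(545, 1.02)
  sim <- simNanoporeTrace(d$distribution, eventRateHz = 40, sigmaPa = 2,
                          durationS = 5, minDepthSigma = 10, seed = 19)
  res <- nanoporeMWSummary(sim$trace, simECDCalibration())
  pr <- eventPrecisionRecall(res$events, sim$truth)
  expect_gte(pr$precision, 0.99)
  expect_gte(pr$recall, 0.99)
  expect_equal(res$Mw, d$truth$Mw, tolerance = 0.1)
})
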