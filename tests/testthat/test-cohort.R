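test_that("the normality gate picks the right branch and detects real shifts", {
  withr::with_seed(11, {
    g1 <- stats::rnorm(50); g2 <- stats::rnorm(50, 1)
    r <- normalityGatedTest(c(g1, g2), rep(c("healthy", "OA"), each = 50))
    expect_equal(r$path, "t_raw")
    expect_lt(r$p_value, 0.01)

    same <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 2)
    rs <- normalityGatedTest(same, rep(c("healthy", "OA"), each = 10))
    expect_gt(rs$p_value, 0.9)

    # heavy-tailed positive data engage the cube-root branch
    h1 <- stats::rlnorm(60, 0, 1.6)^2; h2 <- stats::rlnorm(60, 0, 1.6)^2
    rh <- normalityGatedTest(c(h1, h2), rep(c("healthy", "OA"), each = 60))
    expect_true(rh$path %in% c("t_cube_root", "wilcoxon"))
    expect_false(rh$path == "t_raw")
  })
  expect_error(normalityGatedTest(1:4, c("a", "a", "b", "b")), ">= 3")
})

test_that("type-I error of the gated test is near nominal under the null", {
  withr::with_seed(2024, {
    hits <- replicate(1000, {
      v <- stats::rlnorm(40, 0, 0.8)  # one skewed population, two labels
      normalityGatedTest(v, rep(c("healthy", "OA"), each = 20))$p_value < 0.05
    })
    expect_gte(mean(hits), 0.03)
    expect_lte(mean(hits), 0.07)
  })
})

test_that("Wilcoxon p-values are invariant under monotone transforms", {
  withr::with_seed(3, {
    v <- stats::rlnorm(60, 0, 1.5)
    g <- rep(c("healthy", "OA"), each = 30)
    pRaw <- suppressWarnings(stats::wilcox.test(v[g == "healthy"],
                                                v[g == "OA"])$p.value)
    pCbrt <- suppressWarnings(stats::wilcox.test(v[g == "healthy"]^(1/3),
                                                 v[g == "OA"]^(1/3))$p.value)
    pLog <- suppressWarnings(stats::wilcox.test(log(v[g == "healthy"]),
                                                log(v[g == "OA"]))$p.value)
    expect_equal(pRaw, pCbrt)
    expect_equal(pRaw, pLog)
  })
})

test_that("undetectable values are floored, negatives rejected", {
  expect_equal(floorUndetectable(c(0, 0, 5.2)), c(1, 1, 5.2))
  expect_equal(floorUndetectable(c(2, 3)), c(2, 3))
  expect_equal(floorUndetectable(c(0, 4), floor = 0.5), c(0.5, 4))
  expect_error(floorUndetectable(c(-1)), "negative")
})

test_that("2^-ddCt fold changes follow the closed form with median anchoring", {
  ctRef <- rep(15, 6)
  ctGene <- c(25, 25, 25, 24, 23, 27)  # healthy dCt = 10 throughout
  grp <- c("healthy", "healthy", "healthy", "OA", "OA", "OA")
  r <- ddctFoldChange(ctGene, ctRef, grp)
  expect_equal(r$fold[1], 1.0)          # at the healthy center
  expect_equal(r$fold[4], 2.0)          # ddCt = -1
  expect_equal(r$fold[6], 0.25)         # ddCt = 2
  # mean centering is available and differs when healthy dCt is skewed
  r2 <- ddctFoldChange(c(25, 25, 28, 24), rep(15, 4),
                       c("healthy", "healthy", "healthy", "OA"),
                       center = "mean")
  expect_equal(r2$ddct[4], (24 - 15) - 11)
  # missing reference Ct flags the row
  r3 <- ddctFoldChange(c(25, 25, 25, 24), c(15, 15, NA, 15),
                       c("healthy", "healthy", "healthy", "OA"))
  expect_equal(r3$flag[3], "missing_ref")
})

test_that("5PL fitting recovers known parameters and rejects degenerate data", {
  truth <- c(a = 30, b = 2970, c = 120, d = 1.3, f = 0.8)
  x <- 5^(0:7) * 0.5  # 5-fold dilution series
  y <- predict5PL(x, truth)
  fit <- fit5PL(x, y)
  expect_equal(fit@coefficients[names(truth)], truth, tolerance = 1e-4)

  # algebra: at x = c with f = 1, y = a + b/2
  p1 <- c(a = 10, b = 100, c = 50, d = 2, f = 1)
  expect_equal(predict5PL(50, p1), 10 + 50)

  expect_error(fit5PL(x, rep(3, 8)), "degenerate")
  expect_error(fit5PL(x[1:3], y[1:3]), ">= 5")
})

test_that("5PL inversion round-trips and censors out-of-range responses", {
  p <- c(a = 20, b = -1900, c = 80, d = 1.7, f = 1.2)  # increasing curve
  withr::with_seed(9, {
    x <- stats::runif(200, 1, 4000)
    y <- predict5PL(x, p)
    back <- invert5PL(y, p)
    expect_true(all(back$censored == "ok"))
    expect_lt(max(abs(back$conc - x) / x), 1e-8)
  })
  # y = a is the high-concentration asymptote here (b < 0)
  expect_equal(invert5PL(20, p)$censored, "above_range")
  expect_equal(invert5PL(20 - 1900, p)$censored, "below_range")
  # forward(x = c) with f = 1 inverts to c
  p1 <- c(a = 5, b = 90, c = 30, d = 2, f = 1)
  expect_equal(invert5PL(predict5PL(30, p1), p1)$conc, 30)
})

test_that("5PL with f = 1 reproduces an independent 4PL fit", {
  truth4 <- c(a = 15, b = 985, c = 60, d = 2.2)
  x <- 4^(0:6)
  y <- truth4["a"] + truth4["b"] / (1 + (x / truth4["c"])^truth4["d"])
  fit5 <- fit5PL(x, y)
  # independent 4PL oracle: Levenberg-Marquardt on the reduced model
  o <- minpack.lm::nlsLM(y ~ a + b / (1 + (x / c)^d),
                         start = list(a = 10, b = 900, c = 40, d = 2))
  expect_equal(predict5PL(x, fit5), as.numeric(stats::predict(o)),
               tolerance = 1e-6)
})

test_that("constrained quadratic fit has the closed form and matches an oracle", {
  x <- seq(0.05, 1.5, length.out = 17)
  y <- 1 + 434 * x^2
  fit <- constrainedQuadFit(x, y)
  expect_equal(fit$B2, 434, tolerance = 1e-12)
  expect_equal(fit$R2, 1)
  expect_equal(unname(fit$constraint), c(1, 0))

  expect_equal(constrainedQuadFit(x, rep(1, 17))$B2, 0)

  withr::with_seed(12, {
    xr <- stats::runif(30, 0, 2); yr <- 1 + 100 * xr^2 + stats::rnorm(30, 0, 5)
    ours <- constrainedQuadFit(xr, yr)$B2
    # oracle: unconstrained regression of (y - 1) on x^2 without intercept
    oracle <- unname(stats::coef(stats::lm(I(yr - 1) ~ I(xr^2) - 1))[1])
    expect_equal(ours, oracle, tolerance = 1e-10)
  })
  expect_error(constrainedQuadFit(c(0, 0), c(1, 2)), "zero")
})

test_that("Spearman correlation handles monotone, inverted and null cases", {
  x <- c(1, 3, 4, 7, 11, 15)
  expect_equal(spearmanRho(x, x^3 + 2)$rho, 1)
  expect_equal(spearmanRho(x, -x)$rho, -1)
  withr::with_seed(21, {
    r <- spearmanRho(stats::rnorm(100), stats::rnorm(100))
    expect_lt(abs(r$rho), 0.2)
    expect_gt(r$p_value, 0.05)
  })
  expect_equal(spearmanRho(rep(1, 10), 1:10)$flag, "constant_vector")
  expect_error(spearmanRho(1:2, 1:2), ">= 3")
})

test_that("intra-assay CV averages per-sample replicate CVs", {
  ident <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                      value = rep(c(4, 9), each = 3))
  expect_equal(intraAssayCV(ident)$mean_cv_pct, 0)

  two <- data.frame(sample_id = c("a", "a"), value = c(9, 11))
  expect_equal(intraAssayCV(two)$mean_cv_pct, 100 * sqrt(2) / 10,
               tolerance = 1e-10)  # 14.14%

  withr::with_seed(41, {
    # duplicate-based sample SDs carry the c4(2) = sqrt(2/pi) bias, so the
    # generator noise is scaled so the duplicate-derived CV targets 6.5%
    n <- 400
    sdRel <- 0.065 / sqrt(2 / pi)
    plate <- data.frame(sample_id = rep(seq_len(n), each = 2),
                        plate = rep(rep(1:3, length.out = n), each = 2),
                        value = 50 * (1 + stats::rnorm(2 * n, 0, sdRel)))
    cv <- intraAssayCV(plate)$mean_cv_pct
    expect_equal(cv, 6.5, tolerance = 0.05)
  })
  zm <- data.frame(sample_id = c("z", "z"), value = c(0, 0))
  expect_equal(intraAssayCV(zm)$perSample$flag, "zero_mean")
})

test_that("the viscometer replicate filter drops the lowest flow rate", {
  seg <- data.frame(flow_rate = c(50, 50, 75, 75, 100, 100, 125),
                    viscosity = 1:7)
  r <- viscometerReplicateFilter(seg)
  expect_equal(nrow(r$retained), 5L)
  expect_equal(nrow(r$removed), 2L)
  expect_equal(r$flag, "")

  one <- viscometerReplicateFilter(data.frame(flow_rate = c(50, 50),
                                              viscosity = 1:2))
  expect_equal(nrow(one$retained), 0L)
  expect_equal(one$flag, "all_segments_removed")

  pairR <- viscometerReplicateFilter(data.frame(flow_rate = c(50, 75),
                                                viscosity = 1:2))
  expect_equal(pairR$retained$viscosity, 2)
})

test_that("serial dilution factors multiply", {
  expect_equal(serialDilutionFactor(c(20, 100)), 2000)
  expect_equal(serialDilutionFactor(80000), 80000)
  expect_error(serialDilutionFactor(numeric(0)), "no dilution")
  expect_error(serialDilutionFactor(c(20, -1)), "positive")
})

test_that("runCohortAnalysis handles single groups and empty columns", {
  d <- data.frame(sample_id = sprintf("s%d", 1:6),
                  group = rep("healthy", 6),
                  mw_kda = c(3000, 3500, 4000, 3600, 3900, 3300),
                  empty = NA_real_)
  ct <- CohortTable(d, c(mw_kda = "kDa"))
  expect_warning(res <- runCohortAnalysis(ct), "empty")
  expect_equal(res$tests$mw_kda$path, "summary_only")
  expect_true("empty" %in% res$skipped)
})
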