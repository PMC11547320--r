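# The MR estimator suite.

test_that("Wald ratio arithmetic and its Monte-Carlo delta-method SE", {
  w <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$ratio, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(waldRatio(0.1, 0.01, 0, 0.01)$ratio, 0)
  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "zero exposure")

  # first-order SE vs the SD of simulated ratios when se_exp << |beta_exp|
  set.seed(5)
  n <- 1e6
  bx <- rnorm(n, 0.2, 0.002)  # 1% relative error on the exposure side
  by <- rnorm(n, 0.06, 0.01)
  expect_equal(waldRatio(0.2, 0.002, 0.06, 0.01)$se, sd(by / bx),
               tolerance = 0.02)
})

test_that("IVW matches hand arithmetic and the WLS closed form", {
  # degenerate homogeneity
  hd0 <- makeHarmonized(rep(0.5, 4))
  e0 <- mrIvw(hd0)
  expect_equal(e0@beta, 0.5)
  expect_equal(e0@heterogeneity@q, 0, tolerance = 1e-20)
  expect_equal(e0@extras$phi, 1)

  # weighted mean forced by the weights: (0.4*100 + 0.8*25) / 125 = 0.48
  hd1 <- makeHarmonized(c(0.4, 0.8), ratioSes = c(0.1, 0.2))
  expect_equal(mrIvw(hd1)@beta, 0.48)

  # 9-SNP fixture vs direct weighted-least-squares without intercept
  set.seed(21)
  hd <- harmonizedData(sprintf("rs%d", 1:9), betaExp = runif(9, 0.02, 0.1),
                       seExp = runif(9, 0.002, 0.005),
                       betaOut = rnorm(9, 0.03, 0.01),
                       seOut = runif(9, 0.005, 0.02))
  est <- mrIvw(hd)
  s <- snpData(hd)
  w <- 1 / s$se_out^2
  o <- wlsSolve(s$beta_out, cbind(s$beta_exp), w)
  expect_equal(est@beta, o$coef[1], tolerance = 1e-10)
  phi <- max(1, est@heterogeneity@q / (nSnp(hd) - 1))
  expect_equal(est@se, o$se[1] * sqrt(phi), tolerance = 1e-10)

  expect_error(mrIvw(makeHarmonized(0.5)), "at least 2")
})

test_that("MR-Egger recovers exact fits and matches the WLS closed form", {
  bx <- c(0.02, 0.04, 0.06, 0.08, 0.1)
  # noise-free proportional data: slope 0.3, intercept 0
  hd <- harmonizedData(sprintf("rs%d", 1:5), bx, rep(0.003, 5),
                       0.3 * bx, rep(0.01, 5))
  e <- mrEgger(hd)
  expect_equal(e@beta, 0.3, tolerance = 1e-10)
  expect_equal(e@extras$intercept, 0, tolerance = 1e-12)

  # constant directional pleiotropy appears in the intercept
  hd2 <- harmonizedData(sprintf("rs%d", 1:5), bx, rep(0.003, 5),
                        0.3 * bx + 0.01, rep(0.01, 5))
  e2 <- mrEgger(hd2)
  expect_equal(e2@beta, 0.3, tolerance = 1e-10)
  expect_equal(e2@extras$intercept, 0.01, tolerance = 1e-10)

  # 10-SNP noisy fixture vs the weighted normal equations (with the
  # multiplicative residual floor applied to both SEs)
  set.seed(31)
  bx10 <- runif(10, 0.02, 0.1)
  hd3 <- harmonizedData(sprintf("rs%d", 1:10), bx10, rep(0.003, 10),
                        0.25 * bx10 + rnorm(10, 0, 0.01),
                        runif(10, 0.005, 0.02))
  e3 <- mrEgger(hd3)
  s <- snpData(hd3)
  w <- 1 / s$se_out^2
  o <- wlsSolve(s$beta_out, cbind(1, s$beta_exp), w)
  res <- s$beta_out - cbind(1, s$beta_exp) %*% o$coef
  sigma2 <- sum(w * res^2) / (10 - 2)
  expect_equal(e3@beta, o$coef[2], tolerance = 1e-10)
  expect_equal(e3@se, o$se[2] * sqrt(max(1, sigma2)), tolerance = 1e-10)
  expect_equal(e3@extras$intercept, o$coef[1], tolerance = 1e-10)
  expect_equal(e3@extras$intercept_se, o$se[1] * sqrt(max(1, sigma2)),
               tolerance = 1e-10)

  # negative exposure effects are re-oriented, not sign-flipped in the slope
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  hd4 <- harmonizedData(sprintf("rs%d", 1:10), s$beta_exp * flip,
                        s$se_exp, s$beta_out * flip, s$se_out)
  expect_equal(mrEgger(hd4)@beta, e3@beta, tolerance = 1e-12)

  expect_error(mrEgger(makeHarmonized(c(0.1, 0.2))), "at least 3")
})

test_that("weighted median interpolates the 50th weighted percentile", {
  # symmetric equal weights
  expect_equal(mrWeightedMedian(makeHarmonized(c(0.1, 0.5, 0.9)),
                                bootReps = 50, seed = 1)@beta, 0.5)
  # degenerate: all ratios equal
  eq <- mrWeightedMedian(makeHarmonized(rep(0.7, 5)), bootReps = 200,
                         seed = 2)
  expect_equal(eq@beta, 0.7)
  expect_lt(eq@se, 0.05)

  # 4 unequal weights: hand-computed interpolation point.
  # ratios (0.1, 0.3, 0.6, 1.0), weights (0.4, 0.1, 0.2, 0.3):
  # percentiles p_j = (0.2, 0.45, 0.6, 0.85); 0.5 interpolates to
  # 0.3 + (0.05/0.15) * 0.3 = 0.4
  ratios <- c(0.1, 0.3, 0.6, 1.0)
  wts <- c(0.4, 0.1, 0.2, 0.3)
  hd <- makeHarmonized(ratios, ratioSes = 1 / sqrt(wts))
  est <- mrWeightedMedian(hd, bootReps = 50, seed = 3)
  expect_equal(est@beta, 0.4, tolerance = 1e-12)
  expect_equal(est@extras$seed, 3)
  expect_error(mrWeightedMedian(makeHarmonized(c(0.1, 0.2)), 10, 1),
               "at least 3")
})

test_that("weighted mode finds the dominant ratio cluster", {
  hdc <- makeHarmonized(rep(0.42, 6))
  expect_equal(mrWeightedMode(hdc, bootReps = 50, seed = 1)@beta, 0.42,
               tolerance = 1e-9)

  set.seed(8)
  ratios <- c(rnorm(6, 0.5, 0.02), rnorm(3, 2.0, 0.02))
  hd <- makeHarmonized(ratios)
  est <- mrWeightedMode(hd, bootReps = 50, seed = 2)
  h <- mad(ratios) * length(ratios)^(-1 / 5)
  expect_lt(abs(est@beta - 0.5), max(h, 0.1))

  # scale invariance: doubling all weights leaves the estimate unchanged
  hd2 <- makeHarmonized(ratios, ratioSes = rep(0.05, 9) / sqrt(2))
  expect_equal(mrWeightedMode(hd2, bootReps = 50, seed = 2)@beta, est@beta)
})

test_that("pIVW reduces to the ratio-of-sums IVW when exposure error vanishes", {
  set.seed(41)
  k <- 8
  bx <- runif(k, 0.03, 0.1)
  by <- 0.4 * bx + rnorm(k, 0, 0.005)
  sy <- runif(k, 0.005, 0.02)
  hd <- harmonizedData(sprintf("rs%d", 1:k), bx, rep(0, k), by, sy)
  plain <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  expect_equal(mrPivw(hd, lambda = 0)@beta, plain, tolerance = 1e-12)
  expect_equal(mrPivw(hd, lambda = 1)@beta, plain, tolerance = 1e-12)
  expect_error(mrPivw(makeHarmonized(0.3)), "at least 2")
})

test_that("MR-PRESSO flags an injected outlier and is definitionally consistent", {
  set.seed(55)
  k <- 9
  bx <- runif(k, 0.04, 0.1)
  sy <- rep(0.01, k)
  by <- 0.3 * bx + rnorm(k, 0, 0.004)
  by[4] <- by[4] + 10 * sy[4]   # 10-SE spike
  hd <- harmonizedData(sprintf("rs%d", 1:k), bx, rep(0.003, k), by, sy)
  pr <- mrPresso(hd, nSim = 500, seed = 10)
  expect_true(sprintf("rs%d", 4) %in% pr$outliers)
  expect_lt(pr$globalP, 0.05)

  # corrected estimate is exactly IVW on the remaining SNPs
  keep <- !(snpData(hd)$rsid %in% pr$outliers)
  s <- snpData(hd)
  sub <- harmonizedData(s$rsid[keep], s$beta_exp[keep], s$se_exp[keep],
                        s$beta_out[keep], s$se_out[keep])
  expect_equal(pr$corrected@beta, mrIvw(sub)@beta, tolerance = 1e-12)
  expect_equal(pr$corrected@se, mrIvw(sub)@se, tolerance = 1e-12)
  expect_false(is.na(pr$distortionP))

  # clean data with a fixed seed: no outliers, corrected equals raw
  by2 <- 0.3 * bx + rnorm(k, 0, 0.002)
  hd2 <- harmonizedData(sprintf("rs%d", 1:k), bx, rep(0.003, k), by2, sy)
  pr2 <- mrPresso(hd2, nSim = 500, seed = 11)
  expect_length(pr2$outliers, 0)
  expect_equal(pr2$corrected@beta, pr2$raw@beta)
  expect_true(isTRUE(pr2$corrected@extras$no_outliers))
  expect_error(mrPresso(makeHarmonized(c(1, 2, 3))), "at least 4")
})

test_that("leave-one-out produces one IVW row per omitted SNP", {
  hd0 <- makeHarmonized(rep(0.5, 6))
  loo0 <- leaveOneOut(hd0)
  expect_equal(nrow(loo0), 6)
  expect_true(all(abs(loo0$beta - 0.5) < 1e-12))  # homogeneity

  # the row omitting an extreme SNP deviates most from the full estimate
  hd <- makeHarmonized(c(rep(0.5, 8), 3.0))
  full <- mrIvw(hd)@beta
  loo <- leaveOneOut(hd)
  expect_equal(nrow(loo), 9)
  dev <- abs(loo$beta - full)
  expect_equal(loo$rsid_omitted[which.max(dev)], "rs009")
  # recompute by hand: omitting the outlier leaves the homogeneous 0.5
  expect_equal(loo$beta[loo$rsid_omitted == "rs009"], 0.5, tolerance = 1e-12)
  expect_error(leaveOneOut(makeHarmonized(c(0.1, 0.2))), "at least 3")
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(61)
  k <- 10
  bx <- runif(k, 0.03, 0.1)
  hd <- harmonizedData(sprintf("rs%d", 1:k), bx, rep(0.004, k),
                       0.35 * bx + rnorm(k, 0, 0.01),
                       runif(k, 0.008, 0.02))
  s <- snpData(hd)
  neg <- harmonizedData(s$rsid, s$beta_exp, s$se_exp, -s$beta_out, s$se_out)
  cc <- 2.5
  scl <- harmonizedData(s$rsid, cc * s$beta_exp, cc * s$se_exp, s$beta_out,
                        s$se_out)
  fits <- list(ivw = mrIvw, egger = mrEgger, pivw = mrPivw,
               wmed = function(h) mrWeightedMedian(h, bootReps = 50, seed = 1),
               wmode = function(h) mrWeightedMode(h, bootReps = 50, seed = 1))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    base <- f(hd); negd <- f(neg); scld <- f(scl)
    expect_equal(negd@beta, -base@beta, tolerance = 1e-8, label = nm)
    expect_equal(scld@beta, base@beta / cc, tolerance = 1e-8, label = nm)
    if (nm %in% c("ivw", "egger", "pivw"))
      expect_equal(negd@se, base@se, tolerance = 1e-10, label = nm)
  }
})

test_that("point estimators agree under no pleiotropy with strong instruments", {
  # 1500-replicate simulation (scaled down from 5000 for runtime); the
  # per-method means must agree within 2 Monte-Carlo SEs of each other.
  # nExp = 5e6 keeps MR-Egger's regression-dilution attenuation (driven
  # by exposure-side noise relative to the spread of the true SNP effects)
  # well below the Monte-Carlo resolution of the comparison
  reps <- 1500
  res <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("ivw", "egger", "wmed", "wmode",
                                        "pivw")))
  for (i in seq_len(reps)) {
    cfg <- simConfig(k = 9, nExp = 5e6, nOut = 5e5,
                     traitTypeOut = "quantitative", trueBeta = 0.25,
                     r2Total = 0.02, seed = 7000 + i)
    d <- generateMrDataset(cfg)
    hd <- harmonize(d$exposure, d$outcome, snpData(d$exposure)$rsid)
    s <- snpData(hd)
    rat <- s$beta_out / s$beta_exp
    rse <- s$se_out / abs(s$beta_exp)
    res[i, "ivw"] <- mrIvw(hd)@beta
    res[i, "egger"] <- mrEgger(hd)@beta
    res[i, "wmed"] <- mrpipe:::weightedMedianEstimate(rat, 1 / rse^2)
    res[i, "wmode"] <- mrpipe:::weightedModeEstimate(rat, 1 / rse^2)
    res[i, "pivw"] <- mrPivw(hd)@beta
  }
  means <- colMeans(res)
  mcse <- apply(res, 2, sd) / sqrt(reps)
  for (a in colnames(res)) for (b in colnames(res)) {
    if (a >= b) next
    expect_lt(abs(means[a] - means[b]),
              2 * sqrt(mcse[a]^2 + mcse[b]^2) + 1e-4)
  }
})
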