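# Meta-analysis, sex-difference test, Bonferroni classification, power.

mkEst <- function(beta, se) {
  new("MrEstimate", method = "ivw", beta = beta, se = se,
      ciLow = beta - 1.96 * se, ciHigh = beta + 1.96 * se,
      pval = 2 * pnorm(-abs(beta / se)), nSnp = 9, orScale = numeric(),
      extras = list(), heterogeneity = new("HeterogeneityStat"))
}

test_that("fixed-effect pooling matches hand arithmetic and I2 closed form", {
  # identical estimates: pooled unchanged, no heterogeneity
  m0 <- metaFixed(list(mkEst(0.3, 0.1), mkEst(0.3, 0.1)))
  expect_equal(m0@beta, 0.3)
  expect_equal(m0@q, 0)
  expect_equal(m0@i2, 0)

  # q = 1.730, df = 1  ->  I2 = (q - 1)/q * 100 = 42.2%
  # engineer two estimates with exactly that Q: equal SEs s, difference d:
  # q = d^2 / (2 s^2)
  s <- 0.1
  d <- sqrt(1.730 * 2 * s^2)
  m1 <- metaFixed(list(mkEst(0.2, s), mkEst(0.2 + d, s)))
  expect_equal(m1@q, 1.730, tolerance = 1e-12)
  expect_equal(m1@i2, (1.730 - 1) / 1.730 * 100, tolerance = 1e-9)
  expect_equal(round(m1@i2, 1), 42.2)

  # three estimates vs hand-computed weighted mean/variance
  b <- c(0.5, 0.2, 0.35); se <- c(0.1, 0.05, 0.2)
  m2 <- metaFixed(list(mkEst(b[1], se[1]), mkEst(b[2], se[2]),
                       mkEst(b[3], se[3])))
  w <- 1 / se^2
  expect_equal(m2@beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m2@se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(m2@q, sum(w * (b - m2@beta)^2), tolerance = 1e-12)
  expect_equal(m2@df, 2)
  expect_equal(m2@pHet, pchisq(m2@q, 2, lower.tail = FALSE))

  expect_error(metaFixed(list(mkEst(0.3, 0.1))), "at least 2")
})

test_that("I2 is scale-invariant and zero below the df threshold", {
  b <- c(0.4, 0.1); se <- c(0.12, 0.07)
  m <- metaFixed(data.frame(beta = b, se = se))
  mScaled <- metaFixed(data.frame(beta = 3 * b, se = 3 * se))
  expect_equal(m@i2, mScaled@i2, tolerance = 1e-12)
  # nearly identical estimates (q < 1) give i2 = 0
  mLow <- metaFixed(data.frame(beta = c(0.30, 0.31), se = c(0.1, 0.1)))
  expect_lt(mLow@q, 1)
  expect_equal(mLow@i2, 0)
})

test_that("sex-difference test equals the two-group heterogeneity p", {
  expect_equal(sexDifferenceTest(mkEst(0.3, 0.1), mkEst(0.3, 0.1)), 1)

  # z = (0.5 - 0.1)/sqrt(0.02) = 2.8284..., p ~ 0.00468
  p <- sexDifferenceTest(mkEst(0.5, 0.1), mkEst(0.1, 0.1))
  expect_equal(p, 2 * pnorm(-0.4 / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(round(p, 4), 0.0047)

  # algebraic equivalence with Cochran's Q on the same two estimates
  set.seed(3)
  for (i in 1:10) {
    e1 <- mkEst(rnorm(1), runif(1, 0.05, 0.3))
    e2 <- mkEst(rnorm(1), runif(1, 0.05, 0.3))
    expect_equal(sexDifferenceTest(e1, e2), metaFixed(list(e1, e2))@pHet,
                 tolerance = 1e-12)
  }
  expect_error(sexDifferenceTest(mkEst(0.1, 0.1), NULL), "required")
})

test_that("Bonferroni classification reproduces the 0.05/15 rule", {
  cls <- classifySignificance(c(a = 0.0005, b = 0.04, c = 0.2), nTests = 15)
  expect_equal(unname(cls), c("significant", "suggestive", "null"),
               ignore_attr = TRUE)
  thr <- attr(cls, "threshold")
  expect_equal(thr, 0.05 / 15)
  expect_equal(signif(thr, 1), 0.003)
  # no correction with a single test
  expect_equal(attr(classifySignificance(c(x = 0.2), 1), "threshold"), 0.05)
  # monotonicity: lowering a p-value never demotes its class
  rank <- c(null = 0, suggestive = 1, significant = 2)
  p <- seq(0.0001, 0.9, length.out = 50)
  cl <- rank[classifySignificance(setNames(p, paste0("o", 1:50)), 15)]
  expect_true(all(diff(cl) <= 0))
})

test_that("minimum detectable effect follows the normal-approximation formula", {
  pr <- minDetectableEffect(n = 5e5, caseFraction = 0.2, r2 = 0.005)
  se <- 1 / sqrt(5e5 * 0.005 * 0.2 * 0.8)
  expect_equal(pr@minDetectableBeta, (qnorm(0.975) + qnorm(0.8)) * se,
               tolerance = 1e-12)
  expect_equal(pr@minDetectableOr, exp(pr@minDetectableBeta))
  # multiplier is z_0.975 + z_0.8
  expect_equal(pr@minDetectableBeta / se, 1.959964 + 0.8416212,
               tolerance = 1e-6)
  # doubling r2 divides the detectable effect by sqrt(2)
  pr2 <- minDetectableEffect(n = 5e5, caseFraction = 0.2, r2 = 0.01)
  expect_equal(pr@minDetectableBeta / pr2@minDetectableBeta, sqrt(2),
               tolerance = 1e-12)
  # monotone decreasing in n
  expect_lt(minDetectableEffect(n = 1e6, caseFraction = 0.2,
                                r2 = 0.005)@minDetectableBeta,
            pr@minDetectableBeta)
  expect_error(minDetectableEffect(n = 1e5, caseFraction = 0, r2 = 0.005),
               "caseFraction")
  expect_error(minDetectableEffect(n = 1e5, r2 = 1.5), "r2")
})

test_that("empirical power at the minimum detectable OR is near the target", {
  # 2000 simulated MR analyses at the returned effect size; the rejection
  # rate at alpha = 0.05 must land in [75%, 85%] around the 80% target.
  n <- 3e5; cf <- 0.25; r2 <- 0.004
  mde <- minDetectableEffect(n = n, caseFraction = cf, r2 = r2)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    cfg <- simConfig(k = 9, nExp = 5e5, nOut = n, caseFraction = cf,
                     trueBeta = mde@minDetectableBeta, r2Total = r2,
                     seed = 40000 + i)
    d <- generateMrDataset(cfg)
    hd <- harmonize(d$exposure, d$outcome, snpData(d$exposure)$rsid)
    est <- mrIvw(hd)
    # the power formula models the fixed-effect sampling error, so the
    # check uses the fixed-effect z (over-dispersion scale undone)
    zFixed <- est@beta / (est@se / sqrt(est@extras$phi))
    rej[i] <- 2 * pnorm(-abs(zFixed)) < 0.05
  }
  expect_gte(mean(rej), 0.75)
  expect_lte(mean(rej), 0.85)
})
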