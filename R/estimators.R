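# The MR estimator suite. All estimators operate on HarmonizedData and
# return MrEstimate objects; p-values are two-sided normal throughout
# (summary-data MR convention), and for binary outcomes the log-odds
# estimate and CI are also reported exponentiated as an odds ratio per SD
# of exposure.

Z95 <- qnorm(0.975)

# Assemble an MrEstimate from a point estimate and SE.
makeEstimate <- function(method, beta, se, nSnp, outcomeType,
                         extras = list(), heterogeneity = NULL) {
  ciLow <- beta - Z95 * se
  ciHigh <- beta + Z95 * se
  orScale <- if (identical(outcomeType, "binary"))
    c(or = exp(beta), or_ci_low = exp(ciLow), or_ci_high = exp(ciHigh))
  else numeric()
  if (is.null(heterogeneity)) heterogeneity <- new("HeterogeneityStat")
  new("MrEstimate", method = method, beta = beta, se = se, ciLow = ciLow,
      ciHigh = ciHigh, pval = max(zPvalue(beta, se), .Machine$double.xmin),
      nSnp = as.numeric(nSnp), orScale = orScale, extras = extras,
      heterogeneity = heterogeneity)
}

ratioStats <- function(hd) {
  s <- hd@snps
  if (any(s$beta_exp == 0))
    stop("Wald ratio undefined: zero SNP-exposure effect", call. = FALSE)
  list(ratio = s$beta_out / s$beta_exp, se = s$se_out / abs(s$beta_exp))
}

checkMinSnps <- function(hd, k, what) {
  if (nSnp(hd) < k)
    stop(sprintf("%s needs at least %d instruments (have %d)", what, k,
                 nSnp(hd)), call. = FALSE)
}

#' Wald ratio and its first-order standard error
#'
#' Per-SNP causal estimate: the SNP-outcome association divided by the
#' SNP-exposure association, with the first-order delta-method standard
#' error \eqn{se_{out}/|\beta_{exp}|} (exposure-side sampling error is
#' ignored, the standard default; adequate when instruments are strong).
#'
#' @param betaExp,seExp SNP-exposure effect and SE (vectorized; seExp
#'   accepted for interface symmetry, unused by the first-order SE).
#' @param betaOut,seOut SNP-outcome effect and SE.
#' @return data.frame with columns \code{ratio} and \code{se}.
#' @examples
#' waldRatio(0.1, 0.01, 0.05, 0.01)  # ratio 0.5, se 0.1
#' @export
waldRatio <- function(betaExp, seExp, betaOut, seOut) {
  if (any(betaExp == 0))
    stop("Wald ratio undefined for zero exposure effect", call. = FALSE)
  data.frame(ratio = betaOut / betaExp, se = seOut / abs(betaExp))
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Pools per-SNP Wald ratios with weights \eqn{w_j = 1/se_j^2} (first-order
#' ratio SEs). The standard error is inflated by the square root of the
#' over-dispersion scale \eqn{\phi = \max(1, Q/(k-1))} (multiplicative
#' random effects, floored at 1 so under-dispersion never shrinks the SE).
#' Equivalent to weighted least squares of the outcome effects on the
#' exposure effects without intercept, weights \eqn{1/se_{out}^2}.
#'
#' @param hd a \code{\link{HarmonizedData}} with at least 2 SNPs.
#' @return an \code{\linkS4class{MrEstimate}} (method \code{"ivw"}) whose
#'   \code{heterogeneity} slot carries Cochran's Q with k - 1 df and whose
#'   \code{extras$phi} is the over-dispersion scale.
#' @export
mrIvw <- function(hd) {
  checkMinSnps(hd, 2, "IVW")
  r <- ratioStats(hd)
  w <- 1 / r$se^2
  beta <- sum(w * r$ratio) / sum(w)
  k <- length(w)
  q <- sum(w * (r$ratio - beta)^2)
  phi <- max(1, q / (k - 1))
  se <- sqrt(phi / sum(w))
  het <- new("HeterogeneityStat", q = q, df = k - 1,
             pval = pchisq(q, df = k - 1, lower.tail = FALSE))
  makeEstimate("ivw", beta, se, k, hd@outcomeType,
               extras = list(phi = phi), heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted linear regression of SNP-outcome effects on SNP-exposure
#' effects with an intercept, weights \eqn{1/se_{out}^2}, after orienting
#' every SNP so its exposure effect is positive. The slope estimates the
#' causal effect; the intercept estimates the average directional
#' (horizontal) pleiotropy, and its two-sided test is reported in
#' \code{extras} (\code{intercept}, \code{intercept_se}, \code{intercept_p}).
#' Both standard errors are inflated by \eqn{\max(1, \hat\sigma)} where
#' \eqn{\hat\sigma^2} is the weighted residual scale (multiplicative random
#' effects floored at 1).
#'
#' @param hd a \code{HarmonizedData} with at least 3 SNPs.
#' @return an \code{MrEstimate} (method \code{"egger"}); heterogeneity Q has
#'   k - 2 df.
#' @export
mrEgger <- function(hd) {
  checkMinSnps(hd, 3, "MR-Egger")
  s <- hd@snps
  flip <- sign(s$beta_exp)
  flip[flip == 0] <- 1
  bx <- s$beta_exp * flip
  by <- s$beta_out * flip
  w <- 1 / s$se_out^2
  fit <- lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # lm's SEs include sigma; refloor the residual scale at 1
  adj <- 1 / min(1, sigma)
  slope <- co["bx", "Estimate"]
  slopeSe <- co["bx", "Std. Error"] * adj
  inter <- co["(Intercept)", "Estimate"]
  interSe <- co["(Intercept)", "Std. Error"] * adj
  k <- nrow(s)
  q <- sum(w * fit$residuals^2)
  het <- new("HeterogeneityStat", q = q, df = k - 2,
             pval = pchisq(q, df = k - 2, lower.tail = FALSE))
  makeEstimate("egger", slope, slopeSe, k, hd@outcomeType,
               extras = list(intercept = inter, intercept_se = interSe,
                             intercept_p = zPvalue(inter, interSe),
                             sigma = sigma),
               heterogeneity = het)
}

# Weighted-percentile point estimate used by the weighted median: sort the
# ratios, assign cumulative percentiles p_j = cumsum(w) - w/2 (w
# normalized), and linearly interpolate the ratio at percentile 0.5.
weightedMedianEstimate <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Shared parametric bootstrap: redraw beta_exp and beta_out from normals
# centered at the observed values, recompute the point estimate, return the
# SD over bootReps replicates.
parametricBootSe <- function(hd, bootReps, seed, pointFun) {
  s <- hd@snps
  k <- nrow(s)
  withSeed(seed, {
    ests <- vapply(seq_len(bootReps), function(b) {
      bx <- rnorm(k, s$beta_exp, s$se_exp)
      by <- rnorm(k, s$beta_out, s$se_out)
      bx[bx == 0] <- .Machine$double.eps
      pointFun(by / bx, s$se_out / abs(bx))
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios: consistent as long as at
#' least half the weight comes from valid instruments. The point estimate
#' interpolates the ratio at the 50th weighted percentile (weights
#' \eqn{1/se_j^2}, normalized); the standard error comes from a parametric
#' bootstrap that redraws the SNP-exposure and SNP-outcome effects from
#' their sampling distributions.
#'
#' @param hd a \code{HarmonizedData} with at least 3 SNPs.
#' @param bootReps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in \code{extras}.
#' @return an \code{MrEstimate} (method \code{"weighted_median"}).
#' @export
mrWeightedMedian <- function(hd, bootReps = 1000, seed = NULL) {
  checkMinSnps(hd, 3, "weighted median")
  r <- ratioStats(hd)
  est <- weightedMedianEstimate(r$ratio, 1 / r$se^2)
  se <- parametricBootSe(hd, bootReps, seed,
                         function(rat, rse) weightedMedianEstimate(rat, 1 / rse^2))
  makeEstimate("weighted_median", est, se, nSnp(hd), hd@outcomeType,
               extras = list(boot_reps = bootReps, seed = seed))
}

# Mode of a weighted normal-kernel density over a dense grid. Bandwidth is
# bandwidthFactor times a MAD-based robust spread of the ratios, shrunk
# with k^(-1/5) (normal reference rate).
weightedModeEstimate <- function(ratios, weights, bandwidthFactor = 1) {
  w <- weights / sum(weights)
  s <- mad(ratios)
  if (s == 0) s <- stats::sd(ratios)
  if (!is.finite(s) || s == 0) return(ratios[1])
  h <- bandwidthFactor * s * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 1024)
  dens <- as.vector(w %*% dnorm(outer(ratios, grid, "-") / h))
  grid[which.max(dens)]
}

#' Weighted-mode causal estimate
#'
#' The mode of the inverse-variance-weighted kernel density of the per-SNP
#' Wald ratios: consistent when the largest group of instruments sharing a
#' ratio value is the valid one (no majority of invalid instruments needs to
#' agree). Standard error by the same parametric bootstrap as the weighted
#' median.
#'
#' @param hd a \code{HarmonizedData} with at least 3 SNPs.
#' @param bandwidthFactor multiplier on the MAD-based kernel bandwidth
#'   (default 1).
#' @param bootReps bootstrap replicates (default 1000).
#' @param seed RNG seed, recorded in \code{extras}.
#' @return an \code{MrEstimate} (method \code{"weighted_mode"}).
#' @export
mrWeightedMode <- function(hd, bandwidthFactor = 1, bootReps = 1000,
                           seed = NULL) {
  checkMinSnps(hd, 3, "weighted mode")
  r <- ratioStats(hd)
  est <- weightedModeEstimate(r$ratio, 1 / r$se^2, bandwidthFactor)
  se <- parametricBootSe(hd, bootReps, seed, function(rat, rse)
    weightedModeEstimate(rat, 1 / rse^2, bandwidthFactor))
  makeEstimate("weighted_mode", est, se, nSnp(hd), hd@outcomeType,
               extras = list(bandwidth_factor = bandwidthFactor,
                             boot_reps = bootReps, seed = seed))
}

#' Penalized debiased IVW estimate
#'
#' Weak-instrument-robust IVW. The numerator is
#' \eqn{\sum_j \beta_{Xj}\beta_{Yj}/\sigma_{Yj}^2}; the denominator is the
#' debiased instrument-strength sum
#' \eqn{\hat\mu = \sum_j (\beta_{Xj}^2 - \sigma_{Xj}^2)/\sigma_{Yj}^2},
#' which removes the exposure measurement-error term that attenuates plain
#' IVW, penalized as \eqn{\hat\mu_\lambda = (\hat\mu + \sqrt{\hat\mu^2 +
#' 4\lambda\hat v})/2} (with \eqn{\hat v} an estimate of
#' \eqn{Var(\hat\mu)}) so the denominator stays bounded away from zero even
#' when instruments are very weak. The variance estimator includes a
#' balanced-horizontal-pleiotropy component \eqn{\tau^2} estimated by
#' method of moments. With all \eqn{\sigma_{Xj} = 0} the estimator reduces
#' exactly to the plain IVW ratio of sums.
#'
#' @param hd a \code{HarmonizedData} with at least 2 SNPs and exposure SEs.
#' @param lambda penalty parameter (default 1).
#' @return an \code{MrEstimate} (method \code{"pivw"}); \code{extras} holds
#'   \code{lambda}, the pleiotropy variance \code{tau2} and the effective
#'   instrument-strength statistic \code{kappa} =
#'   \eqn{\hat\mu/\sqrt{\hat v}}.
#' @export
mrPivw <- function(hd, lambda = 1) {
  checkMinSnps(hd, 2, "pIVW")
  s <- hd@snps
  if (anyNA(s$se_exp)) stop("pIVW requires exposure SEs for all SNPs", call. = FALSE)
  bx <- s$beta_exp; sx <- s$se_exp
  by <- s$beta_out; sy <- s$se_out
  num <- sum(bx * by / sy^2)
  mu <- sum((bx^2 - sx^2) / sy^2)
  gamma2 <- pmax(bx^2 - sx^2, 0)            # plug-in for the true gamma_j^2
  v <- sum((2 * sx^4 + 4 * sx^2 * gamma2) / sy^4)
  muPen <- (mu + sqrt(mu^2 + 4 * lambda * v)) / 2
  beta <- num / muPen

  # balanced-pleiotropy variance: E[(beta_Yj - beta*beta_Xj)^2] =
  # tau^2 + sigma_Yj^2 + beta^2 sigma_Xj^2
  res <- by - beta * bx
  wy <- 1 / sy^2
  tau2 <- max(0, sum(wy * (res^2 - sy^2 - beta^2 * sx^2)) / sum(wy))
  sy2t <- sy^2 + tau2
  varTerms <- (gamma2 * sy2t + beta^2 * gamma2 * sx^2 + sx^2 * sy2t +
                 2 * beta^2 * sx^4) / sy^4
  se <- sqrt(sum(varTerms)) / muPen
  kappa <- if (v > 0) mu / sqrt(v) else Inf
  makeEstimate("pivw", beta, se, nrow(s), hd@outcomeType,
               extras = list(lambda = lambda, tau2 = tau2, kappa = kappa))
}

# Simple fixed-effect IVW slope (no over-dispersion), used internally by
# MR-PRESSO for its leave-one-out fits.
fixedSlope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares (RSS) from
#' leave-one-out IVW fits is compared against its null distribution from
#' \code{nSim} parametric simulations under the fitted no-pleiotropy model.
#' When the global test is significant (p < 0.05), per-SNP outlier p-values
#' are taken from each SNP's simulated residual distribution,
#' Bonferroni-adjusted across SNPs; SNPs below \code{outlierP} are reported
#' as outliers and the corrected estimate is \code{\link{mrIvw}} on the
#' remaining SNPs. A distortion test (difference between raw and corrected
#' estimates against differences from removing random subsets of the same
#' size) is reported but never auto-applied.
#'
#' @param hd a \code{HarmonizedData} with at least 4 SNPs.
#' @param nSim parametric simulations for the null distribution
#'   (default 1000).
#' @param outlierP threshold on the Bonferroni-adjusted per-SNP p
#'   (default 0.05).
#' @param seed RNG seed, recorded in the estimates' \code{extras}.
#' @return list with elements \code{raw} and \code{corrected}
#'   (\code{MrEstimate}s, methods \code{presso_raw} / \code{presso_corrected}),
#'   \code{outliers} (character rsids), \code{globalP}, \code{distortionP}
#'   (NA when no outliers) and \code{outlierTable} (per-SNP p-values).
#' @export
mrPresso <- function(hd, nSim = 1000, outlierP = 0.05, seed = NULL) {
  checkMinSnps(hd, 4, "MR-PRESSO")
  s <- hd@snps
  k <- nrow(s)
  bx <- s$beta_exp; sx <- s$se_exp
  by <- s$beta_out; sy <- s$se_out
  w <- 1 / sy^2

  looSlope <- function(BX, BY) {
    # matrix rows = datasets; returns per-(dataset, snp) leave-one-out slope
    sxy <- as.vector((BX * BY) %*% w)
    sxx <- as.vector((BX^2) %*% w)
    num <- outer(sxy, rep(1, k)) - sweep(BX * BY, 2, w, "*")
    den <- outer(sxx, rep(1, k)) - sweep(BX^2, 2, w, "*")
    num / den
  }

  BXo <- matrix(bx, nrow = 1); BYo <- matrix(by, nrow = 1)
  bLooObs <- looSlope(BXo, BYo)[1, ]
  resObs <- by - bLooObs * bx
  statObs <- w * resObs^2
  rssObs <- sum(statObs)

  sim <- withSeed(seed, {
    BX <- matrix(rnorm(nSim * k, rep(bx, each = nSim), rep(sx, each = nSim)),
                 nrow = nSim)
    BY <- matrix(rnorm(nSim * k, rep(bLooObs * bx, each = nSim),
                       rep(sy, each = nSim)), nrow = nSim)
    bLoo <- looSlope(BX, BY)
    RES <- BY - bLoo * BX
    STAT <- sweep(RES^2, 2, w, "*")
    list(rss = rowSums(STAT), stat = STAT)
  })
  globalP <- (1 + sum(sim$rss >= rssObs)) / (nSim + 1)

  snpP <- vapply(seq_len(k), function(j)
    (1 + sum(sim$stat[, j] >= statObs[j])) / (nSim + 1), numeric(1))
  snpPAdj <- pmin(1, snpP * k)
  outlierTable <- data.frame(rsid = s$rsid, pval = snpP, pval_adj = snpPAdj)

  outliers <- character()
  if (globalP < 0.05) outliers <- s$rsid[snpPAdj < outlierP]

  raw <- mrIvw(hd)
  raw@method <- "presso_raw"
  raw@extras <- c(raw@extras, list(global_p = globalP, n_sim = nSim,
                                   seed = seed, outliers = outliers))
  validObject(raw)

  distortionP <- NA_real_
  if (length(outliers) && k - length(outliers) >= 2) {
    keep <- !(s$rsid %in% outliers)
    sub <- hd
    sub@snps <- s[keep, , drop = FALSE]
    corrected <- mrIvw(sub)
    corrected@method <- "presso_corrected"
    obsDiff <- raw@beta - corrected@beta
    m <- length(outliers)
    simDiff <- withSeed(childSeed(seed, "distortion"), {
      vapply(seq_len(min(nSim, 1000)), function(i) {
        drop <- sample.int(k, m)
        raw@beta - fixedSlope(bx[-drop], by[-drop], w[-drop])
      }, numeric(1))
    })
    distortionP <- mean(abs(simDiff) >= abs(obsDiff))
    corrected@extras <- list(global_p = globalP, distortion_p = distortionP,
                             outliers = outliers, n_sim = nSim, seed = seed)
    validObject(corrected)
  } else {
    corrected <- raw
    corrected@method <- "presso_corrected"
    corrected@extras <- c(corrected@extras, list(no_outliers = TRUE))
    validObject(corrected)
  }
  list(raw = raw, corrected = corrected, outliers = outliers,
       globalP = globalP, distortionP = distortionP,
       outlierTable = outlierTable)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn, to check
#' whether the pooled association is driven by a single SNP.
#'
#' @param hd a \code{HarmonizedData} with at least 3 SNPs.
#' @return data.frame with one row per omitted rsid: \code{rsid_omitted},
#'   \code{beta}, \code{se}, \code{ci_low}, \code{ci_high}, \code{pval}.
#' @export
leaveOneOut <- function(hd) {
  checkMinSnps(hd, 3, "leave-one-out")
  s <- hd@snps
  rows <- lapply(seq_len(nrow(s)), function(j) {
    sub <- hd
    sub@snps <- s[-j, , drop = FALSE]
    est <- mrIvw(sub)
    data.frame(rsid_omitted = s$rsid[j], beta = est@beta, se = est@se,
               ci_low = est@ciLow, ci_high = est@ciHigh, pval = est@pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
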