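# Synthetic GWAS summary statistics and colocalization regions with known
# ground truth. The generator's defaults state the emulated world: a
# nine-SNP instrument for a standardized metabolite measured in 121,577
# samples (the exposure GWAS scale), a large binary outcome GWAS
# (547,261 participants, case fraction 0.224, the larger of the two
# coronary-disease datasets), a protective causal odds ratio of 0.62 per SD,
# and instruments explaining 0.5% of exposure variance so that all per-SNP
# F-statistics clear the conventional weak-instrument threshold of 10.

#' SimConfig: parameters of the MR summary-statistics generator
#'
#' @slot k instrument count (>= 2).
#' @slot nExp,nOut exposure / outcome GWAS sample sizes.
#' @slot traitTypeOut \code{"quantitative"} or \code{"binary"}.
#' @slot caseFraction case fraction for binary outcomes.
#' @slot trueBeta causal effect per SD exposure (log OR for binary).
#' @slot r2Total target total exposure variance explained, in (0,1).
#' @slot pleiotropyMode \code{"none"}, \code{"balanced"} (alpha ~ N(0,
#'   sd^2)), \code{"directional"} (alpha ~ N(mean, sd^2)) or
#'   \code{"inside_violating"} (alpha = mean * gamma + N(0, sd^2), which
#'   correlates instrument strength with the direct effect).
#' @slot pleiotropySd,pleiotropyMean parameters of the pleiotropy
#'   distribution.
#' @slot pleiotropyFraction fraction of instruments receiving a pleiotropic
#'   effect (default 1; e.g. 0.4 gives "40 percent invalid instruments").
#' @slot nOutliers instruments whose outcome beta is shifted by
#'   \code{outlierShiftSds} outcome SEs.
#' @slot outlierShiftSds outlier shift magnitude in outcome-SE units.
#' @slot weakFraction fraction of instruments down-scaled to F ~ U(3, 8).
#' @slot injectPalindromic,injectAlleleSwaps counts of harmonization
#'   perturbations: A/T allele pairs (in both datasets) and
#'   swapped-effect-allele outcome records.
#' @slot seed RNG seed.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(k = "numeric", nExp = "numeric", nOut = "numeric",
                 traitTypeOut = "character", caseFraction = "numeric",
                 trueBeta = "numeric", r2Total = "numeric",
                 pleiotropyMode = "character", pleiotropySd = "numeric",
                 pleiotropyMean = "numeric", pleiotropyFraction = "numeric",
                 nOutliers = "numeric", outlierShiftSds = "numeric",
                 weakFraction = "numeric", injectPalindromic = "numeric",
                 injectAlleleSwaps = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  if (object@r2Total <= 0 || object@r2Total >= 1)
    msg <- c(msg, "r2Total must lie in (0,1)")
  if (object@r2Total / object@k > 0.5)
    msg <- c(msg, "infeasible r2Total: a single SNP cannot explain > 50% of variance")
  if (object@weakFraction < 0 || object@weakFraction > 1)
    msg <- c(msg, "weakFraction must lie in [0,1]")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional",
                                    "inside_violating"))
    msg <- c(msg, "unknown pleiotropyMode")
  if (!object@traitTypeOut %in% c("quantitative", "binary"))
    msg <- c(msg, "traitTypeOut must be 'quantitative' or 'binary'")
  if (object@traitTypeOut == "binary" &&
      (object@caseFraction <= 0 || object@caseFraction >= 1))
    msg <- c(msg, "caseFraction must lie in (0,1) for binary outcomes")
  if (object@injectPalindromic + object@injectAlleleSwaps > object@k)
    msg <- c(msg, "cannot perturb more SNPs than k")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' See \code{\linkS4class{SimConfig}} for the meaning of every parameter;
#' the defaults state the emulated study (nine strong instruments for a
#' standardized exposure measured in 121,577 samples, a large binary
#' outcome with causal OR 0.62 per SD, no pleiotropy).
#'
#' @param k,nExp,nOut,traitTypeOut,caseFraction,trueBeta,r2Total see class
#'   documentation.
#' @param pleiotropyMode,pleiotropySd,pleiotropyMean,pleiotropyFraction
#'   pleiotropy regime.
#' @param nOutliers,outlierShiftSds outlier injection.
#' @param weakFraction weak-instrument fraction.
#' @param injectPalindromic,injectAlleleSwaps harmonization perturbations.
#' @param seed RNG seed.
#' @return a validated \code{SimConfig}.
#' @export
simConfig <- function(k = 9, nExp = 121577, nOut = 547261,
                      traitTypeOut = c("binary", "quantitative"),
                      caseFraction = 0.224, trueBeta = log(0.62),
                      r2Total = 0.005, pleiotropyMode = "none",
                      pleiotropySd = 0.01, pleiotropyMean = 0.01,
                      pleiotropyFraction = 1, nOutliers = 0,
                      outlierShiftSds = 10, weakFraction = 0,
                      injectPalindromic = 0, injectAlleleSwaps = 0,
                      seed = 1) {
  traitTypeOut <- match.arg(traitTypeOut)
  new("SimConfig", k = k, nExp = nExp, nOut = nOut,
      traitTypeOut = traitTypeOut, caseFraction = caseFraction,
      trueBeta = trueBeta, r2Total = r2Total,
      pleiotropyMode = pleiotropyMode, pleiotropySd = pleiotropySd,
      pleiotropyMean = pleiotropyMean,
      pleiotropyFraction = pleiotropyFraction, nOutliers = nOutliers,
      outlierShiftSds = outlierShiftSds, weakFraction = weakFraction,
      injectPalindromic = injectPalindromic,
      injectAlleleSwaps = injectAlleleSwaps, seed = seed)
}

# non-palindromic allele pairs used for synthetic SNPs
NONPALINDROMIC_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"),
                              c("T", "C"), c("G", "A"), c("C", "A"),
                              c("G", "T"), c("C", "T"))

#' Generate a two-sample MR dataset with known truth
#'
#' Draws minor-allele frequencies maf_j ~ U(0.05, 0.5) and true exposure
#' effects gamma_j (normal magnitudes, random signs, rescaled so the total
#' variance explained 2 maf (1 - maf) gamma^2 sums to \code{r2Total}); a
#' \code{weakFraction} subset is down-scaled to F ~ U(3, 8). Observed
#' effects add sampling noise at the asymptotic standard errors
#' \eqn{se_{exp} = 1/\sqrt{2 maf (1-maf) n_{exp}}} and
#' \eqn{se_{out} = 1/\sqrt{2 maf (1-maf) n_{out} v}} with v = 1
#' (quantitative) or cf(1 - cf) (binary, log-odds scale). Pleiotropic
#' direct effects alpha_j follow \code{pleiotropyMode}, the true outcome
#' effect is \eqn{\Gamma_j = \beta \gamma_j + \alpha_j}, outliers shift
#' beta_out by \code{outlierShiftSds} outcome SEs, and harmonization
#' perturbations (palindromic pairs, swapped outcome alleles) are injected
#' last. P-values are two-sided normal.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{exposure} and \code{outcome}
#'   (\code{GwasSummary}) and \code{truth} (\code{SyntheticTruth}; the
#'   outlier and perturbation indices are in its attributes).
#' @export
generateMrDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  k <- as.integer(config@k)
  withSeed(config@seed, {
    maf <- runif(k, 0.05, 0.5)
    het <- 2 * maf * (1 - maf)
    gamma <- rnorm(k, mean = 1, sd = 0.15) * sample(c(-1, 1), k, replace = TRUE)
    gamma <- gamma * sqrt(config@r2Total / sum(het * gamma^2))
    seExp <- 1 / sqrt(het * config@nExp)

    nWeak <- round(config@weakFraction * k)
    weakIdx <- if (nWeak > 0) sample.int(k, nWeak) else integer()
    if (nWeak > 0) {
      fTarget <- runif(nWeak, 3, 8)
      gamma[weakIdx] <- sign(gamma[weakIdx]) * sqrt(fTarget) * seExp[weakIdx]
    }

    alpha <- numeric(k)
    nPlei <- round(config@pleiotropyFraction * k)
    pleiIdx <- if (nPlei > 0) sample.int(k, nPlei) else integer()
    if (nPlei > 0) {
      alpha[pleiIdx] <- switch(config@pleiotropyMode,
        none = 0,
        balanced = rnorm(nPlei, 0, config@pleiotropySd),
        directional = rnorm(nPlei, config@pleiotropyMean, config@pleiotropySd),
        inside_violating = config@pleiotropyMean * gamma[pleiIdx] +
          rnorm(nPlei, 0, config@pleiotropySd))
    }

    v <- if (config@traitTypeOut == "binary")
      config@caseFraction * (1 - config@caseFraction) else 1
    seOut <- 1 / sqrt(het * config@nOut * v)
    betaExp <- rnorm(k, gamma, seExp)
    gammaOut <- config@trueBeta * gamma + alpha
    betaOut <- rnorm(k, gammaOut, seOut)

    outlierIdx <- integer()
    if (config@nOutliers > 0) {
      outlierIdx <- sample.int(k, min(config@nOutliers, k))
      betaOut[outlierIdx] <- betaOut[outlierIdx] +
        config@outlierShiftSds * seOut[outlierIdx]
    }

    pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), k,
                                            replace = TRUE), , drop = FALSE]
    ea <- pair[, 1]; oa <- pair[, 2]
    perturbIdx <- sample.int(k, config@injectPalindromic + config@injectAlleleSwaps)
    palIdx <- head(perturbIdx, config@injectPalindromic)
    swapIdx <- tail(perturbIdx, config@injectAlleleSwaps)
    if (length(palIdx)) { ea[palIdx] <- "A"; oa[palIdx] <- "T" }

    rsid <- sprintf("rs%04d", seq_len(k))
    base <- data.frame(rsid = rsid, chrom = as.character(1 + (seq_len(k) - 1) %% 22),
                       pos = 1e6 * seq_len(k), effect_allele = ea,
                       other_allele = oa, eaf = maf, stringsAsFactors = FALSE)

    expDf <- base
    expDf$beta <- betaExp; expDf$se <- seExp
    expDf$pval <- pmax(2 * pnorm(-abs(betaExp / seExp)), .Machine$double.xmin)
    expDf$n <- config@nExp

    outDf <- base
    outDf$beta <- betaOut; outDf$se <- seOut
    outDf$pval <- pmax(2 * pnorm(-abs(betaOut / seOut)), .Machine$double.xmin)
    outDf$n <- config@nOut
    if (length(swapIdx)) {    # report the swapped allele orientation
      tmp <- outDf$effect_allele[swapIdx]
      outDf$effect_allele[swapIdx] <- outDf$other_allele[swapIdx]
      outDf$other_allele[swapIdx] <- tmp
      outDf$beta[swapIdx] <- -outDf$beta[swapIdx]
      outDf$eaf[swapIdx] <- 1 - outDf$eaf[swapIdx]
    }

    nCaseOut <- if (config@traitTypeOut == "binary")
      round(config@caseFraction * config@nOut) else NA_real_
    exposure <- gwasSummary(expDf, trait = "exposure",
                            traitType = "quantitative", n = config@nExp)
    outcome <- gwasSummary(outDf, trait = "outcome",
                           traitType = config@traitTypeOut, n = config@nOut,
                           nCase = nCaseOut)
    truth <- new("SyntheticTruth", trueBeta = config@trueBeta, gamma = gamma,
                 alpha = alpha, maf = maf, seed = config@seed)
    attr(truth, "rsid") <- rsid
    attr(truth, "outlierIdx") <- outlierIdx
    attr(truth, "palindromicIdx") <- palIdx
    attr(truth, "swappedIdx") <- swapIdx
    attr(truth, "weakIdx") <- weakIdx
    attr(truth, "pleiotropyIdx") <- pleiIdx
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Generate a pair of colocalization regions with known scenario
#'
#' Builds an AR(1)-style LD correlation matrix \eqn{R_{ij} = \rho^{|i-j|}}
#' and draws each trait's regional z-scores from
#' \eqn{MVN(R\lambda, R)}, where lambda is zero except for
#' \code{zCausal} at that trait's causal index. Scenarios: \code{shared}
#' (one common causal SNP), \code{distinct} (two causal SNPs whose LD
#' r-squared is below 0.01; an error if infeasible at the given m and rho),
#' \code{trait1_only}, and \code{null}. Betas are backed out as z times the
#' asymptotic SE \eqn{1/\sqrt{n}} (standardized genotypes and trait).
#'
#' @param m number of SNPs (>= 2).
#' @param rho adjacent-SNP LD correlation in [0, 1).
#' @param scenario one of \code{"shared"}, \code{"distinct"},
#'   \code{"trait1_only"}, \code{"null"}.
#' @param zCausal non-centrality of the causal SNP (default 10).
#' @param seed RNG seed.
#' @param n1,n2 per-trait sample sizes.
#' @return list with \code{region1}, \code{region2}
#'   (\code{RegionStats}) and \code{truth} (scenario plus causal indices).
#' @export
generateColocRegion <- function(m, rho, scenario = c("shared", "distinct",
                                                     "trait1_only", "null"),
                                zCausal = 10, seed = NULL, n1 = 50000,
                                n2 = 50000) {
  scenario <- match.arg(scenario)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0,1)", call. = FALSE)
  idx1 <- idx2 <- NA_integer_
  if (scenario %in% c("shared", "trait1_only")) idx1 <- idx2 <- ceiling(m / 2)
  if (scenario == "distinct") {
    idx1 <- max(1L, ceiling(m / 4))
    idx2 <- min(m, ceiling(3 * m / 4))
    if (rho^(2 * abs(idx2 - idx1)) >= 0.01)
      stop("distinct scenario infeasible: causal SNPs cannot reach LD r2 < 0.01",
           call. = FALSE)
  }
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  U <- chol(R)
  lam1 <- lam2 <- numeric(m)
  if (scenario %in% c("shared", "distinct", "trait1_only")) lam1[idx1] <- zCausal
  if (scenario %in% c("shared", "distinct")) lam2[idx2] <- zCausal
  withSeed(seed, {
    z1 <- as.vector(R %*% lam1) + as.vector(t(U) %*% rnorm(m))
    z2 <- as.vector(R %*% lam2) + as.vector(t(U) %*% rnorm(m))
    rsid <- sprintf("rs%05d", seq_len(m))
    r1 <- regionStats(rsid, z1 / sqrt(n1), rep(1 / sqrt(n1), m),
                      trait = "trait1", n = n1)
    r2 <- regionStats(rsid, z2 / sqrt(n2), rep(1 / sqrt(n2), m),
                      trait = "trait2", n = n2)
    list(region1 = r1, region2 = r2,
         truth = list(scenario = scenario, causal1 = idx1, causal2 = idx2,
                      seed = seed))
  })
}
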