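# Single-region, single-causal-variant Bayesian colocalization via
# approximate Bayes factors.

#' Log approximate Bayes factor for one SNP association
#'
#' Wakefield-style asymptotic Bayes factor comparing a normal effect prior
#' N(0, priorSd^2) against the point-null, given an estimate and its SE.
#' With z = beta/se, V = se^2 and shrinkage r = priorSd^2/(priorSd^2 + V),
#' the log ABF is \eqn{0.5 (\log(1-r) + r z^2)}.
#'
#' @param beta,se association estimate and standard error (vectorized).
#' @param priorSd prior SD of the true effect (0.2 is conventional for
#'   per-SD quantitative effects, 0.15 for log odds ratios).
#' @return numeric vector of log approximate Bayes factors.
#' @export
logAbf <- function(beta, se, priorSd) {
  if (any(se <= 0)) stop("'se' must be positive", call. = FALSE)
  if (any(priorSd <= 0)) stop("'priorSd' must be positive", call. = FALSE)
  z <- beta / se
  r <- priorSd^2 / (priorSd^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

#' Construct a RegionStats object
#'
#' @param rsid,beta,se aligned per-SNP association vectors over a
#'   contiguous region.
#' @param trait trait label.
#' @param traitType \code{"quantitative"} or \code{"binary"}.
#' @param n sample size.
#' @param caseFraction case fraction (binary traits).
#' @return a \code{\linkS4class{RegionStats}}.
#' @export
regionStats <- function(rsid, beta, se, trait = "trait",
                        traitType = c("quantitative", "binary"),
                        n = NA_real_, caseFraction = NA_real_) {
  traitType <- match.arg(traitType)
  new("RegionStats", trait = trait, traitType = traitType,
      snps = data.frame(rsid = as.character(rsid), beta = beta, se = se,
                        stringsAsFactors = FALSE),
      n = n, caseFraction = caseFraction)
}

#' Bayesian colocalization of two traits in one region
#'
#' Assumes at most one causal variant per trait in the region and computes
#' posterior probabilities for the five hypotheses: H0 no association with
#' either trait; H1/H2 association with only trait 1/2; H3 two distinct
#' causal variants; H4 one shared causal variant. With per-SNP log ABFs
#' \eqn{l_{1i}, l_{2j}} and per-SNP priors p1, p2, p12, the unnormalized
#' hypothesis likelihoods are H0 = 1, H1 = p1 sum_i ABF1_i, H2 = p2 sum_j
#' ABF2_j, H3 = p1 p2 sum_{i != j} ABF1_i ABF2_j, H4 = p12 sum_i ABF1_i
#' ABF2_i, all evaluated in log space with log-sum-exp for overflow safety.
#'
#' @param region1,region2 \code{RegionStats} for the two traits. The rsid
#'   intersection is analyzed; a non-trivial intersection is required and
#'   any mismatch is messaged.
#' @param priors named numeric: per-SNP prior probabilities \code{p1},
#'   \code{p2} (association with each single trait) and \code{p12} (shared
#'   causal variant). Defaults 1e-4, 1e-4, 1e-5.
#' @param priorSdQuant,priorSdBinary prior effect SDs used for the ABFs,
#'   chosen by each region's trait type.
#' @return a \code{\linkS4class{ColocResult}}; single-SNP regions are valid
#'   but flagged, with PP_H3 structurally zero.
#' @export
colocalize <- function(region1, region2,
                       priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       priorSdQuant = 0.2, priorSdBinary = 0.15) {
  stopifnot(is(region1, "RegionStats"), is(region2, "RegionStats"))
  common <- intersect(region1@snps$rsid, region2@snps$rsid)
  if (!length(common))
    stop("regions share no rsids; cannot colocalize", call. = FALSE)
  nDrop <- max(nrow(region1@snps), nrow(region2@snps)) - length(common)
  if (nDrop > 0)
    message(nDrop, " SNP(s) not shared by both regions were ignored")
  s1 <- region1@snps[match(common, region1@snps$rsid), ]
  s2 <- region2@snps[match(common, region2@snps$rsid), ]

  sdFor <- function(type) if (identical(type, "binary")) priorSdBinary else priorSdQuant
  l1 <- logAbf(s1$beta, s1$se, sdFor(region1@traitType))
  l2 <- logAbf(s2$beta, s2$se, sdFor(region2@traitType))

  lp1 <- log(priors[["p1"]]); lp2 <- log(priors[["p2"]]); lp12 <- log(priors[["p12"]])
  lH0 <- 0
  lH1 <- lp1 + logSumExp(l1)
  lH2 <- lp2 + logSumExp(l2)
  lH4 <- lp12 + logSumExp(l1 + l2)
  # sum over i != j equals (sum_i ABF1_i)(sum_j ABF2_j) - sum_i ABF1_i ABF2_i
  lH3 <- if (length(common) > 1L)
    lp1 + lp2 + logDiffExp(logSumExp(l1) + logSumExp(l2), logSumExp(l1 + l2))
  else -Inf
  flags <- if (length(common) == 1L) "single_snp" else character()

  lAll <- c(lH0, lH1, lH2, lH3, lH4)
  norm <- logSumExp(lAll)
  pp <- exp(lAll - norm)
  pp[!is.finite(lAll)] <- 0
  new("ColocResult", pp = setNames(pp, paste0("PP_H", 0:4)),
      priors = c(p1 = priors[["p1"]], p2 = priors[["p2"]],
                 p12 = priors[["p12"]]),
      nSnps = length(common), flags = flags)
}
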