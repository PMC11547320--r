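# S4 classes for the MR pipeline. Betas are per effect-allele copy, on the
# per-SD scale for quantitative traits and the log-odds scale for binary
# traits; standard errors are always > 0.

SNP_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "n_case")

#' GwasSummary: one trait's GWAS summary statistics
#'
#' Container for per-SNP summary associations of a single trait. The
#' \code{records} slot is a data.frame with one row per SNP and columns
#' \code{rsid}, \code{chrom}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' \code{n}, \code{n_case}. Row validity (alleles in A/C/G/T and distinct,
#' se > 0, p in (0,1], eaf in [0,1] or NA, pos >= 1) is enforced by the
#' validity method; construction via \code{\link{gwasSummary}} or
#' \code{\link{readGwas}} drops and counts invalid rows instead of failing.
#'
#' @slot trait character(1) trait label.
#' @slot traitType \code{"quantitative"} or \code{"binary"}; binary traits
#'   carry betas on the log-odds scale.
#' @slot n numeric(1) total sample size.
#' @slot nCase numeric(1) case count (NA for quantitative traits).
#' @slot records data.frame of per-SNP associations (see above).
#' @slot nDropped numeric(1) rows removed during construction for invariant
#'   violations or duplicate rsids.
#'
#' @exportClass GwasSummary
setClass("GwasSummary",
  representation(trait = "character", traitType = "character",
                 n = "numeric", nCase = "numeric",
                 records = "data.frame", nDropped = "numeric"),
  prototype(trait = NA_character_, traitType = "quantitative",
            n = NA_real_, nCase = NA_real_,
            records = data.frame(), nDropped = 0))

setValidity("GwasSummary", function(object) {
  msg <- character()
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  r <- object@records
  if (nrow(r)) {
    if (!all(SNP_COLUMNS %in% names(r)))
      msg <- c(msg, paste("records must contain columns:",
                          paste(setdiff(SNP_COLUMNS, names(r)), collapse = ", ")))
    else {
      if (anyDuplicated(r$rsid)) msg <- c(msg, "rsid must be unique within records")
      ok <- r$effect_allele %in% names(DNA_COMPLEMENT) &
        r$other_allele %in% names(DNA_COMPLEMENT) &
        r$effect_allele != r$other_allele &
        r$se > 0 & r$pval > 0 & r$pval <= 1 & r$pos >= 1 &
        (is.na(r$eaf) | (r$eaf >= 0 & r$eaf <= 1))
      if (!all(ok)) msg <- c(msg, sprintf("%d record(s) violate SNP invariants",
                                          sum(!ok)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedData: exposure/outcome pairs on a shared effect allele
#'
#' Result of \code{\link{harmonize}}. \code{snps} has one row per retained
#' instrument with columns \code{rsid}, \code{beta_exp}, \code{se_exp},
#' \code{beta_out}, \code{se_out}, \code{eaf_exp}; \code{dropped} has columns
#' \code{rsid}, \code{reason} with reason one of \code{palindromic},
#' \code{allele_mismatch}, \code{missing_in_outcome}, \code{duplicate}.
#' Retained and dropped rsids partition the instrument list that was
#' harmonized.
#'
#' @slot exposureTrait,outcomeTrait character(1) trait labels.
#' @slot outcomeType \code{"quantitative"} or \code{"binary"}; controls
#'   whether estimators report an odds-ratio scale.
#' @slot snps data.frame of retained pairs.
#' @slot dropped data.frame of dropped instruments and reasons.
#'
#' @exportClass HarmonizedData
setClass("HarmonizedData",
  representation(exposureTrait = "character", outcomeTrait = "character",
                 outcomeType = "character", snps = "data.frame",
                 dropped = "data.frame"),
  prototype(exposureTrait = NA_character_, outcomeTrait = NA_character_,
            outcomeType = "quantitative",
            snps = data.frame(rsid = character(), beta_exp = numeric(),
                              se_exp = numeric(), beta_out = numeric(),
                              se_out = numeric(), eaf_exp = numeric()),
            dropped = data.frame(rsid = character(), reason = character())))

setValidity("HarmonizedData", function(object) {
  msg <- character()
  need <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp")
  if (!all(need %in% names(object@snps)))
    msg <- c(msg, "snps must have columns rsid, beta_exp, se_exp, beta_out, se_out, eaf_exp")
  if (!all(c("rsid", "reason") %in% names(object@dropped)))
    msg <- c(msg, "dropped must have columns rsid, reason")
  else if (nrow(object@dropped) &&
           !all(object@dropped$reason %in%
                c("palindromic", "allele_mismatch", "missing_in_outcome", "duplicate")))
    msg <- c(msg, "invalid drop reason")
  if (nrow(object@snps)) {
    if (any(object@snps$se_exp < 0) || any(object@snps$se_out <= 0))
      msg <- c(msg, "outcome SEs must be positive and exposure SEs non-negative")
    if (anyDuplicated(object@snps$rsid)) msg <- c(msg, "duplicate retained rsid")
  }
  if (!object@outcomeType %in% c("quantitative", "binary"))
    msg <- c(msg, "outcomeType must be 'quantitative' or 'binary'")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: quality-controlled genetic instruments
#'
#' Output of \code{\link{selectInstruments}} (optionally annotated by
#' \code{\link{screenConfounders}}). Instruments are sorted by association
#' p-value, ascending.
#'
#' @slot snps data.frame of instrument records (same columns as
#'   \code{GwasSummary} records).
#' @slot fStats numeric per-SNP F-statistic \eqn{(\beta/se)^2}, aligned
#'   with rows of \code{snps}.
#' @slot r2PerSnp numeric per-SNP variance explained
#'   \eqn{2 p (1-p) \beta^2} (NA when eaf is missing).
#' @slot r2Total numeric(1) sum of non-missing per-SNP variance explained.
#' @slot confounderFlags named list; per rsid, character vector of annotated
#'   traits associated at genome-wide significance.
#' @slot unlinked character rsids that were absent from the LD matrix and
#'   treated as unlinked during clumping.
#'
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(snps = "data.frame", fStats = "numeric", r2PerSnp = "numeric",
                 r2Total = "numeric", confounderFlags = "list",
                 unlinked = "character"),
  prototype(snps = data.frame(), fStats = numeric(), r2PerSnp = numeric(),
            r2Total = 0, confounderFlags = list(), unlinked = character()))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  k <- nrow(object@snps)
  if (length(object@fStats) != k || length(object@r2PerSnp) != k)
    msg <- c(msg, "fStats and r2PerSnp must align 1:1 with snps")
  tot <- sum(object@r2PerSnp, na.rm = TRUE)
  if (k && abs(object@r2Total - tot) > 1e-12)
    msg <- c(msg, "r2Total must equal the sum of per-SNP variance explained")
  if (object@r2Total < 0 || object@r2Total > 1)
    msg <- c(msg, "r2Total must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' HeterogeneityStat: Cochran's Q for an estimator fit
#'
#' @slot q numeric(1) Cochran's Q statistic (>= 0).
#' @slot df numeric(1) degrees of freedom: n_snp - 1 for IVW,
#'   n_snp - 2 for MR-Egger.
#' @slot pval numeric(1) chi-square upper-tail probability.
#'
#' @exportClass HeterogeneityStat
setClass("HeterogeneityStat",
  representation(q = "numeric", df = "numeric", pval = "numeric"),
  prototype(q = NA_real_, df = NA_real_, pval = NA_real_))

setValidity("HeterogeneityStat", function(object) {
  if (!is.na(object@q) && object@q < -1e-12) return("q must be non-negative")
  TRUE
})

#' MrEstimate: one method's causal estimate
#'
#' All betas are causal effects per SD of the (standardized) exposure; for
#' binary outcomes they are log odds ratios and \code{orScale} carries the
#' exponentiated estimate and 95\% CI.
#'
#' @slot method label, one of \code{wald}, \code{ivw}, \code{pivw},
#'   \code{egger}, \code{weighted_median}, \code{weighted_mode},
#'   \code{presso_raw}, \code{presso_corrected}.
#' @slot beta,se,ciLow,ciHigh,pval estimate, standard error, 95\% interval
#'   and two-sided normal p-value.
#' @slot nSnp number of instruments used.
#' @slot orScale named numeric \code{(or, or_ci_low, or_ci_high)} for binary
#'   outcomes; length-0 otherwise.
#' @slot extras method-specific list (Egger intercept test, IVW
#'   over-dispersion scale, PRESSO global/distortion p and outliers,
#'   bootstrap reps and seed, pIVW penalty and instrument strength).
#' @slot heterogeneity a \code{HeterogeneityStat} (NA slots when the method
#'   has no heterogeneity statistic).
#'
#' @exportClass MrEstimate
setClass("MrEstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnp = "numeric", orScale = "numeric", extras = "list",
                 heterogeneity = "HeterogeneityStat"),
  prototype(method = NA_character_, beta = NA_real_, se = NA_real_,
            ciLow = NA_real_, ciHigh = NA_real_, pval = NA_real_,
            nSnp = NA_real_, orScale = numeric(), extras = list(),
            heterogeneity = new("HeterogeneityStat")))

setValidity("MrEstimate", function(object) {
  msg <- character()
  okMethods <- c("wald", "ivw", "pivw", "egger", "weighted_median",
                 "weighted_mode", "presso_raw", "presso_corrected")
  if (!object@method %in% okMethods)
    msg <- c(msg, paste("method must be one of:", paste(okMethods, collapse = ", ")))
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be > 0")
  if (!is.na(object@pval) && (object@pval <= 0 || object@pval > 1))
    msg <- c(msg, "pval must lie in (0,1]")
  if (!is.na(object@beta) && !is.na(object@ciLow) &&
      (object@ciLow > object@beta + 1e-12 || object@ciHigh < object@beta - 1e-12))
    msg <- c(msg, "CI must bracket beta")
  if (length(object@orScale) && length(object@orScale) != 3L)
    msg <- c(msg, "orScale must be empty or length 3 (or, or_ci_low, or_ci_high)")
  if (length(msg)) msg else TRUE
})

#' ColocResult: posterior probabilities of the five colocalization hypotheses
#'
#' Posterior support, under a single-causal-variant model, for H0 (no
#' association with either trait), H1/H2 (association with only trait 1/2),
#' H3 (two distinct causal variants) and H4 (one shared causal variant).
#'
#' @slot pp named numeric(5) \code{PP_H0..PP_H4}, summing to 1.
#' @slot priors named numeric(3) per-SNP priors \code{p1}, \code{p2},
#'   \code{p12}.
#' @slot nSnps number of SNPs in the analyzed region.
#' @slot flags character; e.g. \code{"single_snp"} when H3 is structurally 0.
#'
#' @exportClass ColocResult
setClass("ColocResult",
  representation(pp = "numeric", priors = "numeric", nSnps = "numeric",
                 flags = "character"),
  prototype(pp = setNames(rep(NA_real_, 5), paste0("PP_H", 0:4)),
            priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
            nSnps = NA_real_, flags = character()))

setValidity("ColocResult", function(object) {
  msg <- character()
  if (length(object@pp) != 5L) msg <- c(msg, "pp must have 5 entries")
  else if (!anyNA(object@pp)) {
    if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
      msg <- c(msg, "posteriors must lie in [0,1]")
    if (abs(sum(object@pp) - 1) > 1e-9)
      msg <- c(msg, "posteriors must sum to 1 (tolerance 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' RegionStats: one trait's summary statistics over a contiguous region
#'
#' @slot trait character(1) label.
#' @slot traitType \code{"quantitative"} or \code{"binary"}.
#' @slot snps data.frame with columns \code{rsid}, \code{beta}, \code{se}.
#' @slot n numeric(1) sample size.
#' @slot caseFraction numeric(1) case fraction for binary traits (NA
#'   otherwise).
#'
#' @exportClass RegionStats
setClass("RegionStats",
  representation(trait = "character", traitType = "character",
                 snps = "data.frame", n = "numeric", caseFraction = "numeric"),
  prototype(trait = NA_character_, traitType = "quantitative",
            snps = data.frame(rsid = character(), beta = numeric(),
                              se = numeric()),
            n = NA_real_, caseFraction = NA_real_))

setValidity("RegionStats", function(object) {
  msg <- character()
  if (!all(c("rsid", "beta", "se") %in% names(object@snps)))
    msg <- c(msg, "snps must have columns rsid, beta, se")
  else {
    if (nrow(object@snps) < 1L) msg <- c(msg, "a region needs at least one SNP")
    if (nrow(object@snps) && any(object@snps$se <= 0))
      msg <- c(msg, "all se must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' MetaResult: fixed-effect pooled estimate across outcome GWAS
#'
#' @slot beta,se,pval pooled effect, standard error, two-sided normal p.
#' @slot q,df,pHet Cochran's Q across studies, its degrees of freedom
#'   (k - 1) and chi-square p-value.
#' @slot i2 percentage of between-study variation attributable to
#'   heterogeneity: \eqn{\max(0, (Q - df)/Q) \times 100} when Q > 0, else 0.
#' @slot nStudies number of pooled estimates.
#'
#' @exportClass MetaResult
setClass("MetaResult",
  representation(beta = "numeric", se = "numeric", pval = "numeric",
                 q = "numeric", df = "numeric", pHet = "numeric",
                 i2 = "numeric", nStudies = "numeric"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@se <= 0) msg <- c(msg, "se must be > 0")
  expected <- if (object@q > 0) max(0, (object@q - object@df) / object@q) * 100 else 0
  if (abs(object@i2 - expected) > 1e-9)
    msg <- c(msg, "i2 inconsistent with q and df")
  if (length(msg)) msg else TRUE
})

#' PowerResult: minimum detectable effect for an MR analysis
#'
#' @slot alpha two-sided significance level.
#' @slot powerTarget target power (e.g. 0.8).
#' @slot r2 instrument variance explained in the exposure.
#' @slot n outcome sample size.
#' @slot caseFraction case fraction for binary outcomes (NA for
#'   quantitative outcomes).
#' @slot minDetectableBeta smallest causal effect (log OR per SD exposure
#'   for binary outcomes) detectable at the target power.
#' @slot minDetectableOr \code{exp(minDetectableBeta)}.
#'
#' @exportClass PowerResult
setClass("PowerResult",
  representation(alpha = "numeric", powerTarget = "numeric", r2 = "numeric",
                 n = "numeric", caseFraction = "numeric",
                 minDetectableBeta = "numeric", minDetectableOr = "numeric"))

setValidity("PowerResult", function(object) {
  msg <- character()
  if (object@minDetectableBeta <= 0) msg <- c(msg, "minDetectableBeta must be > 0")
  if (object@minDetectableOr <= 1) msg <- c(msg, "minDetectableOr must be > 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: generating parameters recorded with simulated data
#'
#' @slot trueBeta the causal effect used by the generator (log OR per SD
#'   exposure for binary outcomes).
#' @slot gamma per-SNP true exposure effects.
#' @slot alpha per-SNP true pleiotropic (direct) outcome effects.
#' @slot maf per-SNP minor-allele frequencies.
#' @slot seed generator seed.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(trueBeta = "numeric", gamma = "numeric", alpha = "numeric",
                 maf = "numeric", seed = "numeric"))

setValidity("SyntheticTruth", function(object) {
  k <- length(object@gamma)
  if (length(object@alpha) != k || length(object@maf) != k)
    return("gamma, alpha and maf must have equal length")
  TRUE
})
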