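# Generics, accessors and show methods.

#' Number of SNPs in an object
#'
#' @param x a \code{GwasSummary}, \code{HarmonizedData},
#'   \code{InstrumentSet}, \code{MrEstimate}, \code{RegionStats} or
#'   \code{ColocResult}.
#' @return integer count of SNPs (records, retained instruments, or
#'   instruments used by an estimate).
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

setMethod("nSnp", "GwasSummary", function(x) nrow(x@records))
setMethod("nSnp", "HarmonizedData", function(x) nrow(x@snps))
setMethod("nSnp", "InstrumentSet", function(x) nrow(x@snps))
setMethod("nSnp", "MrEstimate", function(x) as.integer(x@nSnp))
setMethod("nSnp", "RegionStats", function(x) nrow(x@snps))
setMethod("nSnp", "ColocResult", function(x) as.integer(x@nSnps))

#' Per-SNP records of a summary-statistics object
#'
#' @param x a \code{GwasSummary}, \code{HarmonizedData},
#'   \code{InstrumentSet} or \code{RegionStats}.
#' @return the underlying per-SNP \code{data.frame}.
#' @export
setGeneric("snpData", function(x) standardGeneric("snpData"))

setMethod("snpData", "GwasSummary", function(x) x@records)
setMethod("snpData", "HarmonizedData", function(x) x@snps)
setMethod("snpData", "InstrumentSet", function(x) x@snps)
setMethod("snpData", "RegionStats", function(x) x@snps)

#' Dropped instruments and drop reasons after harmonization
#'
#' @param x a \code{HarmonizedData}.
#' @return data.frame with columns \code{rsid}, \code{reason}.
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))
setMethod("droppedSnps", "HarmonizedData", function(x) x@dropped)

#' Trait label
#' @param x a \code{GwasSummary} or \code{RegionStats}.
#' @return character(1).
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
setMethod("traitName", "GwasSummary", function(x) x@trait)
setMethod("traitName", "RegionStats", function(x) x@trait)

#' Per-instrument F-statistics
#' @param x an \code{InstrumentSet}.
#' @return numeric vector aligned with \code{snpData(x)} rows.
#' @export
setGeneric("fStats", function(x) standardGeneric("fStats"))
setMethod("fStats", "InstrumentSet", function(x) x@fStats)

#' Instrument variance explained
#' @param x an \code{InstrumentSet}.
#' @param perSnp return the per-SNP values instead of the total.
#' @return numeric(1) total, or the per-SNP vector.
#' @export
setGeneric("varianceExplainedTotal",
           function(x, perSnp = FALSE) standardGeneric("varianceExplainedTotal"))
setMethod("varianceExplainedTotal", "InstrumentSet",
          function(x, perSnp = FALSE) if (perSnp) x@r2PerSnp else x@r2Total)

#' Confounder flags per instrument
#' @param x an \code{InstrumentSet}.
#' @return named list: per rsid, the annotated traits flagged at
#'   genome-wide significance (empty character vector when none).
#' @export
setGeneric("confounderFlags", function(x) standardGeneric("confounderFlags"))
setMethod("confounderFlags", "InstrumentSet", function(x) x@confounderFlags)

#' Posterior probabilities of a colocalization result
#' @param x a \code{ColocResult}.
#' @return named numeric(5): \code{PP_H0} .. \code{PP_H4}.
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
setMethod("posteriors", "ColocResult", function(x) x@pp)

#' Flatten an MrEstimate (or list of them) to a one-row-per-method table
#'
#' @param x an \code{MrEstimate} or a list of them.
#' @return data.frame with columns \code{method}, \code{n_snp}, \code{beta},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{pval}, \code{or},
#'   \code{or_ci_low}, \code{or_ci_high} (OR columns NA for quantitative
#'   outcomes) and \code{extras} (JSON-encoded).
#' @export
setGeneric("estimateTable", function(x) standardGeneric("estimateTable"))

setMethod("estimateTable", "MrEstimate", function(x) {
  orv <- if (length(x@orScale)) x@orScale else rep(NA_real_, 3)
  data.frame(method = x@method, n_snp = as.integer(x@nSnp), beta = x@beta,
             se = x@se, ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
             or = orv[[1]], or_ci_low = orv[[2]], or_ci_high = orv[[3]],
             extras = as.character(jsonlite::toJSON(x@extras, auto_unbox = TRUE,
                                                    digits = NA, null = "null")),
             stringsAsFactors = FALSE)
})

setMethod("estimateTable", "list", function(x) {
  do.call(rbind, lapply(x, estimateTable))
})

setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary '%s' (%s): %d SNPs, n = %s%s; %d row(s) dropped at read\n",
              object@trait, object@traitType, nrow(object@records),
              format(object@n, big.mark = ","),
              if (!is.na(object@nCase))
                sprintf(" (%s cases)", format(object@nCase, big.mark = ",")) else "",
              object@nDropped))
})

setMethod("show", "HarmonizedData", function(object) {
  cat(sprintf("HarmonizedData: %s -> %s (%s outcome)\n", object@exposureTrait,
              object@outcomeTrait, object@outcomeType))
  cat(sprintf("  %d SNP(s) retained, %d dropped", nrow(object@snps),
              nrow(object@dropped)))
  if (nrow(object@dropped)) {
    tab <- table(object@dropped$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: %d instrument(s), r2 total = %.4g\n",
              nrow(object@snps), object@r2Total))
  if (length(object@fStats))
    cat(sprintf("  F-statistics: min %.1f, median %.1f; %d weak (F < 10)\n",
                min(object@fStats), median(object@fStats),
                sum(object@fStats < 10)))
  nf <- sum(lengths(object@confounderFlags) > 0)
  if (nf) cat(sprintf("  %d instrument(s) flagged for potential confounders\n", nf))
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("MrEstimate [%s] (%d SNPs)\n", object@method, object@nSnp))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh, object@pval))
  if (length(object@orScale))
    cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n", object@orScale[[1]],
                object@orScale[[2]], object@orScale[[3]]))
  if (!is.na(object@heterogeneity@q))
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n",
                object@heterogeneity@q, object@heterogeneity@df,
                object@heterogeneity@pval))
})

setMethod("show", "HeterogeneityStat", function(object) {
  cat(sprintf("Cochran's Q = %.4g, df = %d, p = %.4g\n", object@q,
              as.integer(object@df), object@pval))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult (%d SNPs):\n", as.integer(object@nSnps)))
  print(round(object@pp, 4))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("Fixed-effect meta-analysis of %d estimates\n", object@nStudies))
  cat(sprintf("  beta = %.4g (se %.4g), p = %.3g\n", object@beta, object@se,
              object@pval))
  cat(sprintf("  Q = %.3f (df %d), p_het = %.3g, I2 = %.1f%%\n", object@q,
              as.integer(object@df), object@pHet, object@i2))
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf("MR power: alpha = %g, target power = %g, r2 = %g, n = %s\n",
              object@alpha, object@powerTarget, object@r2,
              format(object@n, big.mark = ",")))
  cat(sprintf("  minimum detectable beta = %.4g (OR %.3f)\n",
              object@minDetectableBeta, object@minDetectableOr))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: true beta = %.4g, %d SNPs, seed = %s\n",
              object@trueBeta, length(object@gamma),
              format(object@seed)))
})
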