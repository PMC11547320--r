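# Instrument selection and quality control: p-value screen, greedy LD
# clumping, F-statistics, variance explained, confounder flags.

#' Read a square LD (r-squared) matrix from TSV
#'
#' Expects a square tab-separated matrix with rsids as both the header row
#' and the first column. Entries are squared correlations in [0,1]; the
#' matrix is symmetrized (averaging) and the diagonal forced to 1.
#'
#' @param path file path.
#' @return numeric matrix with rsid dimnames.
#' @export
readLdMatrix <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column rsids disagree", call. = FALSE)
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("LD r-squared entries must lie in [0,1]", call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Per-SNP instrument-strength F-statistic
#'
#' \eqn{F = (\beta/se)^2}; F < 10 conventionally flags a weak instrument.
#'
#' @param beta,se SNP-exposure effect and its standard error (vectorized).
#' @return numeric vector of F values with a logical \code{"weak"}
#'   attribute (TRUE where F < 10).
#' @examples
#' fStatistic(0.02, 0.002)  # 100, strong
#' @export
fStatistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("'se' must be positive", call. = FALSE)
  f <- (beta / se)^2
  attr(f, "weak") <- f < 10
  f
}

#' Variance in a standardized exposure explained by one SNP
#'
#' Assuming a unit-variance exposure, a SNP with effect-allele frequency p
#' and per-allele effect beta explains \eqn{2 p (1-p) \beta^2} of the
#' exposure variance (clipped to [0,1]). Missing eaf returns NA with a
#' warning; such SNPs are excluded from an instrument set's r2 total.
#'
#' @param eaf effect-allele frequency in (0,1) (vectorized).
#' @param beta per-allele effect on the standardized exposure.
#' @return numeric vector of variance proportions.
#' @examples
#' varianceExplained(0.5, 0.1)  # 0.005
#' @export
varianceExplained <- function(eaf, beta) {
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (anyNA(r2))
    warning(sum(is.na(r2)),
            " SNP(s) with missing eaf excluded from variance explained")
  pmin(pmax(r2, 0), 1)
}

#' Select genetic instruments by p-value threshold and greedy LD clumping
#'
#' Candidates are records with association p strictly below
#' \code{pThreshold}. Greedy clumping then repeatedly takes the smallest-p
#' remaining candidate as an index SNP and discards every remaining
#' candidate whose r-squared with any retained index exceeds
#' \code{r2Threshold}. Ties in p break by (chrom, pos) then rsid, so the
#' result is invariant to input row order. SNPs absent from the LD matrix
#' are treated as unlinked and recorded in the \code{unlinked} slot (also
#' raised as a warning).
#'
#' @param gwas a \code{GwasSummary} for the exposure.
#' @param pThreshold genome-wide significance level (default 5e-8).
#' @param ld square r-squared matrix with rsid dimnames (see
#'   \code{\link{readLdMatrix}}), or NULL to treat all SNPs as unlinked.
#' @param r2Threshold LD cut-off (default 1e-3).
#' @return an \code{\linkS4class{InstrumentSet}} sorted by p ascending, with
#'   per-SNP F-statistics and variance explained filled in.
#' @export
selectInstruments <- function(gwas, pThreshold = 5e-8, ld = NULL,
                              r2Threshold = 1e-3) {
  stopifnot(is(gwas, "GwasSummary"))
  rec <- gwas@records
  cand <- rec[rec$pval < pThreshold, , drop = FALSE]
  if (!nrow(cand))
    stop(sprintf("no SNP passes the p < %g instrument threshold", pThreshold),
         call. = FALSE)
  cand <- cand[order(cand$pval, cand$chrom, cand$pos, cand$rsid), , drop = FALSE]

  unlinked <- character()
  if (!is.null(ld)) {
    unlinked <- setdiff(cand$rsid, rownames(ld))
    if (length(unlinked))
      warning(length(unlinked), " candidate SNP(s) absent from the LD matrix;",
              " treated as unlinked: ", paste(unlinked, collapse = ", "))
  } else {
    unlinked <- cand$rsid
  }

  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (is.null(ld) || !(cand$rsid[i] %in% rownames(ld))) next
    r2row <- ld[cand$rsid[i], ]
    for (j in seq_len(nrow(cand))) {
      if (j == i || !alive[j]) next
      rsj <- cand$rsid[j]
      if (rsj %in% names(r2row) && r2row[[rsj]] > r2Threshold) alive[j] <- FALSE
    }
  }
  snps <- cand[keep, , drop = FALSE]
  rownames(snps) <- NULL
  f <- as.numeric(fStatistic(snps$beta, snps$se))
  r2 <- suppressWarnings(varianceExplained(snps$eaf, snps$beta))
  if (anyNA(r2))
    warning(sum(is.na(r2)), " instrument(s) with missing eaf excluded from r2 total")
  flags <- setNames(rep(list(character()), nrow(snps)), snps$rsid)
  new("InstrumentSet", snps = snps, fStats = f, r2PerSnp = r2,
      r2Total = sum(r2, na.rm = TRUE), confounderFlags = flags,
      unlinked = intersect(unlinked, snps$rsid))
}

#' Flag instruments associated with potential confounders
#'
#' Looks each instrument up in a long-format annotation table (columns
#' \code{rsid}, \code{trait}, \code{pval}; the offline replacement for a
#' phenome-scan service) and records every annotated trait whose
#' association p is below \code{pThreshold}. Instruments are flagged, never
#' removed: exclusion is a sensitivity-analysis decision made downstream
#' (see \code{\link{buildSensitivitySets}}).
#'
#' @param instruments an \code{InstrumentSet}.
#' @param annotations data.frame with columns \code{rsid}, \code{trait},
#'   \code{pval}; SNPs absent from the table receive no flags.
#' @param pThreshold significance level for flagging (default 5e-8).
#' @return the \code{InstrumentSet} with \code{confounderFlags} filled in.
#' @export
screenConfounders <- function(instruments, annotations, pThreshold = 5e-8) {
  stopifnot(is(instruments, "InstrumentSet"))
  if (!all(c("rsid", "trait", "pval") %in% names(annotations)))
    stop("annotations must have columns rsid, trait, pval", call. = FALSE)
  flags <- lapply(instruments@snps$rsid, function(rs) {
    hit <- annotations[annotations$rsid == rs &
                         annotations$pval < pThreshold, , drop = FALSE]
    unique(as.character(hit$trait))
  })
  instruments@confounderFlags <- setNames(flags, instruments@snps$rsid)
  validObject(instruments)
  instruments
}
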