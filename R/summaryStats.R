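# GWAS summary-statistics I/O and exposure/outcome harmonization.

DEFAULT_COLUMN_MAP <- c(rsid = "rsid", chrom = "chr", pos = "pos",
                        effect_allele = "ea", other_allele = "oa",
                        eaf = "eaf", beta = "beta", se = "se",
                        pval = "pval", n = "n")

#' Construct a GwasSummary from a per-SNP data.frame
#'
#' Rows violating the per-SNP invariants (alleles in \{A,C,G,T\} and
#' distinct, se > 0, p-value in (0,1], position >= 1, eaf in [0,1] or
#' missing) are dropped and counted, alleles are upper-cased, and duplicated
#' rsids are resolved by keeping the smallest-p record.
#'
#' @param records data.frame with columns \code{rsid}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pval}, \code{n} (and optionally
#'   \code{n_case}).
#' @param trait trait label.
#' @param traitType \code{"quantitative"} or \code{"binary"} (betas on the
#'   log-odds scale).
#' @param n total sample size (defaults to the maximum per-SNP n).
#' @param nCase case count for binary traits.
#' @return a validated \code{\linkS4class{GwasSummary}}; the number of rows
#'   dropped is in the \code{nDropped} slot.
#' @examples
#' rec <- data.frame(rsid = "rs1", chrom = "1", pos = 100,
#'                   effect_allele = "a", other_allele = "g", eaf = 0.3,
#'                   beta = 0.02, se = 0.004, pval = 1e-9, n = 1e5)
#' gwasSummary(rec, trait = "acetate")
#' @export
gwasSummary <- function(records, trait, traitType = c("quantitative", "binary"),
                        n = NULL, nCase = NA_real_) {
  traitType <- match.arg(traitType)
  if (!is.data.frame(records)) stop("'records' must be a data.frame", call. = FALSE)
  if (!"n_case" %in% names(records)) records$n_case <- NA_real_
  miss <- setdiff(SNP_COLUMNS, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records <- records[SNP_COLUMNS]
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case"))
    records[[col]] <- as.numeric(records[[col]])

  ok <- !is.na(records$rsid) & nzchar(records$rsid) &
    records$effect_allele %in% names(DNA_COMPLEMENT) &
    records$other_allele %in% names(DNA_COMPLEMENT) &
    records$effect_allele != records$other_allele &
    !is.na(records$beta) & !is.na(records$se) & records$se > 0 &
    !is.na(records$pval) & records$pval > 0 & records$pval <= 1 &
    !is.na(records$pos) & records$pos >= 1 &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1))
  dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  if (anyDuplicated(records$rsid)) {
    # keep the smallest-p record per rsid; count the rest as dropped
    records <- records[order(records$pval, records$rsid), , drop = FALSE]
    dup <- duplicated(records$rsid)
    dropped <- dropped + sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  records <- records[order(records$chrom, records$pos, records$rsid), , drop = FALSE]
  rownames(records) <- NULL
  if (!nrow(records)) stop("no valid summary-statistics rows", call. = FALSE)
  if (is.null(n)) n <- suppressWarnings(max(records$n, na.rm = TRUE))
  new("GwasSummary", trait = as.character(trait), traitType = traitType,
      n = as.numeric(n), nCase = as.numeric(nCase), records = records,
      nDropped = dropped)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-separated file with a header (gzip accepted),
#' renames columns via \code{columnMap}, and validates records as in
#' \code{\link{gwasSummary}}.
#'
#' @param path file path.
#' @param columnMap named character vector mapping the canonical field names
#'   (\code{rsid}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#'   \code{n}, optionally \code{n_case}) to the file's column names.
#'   Defaults to \code{rsid, chr, pos, ea, oa, eaf, beta, se, pval, n}.
#' @param trait,traitType,n,nCase trait metadata, as in
#'   \code{\link{gwasSummary}}.
#' @param sep field separator; inferred from the header line when NULL.
#' @return a \code{\linkS4class{GwasSummary}}.
#' @export
readGwas <- function(path, columnMap = DEFAULT_COLUMN_MAP, trait,
                     traitType = c("quantitative", "binary"), n = NULL,
                     nCase = NA_real_, sep = NULL) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("cannot read GWAS file: ", path, call. = FALSE)
  required <- setdiff(SNP_COLUMNS, c("eaf", "n_case"))
  miss <- setdiff(required, names(columnMap))
  if (length(miss))
    stop("columnMap missing required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(sep)) {
    con <- gzfile(path, "rt"); on.exit(close(con))
    header <- readLines(con, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  absent <- setdiff(unname(columnMap[names(columnMap) %in% required]), names(raw))
  if (length(absent))
    stop("column(s) named in columnMap absent from file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in SNP_COLUMNS) {
    src <- if (field %in% names(columnMap)) columnMap[[field]] else NULL
    out[[field]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA
  }
  gwasSummary(out, trait = trait, traitType = traitType, n = n, nCase = nCase)
}

#' Write a GwasSummary to a TSV file
#'
#' Writes the validated records with the default canonical column names so
#' the file round-trips through \code{\link{readGwas}}.
#'
#' @param gwas a \code{GwasSummary}.
#' @param path output path (".gz" suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeGwas <- function(gwas, path) {
  stopifnot(is(gwas, "GwasSummary"))
  out <- gwas@records
  names(out) <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                  "pval", "n", "n_case")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome GWAS onto a shared effect allele
#'
#' For each instrument, the outcome record is aligned to the exposure's
#' effect allele: identical allele pairs are kept as-is; swapped alleles
#' (effect/other exchanged) negate the outcome beta and flip its frequency;
#' strand-complement pairs (and swapped complements) are complemented first,
#' provided the pair is not palindromic. Palindromic pairs (A/T, C/G) are
#' always dropped, regardless of allele frequency, because their strand is
#' ambiguous. Any other allele combination is dropped as a mismatch, and
#' instruments absent from the outcome are dropped as missing.
#'
#' @param exposure,outcome \code{GwasSummary} objects.
#' @param instrumentRsids rsids of the instruments (must all be present in
#'   the exposure records).
#' @return a \code{\linkS4class{HarmonizedData}}; retained and dropped rsids
#'   partition \code{instrumentRsids}.
#' @export
harmonize <- function(exposure, outcome, instrumentRsids) {
  stopifnot(is(exposure, "GwasSummary"), is(outcome, "GwasSummary"))
  instrumentRsids <- unique(as.character(instrumentRsids))
  if (!length(instrumentRsids)) stop("empty instrument list", call. = FALSE)
  missingExp <- setdiff(instrumentRsids, exposure@records$rsid)
  if (length(missingExp))
    stop("instrument(s) absent from exposure records: ",
         paste(missingExp, collapse = ", "), call. = FALSE)

  exp <- exposure@records[match(instrumentRsids, exposure@records$rsid), ]
  outIdx <- match(instrumentRsids, outcome@records$rsid)

  kept <- vector("list", length(instrumentRsids))
  drop <- vector("list", length(instrumentRsids))
  for (i in seq_along(instrumentRsids)) {
    rs <- instrumentRsids[i]
    e <- exp[i, ]
    if (isPalindromic(e$effect_allele, e$other_allele)) {
      drop[[i]] <- data.frame(rsid = rs, reason = "palindromic")
      next
    }
    if (is.na(outIdx[i])) {
      drop[[i]] <- data.frame(rsid = rs, reason = "missing_in_outcome")
      next
    }
    o <- outcome@records[outIdx[i], ]
    ea <- o$effect_allele; oa <- o$other_allele
    betaOut <- o$beta
    matched <- FALSE
    if (ea == e$effect_allele && oa == e$other_allele) {
      matched <- TRUE
    } else if (ea == e$other_allele && oa == e$effect_allele) {
      betaOut <- -betaOut; matched <- TRUE
    } else {
      # try the strand complement (safe: exposure pair is non-palindromic)
      cea <- complementAllele(ea); coa <- complementAllele(oa)
      if (cea == e$effect_allele && coa == e$other_allele) {
        matched <- TRUE
      } else if (cea == e$other_allele && coa == e$effect_allele) {
        betaOut <- -betaOut; matched <- TRUE
      }
    }
    if (!matched) {
      drop[[i]] <- data.frame(rsid = rs, reason = "allele_mismatch")
      next
    }
    kept[[i]] <- data.frame(rsid = rs, beta_exp = e$beta, se_exp = e$se,
                            beta_out = betaOut, se_out = o$se,
                            eaf_exp = e$eaf, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, kept[!vapply(kept, is.null, TRUE)])
  dropped <- do.call(rbind, drop[!vapply(drop, is.null, TRUE)])
  if (is.null(snps))
    snps <- data.frame(rsid = character(), beta_exp = numeric(),
                       se_exp = numeric(), beta_out = numeric(),
                       se_out = numeric(), eaf_exp = numeric())
  if (is.null(dropped))
    dropped <- data.frame(rsid = character(), reason = character())
  rownames(snps) <- rownames(dropped) <- NULL
  new("HarmonizedData", exposureTrait = exposure@trait,
      outcomeTrait = outcome@trait, outcomeType = outcome@traitType,
      snps = snps, dropped = dropped)
}

#' Write harmonized data and its drop log as TSV
#'
#' @param hd a \code{HarmonizedData}.
#' @param path output path for the retained-SNP table; the drop log goes to
#'   \code{dropLogPath}.
#' @param dropLogPath path for the drop log (default: \code{path} with a
#'   \code{.droplog.tsv} suffix).
#' @return \code{path}, invisibly.
#' @export
writeHarmonized <- function(hd, path,
                            dropLogPath = sub("\\.tsv$", "", path)) {
  stopifnot(is(hd, "HarmonizedData"))
  if (identical(dropLogPath, sub("\\.tsv$", "", path)))
    dropLogPath <- paste0(dropLogPath, ".droplog.tsv")
  write.table(hd@snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hd@dropped, dropLogPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Build a HarmonizedData from already-aligned per-SNP vectors
#'
#' Convenience constructor for data whose alleles are consistent by
#' construction (e.g. simulator output, or tables harmonized elsewhere).
#'
#' @param rsid,betaExp,seExp,betaOut,seOut aligned per-SNP vectors.
#' @param eafExp exposure effect-allele frequency (recycled; NA allowed).
#' @param exposureTrait,outcomeTrait trait labels.
#' @param outcomeType \code{"quantitative"} or \code{"binary"}.
#' @return a \code{\linkS4class{HarmonizedData}} with an empty drop log.
#' @export
harmonizedData <- function(rsid, betaExp, seExp, betaOut, seOut,
                           eafExp = NA_real_, exposureTrait = "exposure",
                           outcomeTrait = "outcome",
                           outcomeType = "quantitative") {
  new("HarmonizedData", exposureTrait = exposureTrait,
      outcomeTrait = outcomeTrait, outcomeType = outcomeType,
      snps = data.frame(rsid = as.character(rsid), beta_exp = betaExp,
                        se_exp = seExp, beta_out = betaOut, se_out = seOut,
                        eaf_exp = rep_len(eafExp, length(rsid)),
                        stringsAsFactors = FALSE),
      dropped = data.frame(rsid = character(), reason = character()))
}
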