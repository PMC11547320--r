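# Study orchestration: per-outcome MR with the full method suite,
# sensitivity instrument sets driven by confounder flags and colocalization,
# sex-specific and bidirectional analyses, meta-analysis across outcome
# GWAS, and the final classified report.

ALL_METHODS <- c("ivw", "pivw", "egger", "weighted_median", "weighted_mode",
                 "presso_raw", "presso_corrected")

resolveGwas <- function(x) {
  if (is(x, "GwasSummary")) return(x)
  if (is.list(x) && !is.null(x$path))
    return(do.call(readGwas, x))
  stop("outcome/exposure entries must be GwasSummary objects or ",
       "list(path=, trait=, ...) readGwas arguments", call. = FALSE)
}

#' Build a study run configuration
#'
#' Collects everything \code{\link{runStudy}} needs. GWAS inputs are
#' \code{GwasSummary} objects or \code{list(path =, trait =, ...)}
#' argument lists for \code{\link{readGwas}}; a configuration can also be
#' read from JSON with \code{\link{readRunConfig}}.
#'
#' @param exposure exposure GWAS.
#' @param outcomes named list; each element is a list with \code{datasets}
#'   (list of one or more outcome GWAS for the same outcome; two datasets
#'   trigger a fixed-effect meta-analysis) and optionally \code{sex}
#'   (list with \code{men} and \code{women} GWAS).
#' @param pThreshold,r2Threshold instrument selection parameters.
#' @param ld LD r-squared matrix (or path to one), or NULL.
#' @param annotations confounder annotation table (data.frame with
#'   \code{rsid}, \code{trait}, \code{pval}, or a TSV path), or NULL.
#' @param colocResults named list of \code{ColocResult}s keyed
#'   \code{"rsid|outcome"} (or data.frame with columns \code{rsid},
#'   \code{outcome}, \code{pp_h4}) backing the sensitivity-set rule.
#' @param outcomeAssociated optional data.frame (\code{rsid},
#'   \code{outcome}) declaring which flagged SNPs are also
#'   outcome-associated; a missing coloc result for such a pair is a hard
#'   error.
#' @param ppH4Threshold posterior-probability threshold above which a
#'   flagged SNP is retained as a shared (vertical) signal (default 0.8).
#' @param bootReps,pressoSims,pivwLambda,bandwidthFactor estimator settings.
#' @param nTests,alpha multiple-testing family size and base level.
#' @param seed master seed; every stochastic step derives its own stream
#'   from it.
#' @param outDir optional output directory for report TSVs and the JSON
#'   manifest.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(exposure, outcomes, pThreshold = 5e-8,
                      r2Threshold = 1e-3, ld = NULL, annotations = NULL,
                      colocResults = list(), outcomeAssociated = NULL,
                      ppH4Threshold = 0.8, bootReps = 1000,
                      pressoSims = 1000, pivwLambda = 1,
                      bandwidthFactor = 1, nTests = 15, alpha = 0.05,
                      seed = 1, outDir = NULL) {
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("'outcomes' must be a named list", call. = FALSE)
  if (is.character(ld)) ld <- readLdMatrix(ld)
  if (is.character(annotations))
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  cfg <- list(exposure = exposure, outcomes = outcomes,
              pThreshold = pThreshold, r2Threshold = r2Threshold, ld = ld,
              annotations = annotations, colocResults = colocResults,
              outcomeAssociated = outcomeAssociated,
              ppH4Threshold = ppH4Threshold, bootReps = bootReps,
              pressoSims = pressoSims, pivwLambda = pivwLambda,
              bandwidthFactor = bandwidthFactor, nTests = nTests,
              alpha = alpha, seed = seed, outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from JSON
#'
#' The JSON keys mirror the arguments of \code{\link{runConfig}}; GWAS
#' entries are \code{\{"path": ..., "trait": ..., "traitType": ...\}}
#' objects resolved through \code{\link{readGwas}} at run time.
#'
#' @param path JSON file path.
#' @return a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- raw
  for (scalar in c("pThreshold", "r2Threshold", "ppH4Threshold", "bootReps",
                   "pressoSims", "pivwLambda", "bandwidthFactor", "nTests",
                   "alpha", "seed", "outDir", "ld"))
    if (!is.null(raw[[scalar]])) args[[scalar]] <- raw[[scalar]][[1]]
  if (!is.null(raw$annotations))
    args$annotations <- as.character(raw$annotations[[1]])
  do.call(runConfig, args)
}

# Normalize coloc results to a data.frame (rsid, outcome, pp_h4).
colocTable <- function(colocResults) {
  if (is.data.frame(colocResults)) {
    stopifnot(all(c("rsid", "outcome", "pp_h4") %in% names(colocResults)))
    return(colocResults)
  }
  if (!length(colocResults))
    return(data.frame(rsid = character(), outcome = character(),
                      pp_h4 = numeric()))
  keys <- strsplit(names(colocResults), "|", fixed = TRUE)
  data.frame(rsid = vapply(keys, `[`, "", 1),
             outcome = vapply(keys, `[`, "", 2),
             pp_h4 = vapply(colocResults, function(cr) {
               if (is(cr, "ColocResult")) unname(cr@pp[["PP_H4"]])
               else as.numeric(cr)
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Build main and per-outcome sensitivity instrument sets
#'
#' The main set contains every instrument. For each outcome, the
#' sensitivity set excludes confounder-flagged instruments unless their
#' colocalization with that outcome supports a shared causal variant
#' (PP_H4 at or above \code{ppH4Threshold}), in which case the association
#' is treated as vertical pleiotropy and the SNP is kept. Exclusion
#' reasons are recorded in the \code{"exclusions"} attribute.
#'
#' @param instruments an \code{InstrumentSet} (after
#'   \code{\link{screenConfounders}}).
#' @param outcomes character vector of outcome labels.
#' @param colocResults named list of \code{ColocResult}s keyed
#'   \code{"rsid|outcome"}, or a data.frame (\code{rsid}, \code{outcome},
#'   \code{pp_h4}).
#' @param ppH4Threshold retention threshold on PP_H4 (default 0.8).
#' @param outcomeAssociated optional data.frame (\code{rsid},
#'   \code{outcome}): flagged SNPs declared outcome-associated must have a
#'   coloc result for that outcome, otherwise a hard error names the pair.
#' @return named list of rsid vectors: \code{main} plus
#'   \code{sensitivity_<outcome>} for every outcome, with an
#'   \code{"exclusions"} attribute (data.frame: set, rsid, reason).
#' @export
buildSensitivitySets <- function(instruments, outcomes, colocResults = list(),
                                 ppH4Threshold = 0.8,
                                 outcomeAssociated = NULL) {
  stopifnot(is(instruments, "InstrumentSet"))
  rsids <- instruments@snps$rsid
  flags <- instruments@confounderFlags
  ct <- colocTable(colocResults)
  sets <- list(main = rsids)
  exclusions <- data.frame(set = character(), rsid = character(),
                           reason = character(), stringsAsFactors = FALSE)
  for (out in outcomes) {
    keep <- rsids
    for (rs in rsids) {
      if (!length(flags[[rs]])) next
      hit <- ct[ct$rsid == rs & ct$outcome == out, , drop = FALSE]
      if (!nrow(hit)) {
        if (!is.null(outcomeAssociated) &&
            any(outcomeAssociated$rsid == rs & outcomeAssociated$outcome == out))
          stop(sprintf(paste0("flagged instrument %s is associated with ",
                              "outcome '%s' but has no colocalization ",
                              "result"), rs, out), call. = FALSE)
        keep <- setdiff(keep, rs)
        exclusions <- rbind(exclusions, data.frame(
          set = paste0("sensitivity_", out), rsid = rs,
          reason = paste0("confounder_flag:",
                          paste(flags[[rs]], collapse = ","))))
      } else if (max(hit$pp_h4) >= ppH4Threshold) {
        # shared causal variant: vertical pleiotropy, keep
      } else {
        keep <- setdiff(keep, rs)
        exclusions <- rbind(exclusions, data.frame(
          set = paste0("sensitivity_", out), rsid = rs,
          reason = sprintf("pp_h4=%.3g<%g", max(hit$pp_h4), ppH4Threshold)))
      }
    }
    sets[[paste0("sensitivity_", out)]] <- keep
  }
  attr(sets, "exclusions") <- exclusions
  sets
}

# Run the full estimator suite on one HarmonizedData; returns a list of
# MrEstimate plus the leave-one-out table and PRESSO detail. Methods whose
# minimum instrument count is not met are skipped with a note.
runEstimatorSuite <- function(hd, cfg, seed) {
  ests <- list()
  notes <- character()
  presso <- NULL
  tryAdd <- function(label, fun) {
    res <- tryCatch(fun(), error = function(e) conditionMessage(e))
    if (is.character(res)) notes[[label]] <<- res else ests[[label]] <<- res
  }
  tryAdd("ivw", function() mrIvw(hd))
  tryAdd("pivw", function() mrPivw(hd, lambda = cfg$pivwLambda))
  tryAdd("egger", function() mrEgger(hd))
  tryAdd("weighted_median", function()
    mrWeightedMedian(hd, bootReps = cfg$bootReps,
                     seed = childSeed(seed, "wmedian")))
  tryAdd("weighted_mode", function()
    mrWeightedMode(hd, bandwidthFactor = cfg$bandwidthFactor,
                   bootReps = cfg$bootReps, seed = childSeed(seed, "wmode")))
  if (nSnp(hd) >= 4) {
    presso <- tryCatch(mrPresso(hd, nSim = cfg$pressoSims,
                                seed = childSeed(seed, "presso")),
                       error = function(e) NULL)
    if (!is.null(presso)) {
      ests$presso_raw <- presso$raw
      ests$presso_corrected <- presso$corrected
    }
  }
  loo <- tryCatch(leaveOneOut(hd), error = function(e) NULL)
  list(estimates = ests, loo = loo, presso = presso, notes = notes)
}

analyzeOneDataset <- function(exposure, outcomeGwas, rsids, cfg, seed,
                              label) {
  hd <- harmonize(exposure, outcomeGwas, rsids)
  if (nSnp(hd) < 2)
    stop(sprintf("%s: fewer than 2 instruments survive harmonization", label),
         call. = FALSE)
  suite <- runEstimatorSuite(hd, cfg, seed)
  c(list(harmonized = hd), suite)
}

#' Run the full MR study described by a configuration
#'
#' Executes, per outcome and per outcome dataset: harmonization, the full
#' estimator suite with diagnostics (heterogeneity, Egger intercept,
#' MR-PRESSO outliers, leave-one-out), the per-outcome sensitivity
#' instrument set (confounder flags adjudicated by colocalization),
#' sex-specific estimates with a sex-difference test, fixed-effect
#' meta-analysis when an outcome has two datasets, a power row, and the
#' Bonferroni significance class. Failures are isolated per outcome; the
#' run aborts only if every outcome fails. Fully deterministic given the
#' configuration seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return a list of class \code{"StudyReport"}: \code{instruments}
#'   (table with F, r2 and flags), \code{estimates} (long table: outcome,
#'   dataset, stratum, set, method, ...), \code{outcomes} (per-outcome
#'   detail: harmonized data, drop logs, leave-one-out, PRESSO, meta row,
#'   sex-difference p, power, class, errors), \code{significance},
#'   \code{sets}, and \code{manifest} (seed, parameters, package version).
#'   When \code{config$outDir} is set the tables are also written as TSV
#'   plus a JSON manifest.
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  exposure <- resolveGwas(config$exposure)
  instruments <- selectInstruments(exposure, pThreshold = config$pThreshold,
                                   ld = config$ld,
                                   r2Threshold = config$r2Threshold)
  if (!is.null(config$annotations))
    instruments <- screenConfounders(instruments, config$annotations,
                                     pThreshold = config$pThreshold)
  sets <- buildSensitivitySets(instruments, names(config$outcomes),
                               colocResults = config$colocResults,
                               ppH4Threshold = config$ppH4Threshold,
                               outcomeAssociated = config$outcomeAssociated)

  estRows <- list()
  outcomeReports <- list()
  pooledP <- c()
  for (outName in names(config$outcomes)) {
    spec <- config$outcomes[[outName]]
    rep <- tryCatch({
      datasets <- lapply(spec$datasets, resolveGwas)
      if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
        names(datasets) <- paste0("dataset", seq_along(datasets))
      setsHere <- list(main = sets$main,
                       sensitivity = sets[[paste0("sensitivity_", outName)]])
      detail <- list()
      ivwPerDataset <- list()
      caseFractions <- c(); totalN <- 0
      for (ds in names(datasets)) {
        g <- datasets[[ds]]
        totalN <- totalN + g@n
        if (!is.na(g@nCase)) caseFractions <- c(caseFractions, g@nCase / g@n)
        for (setName in names(setsHere)) {
          seed <- childSeed(config$seed, paste(outName, ds, setName))
          res <- analyzeOneDataset(exposure, g, setsHere[[setName]], config,
                                   seed, paste(outName, ds, setName))
          detail[[paste(ds, setName, sep = ".")]] <- res
          for (m in names(res$estimates)) {
            row <- estimateTable(res$estimates[[m]])
            row <- cbind(data.frame(outcome = outName, dataset = ds,
                                    stratum = "overall", set = setName), row)
            estRows[[length(estRows) + 1L]] <- row
          }
          if (setName == "main") ivwPerDataset[[ds]] <- res$estimates$ivw
        }
      }
      meta <- NULL
      if (length(ivwPerDataset) >= 2)
        meta <- metaFixed(unname(ivwPerDataset))

      sexP <- NA_real_
      sexEst <- list()
      if (!is.null(spec$sex)) {
        for (sx in c("men", "women")) {
          g <- resolveGwas(spec$sex[[sx]])
          seed <- childSeed(config$seed, paste(outName, sx))
          res <- analyzeOneDataset(exposure, g, sets$main, config, seed,
                                   paste(outName, sx))
          detail[[paste0("sex.", sx)]] <- res
          sexEst[[sx]] <- res$estimates$ivw
          for (m in names(res$estimates)) {
            row <- estimateTable(res$estimates[[m]])
            row <- cbind(data.frame(outcome = outName, dataset = "sex",
                                    stratum = sx, set = "main"), row)
            estRows[[length(estRows) + 1L]] <- row
          }
        }
        sexP <- sexDifferenceTest(sexEst$men, sexEst$women)
      }

      power <- NULL
      if (instruments@r2Total > 0 && instruments@r2Total < 1) {
        cf <- if (length(caseFractions)) mean(caseFractions) else NA_real_
        power <- minDetectableEffect(n = totalN, caseFraction = cf,
                                     r2 = instruments@r2Total,
                                     alpha = config$alpha)
      }

      headline <- if (!is.null(meta)) meta@pval else {
        firstMain <- detail[[paste(names(datasets)[1], "main", sep = ".")]]
        firstMain$estimates$ivw@pval
      }
      pooledP[outName] <- headline
      list(status = "ok", detail = detail, meta = meta, sexDifferenceP = sexP,
           power = power, headlineP = headline)
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    outcomeReports[[outName]] <- rep
  }

  okOutcomes <- names(Filter(function(x) identical(x$status, "ok"),
                             outcomeReports))
  if (!length(okOutcomes))
    stop("no outcome could be analyzed; first error: ",
         outcomeReports[[1]]$message, call. = FALSE)

  signif <- classifySignificance(pooledP, nTests = config$nTests,
                                 alpha = config$alpha)
  for (outName in names(signif))
    outcomeReports[[outName]]$class <- unname(signif[outName])

  instrumentTable <- data.frame(
    instruments@snps[c("rsid", "chrom", "pos", "beta", "se", "pval", "eaf")],
    f_stat = instruments@fStats, r2 = instruments@r2PerSnp,
    flags = vapply(instruments@confounderFlags, paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  report <- list(instruments = instrumentTable,
                 instrumentSet = instruments,
                 estimates = do.call(rbind, estRows),
                 outcomes = outcomeReports,
                 significance = signif,
                 sets = sets,
                 manifest = list(seed = config$seed,
                                 pThreshold = config$pThreshold,
                                 r2Threshold = config$r2Threshold,
                                 ppH4Threshold = config$ppH4Threshold,
                                 nTests = config$nTests, alpha = config$alpha,
                                 package = as.character(packageVersion("mrpipe"))))
  class(report) <- "StudyReport"
  if (!is.null(config$outDir)) writeStudyReport(report, config$outDir)
  report
}

#' Write a StudyReport's tables to a directory
#'
#' Emits \code{estimates.tsv}, \code{instruments.tsv},
#' \code{significance.tsv}, per-outcome leave-one-out and drop-log TSVs,
#' and \code{manifest.json}.
#'
#' @param report a \code{StudyReport}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(inherits(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$estimates, file.path(dir, "estimates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$instruments, file.path(dir, "instruments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(outcome = names(report$significance),
                         class = unname(report$significance)),
              file.path(dir, "significance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (outName in names(report$outcomes)) {
    rep <- report$outcomes[[outName]]
    if (!identical(rep$status, "ok")) next
    for (key in names(rep$detail)) {
      d <- rep$detail[[key]]
      if (!is.null(d$loo))
        write.table(d$loo, file.path(dir, sprintf("loo_%s_%s.tsv", outName,
                                                  key)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      writeHarmonized(d$harmonized,
                      file.path(dir, sprintf("harmonized_%s_%s.tsv", outName,
                                             key)))
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport:", length(x$outcomes), "outcome(s),",
      nrow(x$instruments), "instrument(s)\n")
  for (outName in names(x$outcomes)) {
    rep <- x$outcomes[[outName]]
    if (identical(rep$status, "ok"))
      cat(sprintf("  %s: headline p = %.3g [%s]\n", outName, rep$headlineP,
                  rep$class))
    else cat(sprintf("  %s: FAILED (%s)\n", outName, rep$message))
  }
  invisible(x)
}

#' Swap exposure and outcome roles in a configuration
#'
#' Returns a configuration in which the named outcome's first dataset
#' becomes the exposure and the original exposure becomes the sole
#' outcome. Applying the swap twice returns a configuration equivalent to
#' the forward one.
#'
#' @param config a \code{RunConfig}.
#' @param outcome which outcome to promote to exposure (default: first).
#' @return a \code{RunConfig} for the reverse-direction analysis.
#' @export
swapRoles <- function(config, outcome = names(config$outcomes)[1]) {
  stopifnot(inherits(config, "RunConfig"))
  fwdExposure <- config$exposure
  newExposure <- config$outcomes[[outcome]]$datasets[[1]]
  cfg <- config
  cfg$exposure <- newExposure
  cfg$outcomes <- setNames(
    list(list(datasets = setNames(list(fwdExposure), "dataset1"))),
    if (is(fwdExposure, "GwasSummary")) fwdExposure@trait else "exposure")
  cfg$colocResults <- list()
  cfg$outcomeAssociated <- NULL
  cfg$annotations <- NULL
  attr(cfg, "swappedFrom") <- outcome
  cfg
}

#' Reverse-direction (bidirectional) MR analysis
#'
#' For each outcome in the forward configuration, selects instruments from
#' the outcome GWAS under the same thresholds, swaps exposure and outcome
#' roles, and runs the identical harmonization and estimation chain. An
#' outcome whose GWAS yields no instruments is reported as
#' \code{"not estimable"} instead of failing the run.
#'
#' @param config the forward \code{\link{runConfig}}.
#' @return named list (one entry per forward outcome) with \code{status}
#'   (\code{"ok"} or \code{"not estimable"}), and when ok: the reverse
#'   \code{estimates} table, the reverse \code{instruments} used (always
#'   the outcome's own, never the forward exposure's) and the full reverse
#'   \code{report}.
#' @export
runBidirectional <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  sections <- list()
  for (outName in names(config$outcomes)) {
    rev <- swapRoles(config, outName)
    sections[[outName]] <- tryCatch({
      report <- runStudy(rev)
      list(status = "ok", direction = sprintf("%s -> exposure", outName),
           estimates = report$estimates, instruments = report$instruments,
           report = report)
    }, error = function(e)
      list(status = "not estimable", direction = sprintf("%s -> exposure",
                                                         outName),
           message = conditionMessage(e)))
  }
  sections
}
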