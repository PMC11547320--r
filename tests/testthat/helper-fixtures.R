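# Shared fixture builders. Everything is generated in code; no data files.

# Minimal well-formed per-SNP records table.
makeRecords <- function(k = 9, seed = 42, ea = NULL, oa = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pair <- matrix(c("A", "G", "T", "C", "G", "T", "C", "A"), ncol = 2,
                 byrow = TRUE)
  pick <- pair[1 + (seq_len(k) - 1) %% nrow(pair), , drop = FALSE]
  data.frame(
    rsid = sprintf("rs%03d", seq_len(k)),
    chrom = as.character(1 + (seq_len(k) - 1) %% 22),
    pos = 1000 * seq_len(k),
    effect_allele = if (is.null(ea)) pick[, 1] else rep_len(ea, k),
    other_allele = if (is.null(oa)) pick[, 2] else rep_len(oa, k),
    eaf = round(runif(k, 0.05, 0.95), 3),
    beta = round(rnorm(k, 0, 0.05), 5),
    se = round(runif(k, 0.003, 0.01), 5),
    pval = signif(runif(k, 1e-30, 1e-9), 4),
    n = 100000,
    stringsAsFactors = FALSE)
}

makeGwas <- function(k = 9, seed = 42, trait = "exposure",
                     traitType = "quantitative", ...) {
  gwasSummary(makeRecords(k, seed, ...), trait = trait, traitType = traitType)
}

# A fixed harmonized fixture with known ratios: beta_out = ratio * beta_exp.
makeHarmonized <- function(ratios, ratioSes = NULL, betaExp = NULL,
                           seExp = 1e-4, outcomeType = "quantitative") {
  k <- length(ratios)
  if (is.null(betaExp)) betaExp <- rep(0.1, k)
  if (is.null(ratioSes)) ratioSes <- rep(0.05, k)
  harmonizedData(rsid = sprintf("rs%03d", seq_len(k)), betaExp = betaExp,
                 seExp = rep_len(seExp, k), betaOut = ratios * betaExp,
                 seOut = ratioSes * abs(betaExp), outcomeType = outcomeType)
}

# Forward-only causal world for bidirectional checks: the exposure has k
# instruments whose outcome effects are purely mediated (causal beta), and
# the outcome has its own m instruments with zero exposure effect. Both
# GWAS contain all k + m SNPs.
makeDirectionalPair <- function(seed, k = 20, m = 20, nExp = 4e5,
                                nOut = 1e5, beta = 0.3, r2X = 4e-4,
                                r2Y = 1e-3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tot <- k + m
  maf <- runif(tot, 0.2, 0.4)
  het <- 2 * maf * (1 - maf)
  seX <- 1 / sqrt(het * nExp)
  seY <- 1 / sqrt(het * nOut)
  gammaX <- c(sqrt(r2X / het[1:k]), rep(0, m))           # exposure arch.
  deltaY <- c(rep(0, k), sqrt(r2Y / het[k + 1:m]))       # outcome arch.
  bX <- rnorm(tot, gammaX, seX)
  bY <- rnorm(tot, beta * gammaX + deltaY, seY)
  base <- data.frame(rsid = sprintf("rsd%03d", 1:tot), chrom = "1",
                     pos = 1e4 * (1:tot),
                     effect_allele = "A", other_allele = "G", eaf = maf,
                     stringsAsFactors = FALSE)
  expDf <- cbind(base, beta = bX, se = seX,
                 pval = pmax(2 * pnorm(-abs(bX / seX)), 1e-300), n = nExp)
  outDf <- cbind(base, beta = bY, se = seY,
                 pval = pmax(2 * pnorm(-abs(bY / seY)), 1e-300), n = nOut)
  list(exposure = gwasSummary(expDf, trait = "exposure"),
       outcome = gwasSummary(outDf, trait = "outcome"),
       outcomeOwnRsids = base$rsid[k + 1:m])
}

# Independent closed-form WLS solve via normal equations (test oracle).
wlsSolve <- function(y, X, w) {
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  est <- solve(A, b)
  covUnscaled <- solve(A)
  list(coef = as.vector(est), se = sqrt(diag(covUnscaled)))
}
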