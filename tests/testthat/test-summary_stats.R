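# GWAS summary-statistics I/O and harmonization.

test_that("readGwas validates rows, upper-cases alleles, and round-trips", {
  rec <- makeRecords(9)
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- rec
  names(out) <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                  "pval", "n")
  out$ea <- tolower(out$ea)   # lowercase alleles must be accepted
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)

  g <- readGwas(f, trait = "acetate")
  expect_s4_class(g, "GwasSummary")
  expect_equal(nSnp(g), 9)
  expect_equal(g@nDropped, 0)
  expect_true(all(snpData(g)$effect_allele %in% c("A", "C", "G", "T")))
  expect_equal(sort(snpData(g)$beta), sort(rec$beta))  # betas untouched

  # write/read round trip is bit-identical on all retained fields
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeGwas(g, f2)
  g2 <- readGwas(f2, trait = "acetate")
  expect_identical(snpData(g2), snpData(g))

  # invalid rows are dropped and counted: se = 0 and palindromic-ok but
  # identical alleles
  bad <- out
  bad$se[2] <- 0
  bad$oa[5] <- bad$ea[5]
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  g3 <- readGwas(f3, trait = "acetate")
  expect_equal(nSnp(g3), 7)
  expect_equal(g3@nDropped, 2)
})

test_that("readGwas error paths: missing file, bad column map, zero rows", {
  expect_error(readGwas("/nonexistent/file.tsv", trait = "x"), "cannot read")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(a = 1), f, sep = "\t", row.names = FALSE)
  expect_error(readGwas(f, columnMap = c(rsid = "rsid"), trait = "x"),
               "columnMap missing")
  expect_error(readGwas(f, trait = "x"), "absent from file")
  # all rows invalid -> empty-input error
  rec <- makeRecords(2)
  rec$se <- 0
  expect_error(gwasSummary(rec, trait = "x"), "no valid")
})

test_that("duplicate rsids keep the smallest-p record", {
  rec <- makeRecords(4)
  rec$rsid[2] <- rec$rsid[1]
  rec$pval[1] <- 1e-20; rec$pval[2] <- 1e-10
  g <- gwasSummary(rec, trait = "x")
  expect_equal(nSnp(g), 3)
  expect_equal(g@nDropped, 1)
  expect_equal(snpData(g)$pval[snpData(g)$rsid == rec$rsid[1]], 1e-20)
})

test_that("harmonize handles matches, swaps, complements and palindromes", {
  expRec <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
                       chrom = "1", pos = 1:6 * 100,
                       effect_allele = c("A", "A", "A", "A", "A", "A"),
                       other_allele = c("G", "G", "G", "G", "T", "G"),
                       eaf = 0.4, beta = 0.1, se = 0.01, pval = 1e-10,
                       n = 1e5)
  outRec <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                       chrom = "1", pos = 1:5 * 100,
                       # identical, swapped, complement, swapped complement,
                       # palindromic in exposure
                       effect_allele = c("A", "G", "T", "C", "A"),
                       other_allele = c("G", "A", "C", "T", "T"),
                       eaf = c(0.4, 0.3, 0.4, 0.6, 0.4),
                       beta = c(0.05, 0.05, 0.05, 0.05, 0.05), se = 0.02,
                       pval = 1e-4, n = 2e5)
  expo <- gwasSummary(expRec, trait = "exposure")
  outc <- gwasSummary(outRec, trait = "outcome")
  hd <- harmonize(expo, outc, expRec$rsid)

  s <- snpData(hd)
  expect_equal(s$beta_out[s$rsid == "rs1"], 0.05)    # identical: unchanged
  expect_equal(s$beta_out[s$rsid == "rs2"], -0.05)   # swap: negated
  expect_equal(s$beta_out[s$rsid == "rs3"], 0.05)    # complement: unchanged
  expect_equal(s$beta_out[s$rsid == "rs4"], -0.05)   # swap+complement
  d <- droppedSnps(hd)
  expect_equal(d$reason[d$rsid == "rs5"], "palindromic")
  expect_equal(d$reason[d$rsid == "rs6"], "missing_in_outcome")
  # retained + dropped partition the instrument list
  expect_setequal(c(s$rsid, d$rsid), expRec$rsid)
})

test_that("mismatched alleles are dropped, empty instrument list errors", {
  expo <- makeGwas(3, ea = "A", oa = "G")
  rec <- makeRecords(3, ea = "A", oa = "C")  # incompatible pair for rs in expo
  outc <- gwasSummary(rec, trait = "outcome")
  hd <- harmonize(expo, outc, snpData(expo)$rsid)
  expect_equal(nSnp(hd), 0)
  expect_true(all(droppedSnps(hd)$reason == "allele_mismatch"))
  expect_error(harmonize(expo, outc, character()), "empty instrument")
  expect_error(harmonize(expo, outc, "rs999"), "absent from exposure")
})

test_that("harmonization is idempotent and sign-consistent under random strand/swap perturbations", {
  set.seed(20240917)
  for (i in 1:100) {
    k <- sample(4:10, 1)
    expo <- makeGwas(k, seed = i)
    outRec <- makeRecords(k, seed = i + 5000)
    # same alleles as exposure (aligned by rsid), then randomly swap
    # and/or complement
    ord <- match(outRec$rsid, snpData(expo)$rsid)
    outRec$effect_allele <- snpData(expo)$effect_allele[ord]
    outRec$other_allele <- snpData(expo)$other_allele[ord]
    ref <- harmonize(expo, gwasSummary(outRec, trait = "out"), outRec$rsid)

    pert <- outRec
    swap <- runif(k) < 0.5
    comp <- runif(k) < 0.5
    tmp <- pert$effect_allele[swap]
    pert$effect_allele[swap] <- pert$other_allele[swap]
    pert$other_allele[swap] <- tmp
    pert$beta[swap] <- -pert$beta[swap]
    pert$eaf[swap] <- 1 - pert$eaf[swap]
    pert$effect_allele[comp] <- unname(
      c(A = "T", C = "G", G = "C", T = "A")[pert$effect_allele[comp]])
    pert$other_allele[comp] <- unname(
      c(A = "T", C = "G", G = "C", T = "A")[pert$other_allele[comp]])
    got <- harmonize(expo, gwasSummary(pert, trait = "out"), outRec$rsid)
    expect_equal(snpData(got)$beta_out, snpData(ref)$beta_out)
    expect_equal(snpData(got)$rsid, snpData(ref)$rsid)

    # idempotence: re-harmonizing the already-harmonized pairs changes nothing
    s <- snpData(ref)
    ord2 <- match(s$rsid, snpData(expo)$rsid)
    expo2 <- gwasSummary(data.frame(
      rsid = s$rsid, chrom = "1", pos = seq_along(s$rsid),
      effect_allele = snpData(expo)$effect_allele[ord2],
      other_allele = snpData(expo)$other_allele[ord2],
      eaf = 0.3, beta = s$beta_exp, se = s$se_exp, pval = 1e-10, n = 1e5),
      trait = "exp2")
    outc2 <- gwasSummary(data.frame(
      rsid = s$rsid, chrom = "1", pos = seq_along(s$rsid),
      effect_allele = snpData(expo)$effect_allele[ord2],
      other_allele = snpData(expo)$other_allele[ord2],
      eaf = 0.3, beta = s$beta_out, se = s$se_out, pval = 1e-4, n = 1e5),
      trait = "out2")
    again <- harmonize(expo2, outc2, s$rsid)
    expect_equal(nSnp(again), nrow(s))
    expect_equal(snpData(again)$beta_out, s$beta_out)
  }
})
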