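make_spec <- function(ids, mode = "presence", risk = "A") {
  data.frame(variant_id = ids, chromosome = "1",
             position = seq_along(ids) * 1000L, gene = "G",
             risk_allele = risk, mode = mode, stringsAsFactors = FALSE)
}

test_that("TSV genotypes load as hand-computed counts", {
  tmp <- file.path(tempdir(), "g.tsv")
  writeLines(c("subject_id\trs1\trs2",
               "s1\t0\t2", "s2\t1\tNA", "s3\t2\t0"), tmp)
  gm <- readGenotypes(tmp, "tsv", make_spec(c("rs1", "rs2")))
  g <- genotypeCounts(gm)
  expect_identical(unname(g[, "rs1"]), c(0L, 1L, 2L))
  expect_identical(unname(g[, "rs2"]), c(2L, NA, 0L))
})

test_that("VCF genotype counts are oriented to the risk allele", {
  tmp <- file.path(tempdir(), "g.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
               "1\t100\trs1\tC\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
               "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./."), tmp)
  spec <- make_spec(c("rs1", "rs2"), risk = c("A", "A"))
  gm <- readGenotypes(tmp, "vcf", spec)
  g <- genotypeCounts(gm)
  expect_identical(unname(g[, "rs1"]), c(1L, 0L, 2L))   # risk = ALT
  expect_identical(unname(g[, "rs2"]), c(2L, 1L, NA))   # risk = REF: flipped
  ## risk allele matching neither REF nor ALT is a hard error
  expect_error(readGenotypes(tmp, "vcf", make_spec("rs1", risk = "T")),
               "rs1")
  ## a spec variant absent from the file lands in the read report
  gm2 <- readGenotypes(tmp, "vcf", make_spec(c("rs1", "rs2", "rs99")))
  expect_identical(
    S4Vectors::metadata(gm2)$readReport$missingVariants, "rs99")
})

test_that("PLINK .raw counted-allele orientation is honored", {
  tmp <- file.path(tempdir(), "g.raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
               "f1 s1 0 0 1 1 2 0",
               "f2 s2 0 0 2 2 1 2"), tmp)
  spec <- make_spec(c("rs1", "rs2"), risk = c("A", "A"))
  gm <- readGenotypes(tmp, "plink_raw", spec)
  g <- genotypeCounts(gm)
  expect_identical(unname(g[, "rs1"]), c(2L, 1L))   # counted = risk
  expect_identical(unname(g[, "rs2"]), c(2L, 0L))   # counted = other: 2 - x
})

test_that("mode imputation replaces by the most frequent code", {
  g <- cbind(rs1 = c(0L, 0L, 0L, NA), rs2 = c(2L, 2L, 1L, 2L))
  gm <- GenotypeMatrix(g, make_spec(c("rs1", "rs2")))
  out <- genotypeCounts(imputeMissing(gm, "mode", maxMissing = 0.3))
  expect_identical(unname(out[, "rs1"]), c(0L, 0L, 0L, 0L))
  ## no-missing input returned unchanged by either method
  gm2 <- GenotypeMatrix(cbind(rs1 = c(1L, 2L), rs2 = c(0L, 0L)),
                        make_spec(c("rs1", "rs2")))
  expect_identical(genotypeCounts(imputeMissing(gm2, "mode")),
                   genotypeCounts(gm2))
  expect_identical(genotypeCounts(imputeMissing(gm2, "iterative_forest")),
                   genotypeCounts(gm2))
  ## fully missing variant is a hard error
  gm3 <- GenotypeMatrix(cbind(rs1 = c(NA, NA), rs2 = c(0L, 1L)),
                        make_spec(c("rs1", "rs2")))
  expect_error(imputeMissing(gm3, "mode", maxMissing = 1), "rs1")
})

test_that("forest imputation beats mode imputation on structured data", {
  ## two blocks of perfectly correlated variants: the forest can read a
  ## masked genotype off its partners, the per-variant mode cannot
  set.seed(42)
  n <- 120
  base1 <- rbinom(n, 2, 0.45)
  base2 <- rbinom(n, 2, 0.45)
  g <- cbind(a1 = base1, a2 = base1, a3 = base1,
             b1 = base2, b2 = base2, b3 = base2)
  mask <- matrix(FALSE, n, 6)
  mask[sample(length(mask), 25)] <- TRUE
  gma <- g; gma[mask] <- NA
  gm <- GenotypeMatrix(gma, make_spec(colnames(g)))
  truth <- g[mask]
  acc_mode <- mean(genotypeCounts(
    imputeMissing(gm, "mode", maxMissing = 0.2))[mask] == truth)
  acc_rf <- mean(genotypeCounts(
    imputeMissing(gm, "iterative_forest", seed = 1,
                  maxMissing = 0.2))[mask] == truth)
  expect_gte(acc_rf, acc_mode)
  expect_gt(acc_rf, 0.9)
})

test_that("dominant-model incidence encoding honors presence and absence modes", {
  g <- cbind(rs1 = c(0L, 1L, 2L, 0L), hla = c(0L, 0L, 1L, 2L))
  spec <- make_spec(c("rs1", "hla"), mode = c("presence", "absence"))
  gm <- GenotypeMatrix(g, spec, phenotype = c(1, 1, 0, 0))
  I <- encodeIncidence(gm)
  X <- incidence(I)
  expect_identical(unname(X[, "rs1"]), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(unname(X[, "hla"]), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unname(X[, "MS"]), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(itemIds(I), c("rs1", "hla", "MS"))
  ## missing codes refuse encoding
  gm2 <- GenotypeMatrix(cbind(rs1 = c(NA, 1L)), make_spec("rs1"),
                        phenotype = c(1, 0))
  expect_error(encodeIncidence(gm2), "imputeMissing")
})

test_that("incidence encoding round-trips through its TSV serialization", {
  cfg <- syntheticCohortConfig(nCases = 15, nControls = 10, nVariants = 6,
                               seed = 13, missingRate = 0)
  I <- encodeIncidence(simulateCohort(cfg))
  tmp <- file.path(tempdir(), "inc.tsv")
  writeIncidence(I, tmp)
  I2 <- readIncidence(tmp, "MS")
  expect_identical(incidence(I2), incidence(I))
  expect_identical(phenotypeItem(I2), "MS")
})

test_that("orientation invariance: flipping REF/ALT with the risk allele is a no-op", {
  tmpa <- file.path(tempdir(), "a.vcf"); tmpb <- file.path(tempdir(), "b.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  writeLines(c(hdr, "1\t100\trs1\tC\tA\t.\tPASS\t.\tGT\t0/1\t1/1"), tmpa)
  ## same subjects, REF/ALT swapped and genotype codes complemented
  writeLines(c(hdr, "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0"), tmpb)
  ga <- genotypeCounts(readGenotypes(tmpa, "vcf", make_spec("rs1", risk = "A")))
  gb <- genotypeCounts(readGenotypes(tmpb, "vcf", make_spec("rs1", risk = "A")))
  expect_identical(ga, gb)
})

test_that("item frequency tracks dominant carrier frequency under HWE", {
  cfg <- syntheticCohortConfig(nCases = 300, nControls = 300,
                               nVariants = 40, mafRange = c(0.3, 0.3),
                               patterns = list(), substructureEffect = 0,
                               nSubstructureDims = 0,
                               missingRate = 0, baselinePrevalence = 0.5,
                               seed = 17)
  I <- encodeIncidence(simulateCohort(cfg))
  f <- colMeans(incidence(I)[, seq_len(40)])
  expected <- 1 - (1 - 0.3)^2              # 0.51 under HWE
  ## each item within binomial 99.9% bounds; mean much tighter
  bound <- 3.3 * sqrt(expected * (1 - expected) / 600)
  expect_true(all(abs(f - expected) < bound + 0.02))
  expect_lt(abs(mean(f) - expected), 0.01)
})

test_that("classical MDS separates a two-group cohort", {
  set.seed(23)
  n <- 60
  grp <- rep(c(0, 1), each = n / 2)
  maf <- runif(25, 0.1, 0.4)
  shift <- plogis(qlogis(maf) + 1.5)
  g <- sapply(seq_len(25), function(j)
    rbinom(n, 2, ifelse(grp == 1, shift[j], maf[j])))
  colnames(g) <- sprintf("v%02d", 1:25)
  gm <- GenotypeMatrix(g, make_spec(colnames(g)))
  ## identical subjects are at distance zero: duplicate row 1
  g2 <- g; g2[2, ] <- g2[1, ]
  d <- dist(g2, method = "manhattan") / (2 * ncol(g2))
  expect_equal(as.matrix(d)[1, 2], 0)

  mds <- computeSubstructure(gm, k = 3)
  expect_identical(dim(mds), c(as.integer(n), 3L))
  expect_true(all(is.finite(mds)))
  expect_gt(abs(cor(mds[, 1], grp)), 0.9)
  expect_error(computeSubstructure(gm, k = n), "smaller")
})
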