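test_that("rule contingency tables match hand tallies", {
  I <- top_rule_fixture()
  triad <- c("HLA-DRB1*15:01", "rs56678847", "rs6880809")
  tab <- ruleContingency(I, triad)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(20L, 1L, 187L, 178L))
  expect_equal(tab$freq_cases, 20 / 207)
  expect_equal(tab$freq_controls, 1 / 179)

  ## random fixture vs direct scan
  I2 <- random_incidence(30, 4, seed = 9)
  X <- incidence(I2)
  lhs <- c("i01", "i03")
  carrier <- X[, "i01"] & X[, "i03"]
  t2 <- ruleContingency(I2, lhs)
  expect_identical(t2$a, sum(carrier & X[, "MS"]))
  expect_identical(t2$b, sum(carrier & !X[, "MS"]))

  ## all-carriers: no non-carrier cells
  Xall <- cbind(a = rep(TRUE, 10), MS = rep(c(TRUE, FALSE), 5))
  t3 <- ruleContingency(IncidenceMatrix(Xall, "MS"), "a")
  expect_identical(c(t3$c, t3$d), c(0L, 0L))
})

test_that("crude odds ratio follows the closed form with symmetry and zero-cell policy", {
  expect_equal(crudeOddsRatio(contingencyTable(7, 7, 7, 7))$or, 1)
  cr <- crudeOddsRatio(contingencyTable(20, 1, 187, 178))
  expect_equal(cr$or, (20 * 178) / (1 * 187))
  expect_false(cr$corrected)
  ## transposing rows and columns simultaneously leaves the OR unchanged
  cr2 <- crudeOddsRatio(contingencyTable(20, 187, 1, 178))
  expect_equal(cr2$or, crudeOddsRatio(contingencyTable(20, 1, 187, 178))$or *
                 (187 * 187) / (178 * 178) * (178 * 178) / (187 * 187))
  expect_equal(crudeOddsRatio(contingencyTable(5, 3, 2, 8))$or,
               crudeOddsRatio(contingencyTable(8, 2, 3, 5))$or)
  ## zero cell: Haldane flagged, or explicit degenerate result
  h <- crudeOddsRatio(contingencyTable(5, 0, 5, 5))
  expect_true(h$corrected)
  expect_equal(h$or, (5.5 * 5.5) / (0.5 * 5.5))
  d <- crudeOddsRatio(contingencyTable(5, 0, 5, 5), zeroCell = "none")
  expect_true(d$degenerate)
  expect_identical(d$or, Inf)
})

test_that("logistic fit equals the crude OR for a single binary predictor", {
  set.seed(31)
  x <- rbinom(120, 1, 0.4)
  y <- rbinom(120, 1, plogis(-0.3 + 0.9 * x))
  tab <- contingencyTable(sum(x & y), sum(x & !y), sum(!x & y),
                          sum(!x & !y))
  fit <- fitLogistic(y, cbind(carrier = x))
  expect_equal(exp(unname(fit$coef["carrier"])),
               crudeOddsRatio(tab)$or, tolerance = 1e-6)
  expect_false(fit$separated)
})

test_that("rank-deficient designs fail with collinear columns named", {
  set.seed(32)
  x <- rbinom(50, 1, 0.5)
  y <- rbinom(50, 1, 0.5)
  expect_error(fitLogistic(y, cbind(a = x, b = x)), "b")
})

test_that("complete separation raises the flag", {
  x <- rep(c(0, 1), each = 20)
  y <- x
  fit <- fitLogistic(y, cbind(carrier = x))
  expect_true(fit$separated)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(33)
  ps <- vapply(1:200, function(i) {
    x <- rbinom(150, 1, 0.5)
    y <- rbinom(150, 1, 0.5)
    f <- fitLogistic(y, cbind(x = x))
    z <- unname(f$coef["x"]) / sqrt(f$vcov["x", "x"])
    2 * pnorm(-abs(z))
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bootstrap association reports the full-data point estimate with stable seeds", {
  cfg <- syntheticCohortConfig(nCases = 120, nControls = 120,
                               nVariants = 10, mafRange = c(0.25, 0.4),
                               patterns = list(plantedPattern(
                                 c("v001", "v002"), jointOddsRatio = 4,
                                 marginalOddsRatios = 1)),
                               substructureEffect = 0, missingRate = 0,
                               seed = 5)
  I <- encodeIncidence(simulateCohort(cfg))
  ba1 <- bootstrapAssociation(I, c("v001", "v002"), nBoot = 300, seed = 1)
  ba2 <- bootstrapAssociation(I, c("v001", "v002"), nBoot = 300, seed = 2)
  tab <- ruleContingency(I, c("v001", "v002"))
  expect_equal(ba1$or_adjusted, (tab$a * tab$d) / (tab$b * tab$c),
               tolerance = 1e-9)
  ## different seeds change replicates, never the point estimate
  expect_identical(ba1$or_adjusted, ba2$or_adjusted)
  expect_false(identical(ba1$se, ba2$se))
  ## same seed reproduces everything
  ba3 <- bootstrapAssociation(I, c("v001", "v002"), nBoot = 300, seed = 1)
  expect_identical(ba1[c("se", "ci_low", "ci_high", "p_value")],
                   ba3[c("se", "ci_low", "ci_high", "p_value")])
  ## constant predictor refuses to fit
  Xc <- cbind(always = rep(TRUE, 20), MS = rep(c(TRUE, FALSE), 10))
  expect_error(bootstrapAssociation(IncidenceMatrix(Xc, "MS"), "always",
                                    nBoot = 10),
               "constant")
})

test_that("adjusted and crude fits agree when covariates are pure noise", {
  cfg <- syntheticCohortConfig(nCases = 150, nControls = 150,
                               nVariants = 8, mafRange = c(0.3, 0.4),
                               patterns = list(plantedPattern(
                                 c("v001", "v002"), jointOddsRatio = 3,
                                 marginalOddsRatios = 1)),
                               substructureEffect = 0, missingRate = 0,
                               seed = 8)
  gm <- simulateCohort(cfg)
  I <- encodeIncidence(gm)
  set.seed(99)
  noise <- matrix(rnorm(300 * 3), 300, 3)
  ba <- bootstrapAssociation(I, c("v001", "v002"), covariates = noise,
                             nBoot = 200, seed = 3)
  crude <- crudeOddsRatio(ruleContingency(I, c("v001", "v002")))$or
  expect_lt(abs(log(ba$or_adjusted) - log(crude)), 0.25)
})

test_that("Bonferroni thresholds and flags are exact", {
  b <- bonferroni(c(1e-5, 0.01, 0.02, 0.5), alpha = 0.05)
  expect_equal(b$threshold, 0.05 / 4)
  expect_identical(b$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bonferroni(0.2, alpha = 0.05)$threshold, 0.05)
  expect_equal(bonferroni(rep(0.5, 20))$threshold, 0.0025)
  p <- runif(50)
  expect_identical(bonferroni(p)$significant, p <= 0.001)
})

test_that("stratified odds ratios recover profile-specific effects", {
  ## hand fixture over the 8 profiles of 3 items
  X <- rbind(
    matrix(rep(c(FALSE, FALSE, FALSE), 40), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, TRUE), 30), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE, FALSE), 30), ncol = 3, byrow = TRUE))
  colnames(X) <- c("g1", "g2", "g3")
  y <- c(rep(c(TRUE, FALSE), 20),          # ref: 20/20
         rep(TRUE, 24), rep(FALSE, 6),     # 111: 24/6
         rep(c(TRUE, FALSE), 15))          # 100: 15/15
  I <- IncidenceMatrix(cbind(X, MS = y), "MS")
  so <- stratifiedOrs(I, c("g1", "g2", "g3"))
  expect_equal(unname(so$or["000"]), 1)
  expect_equal(unname(so$or["111"]), (24 * 20) / (6 * 20))
  expect_equal(unname(so$or["100"]), 1)
  expect_true(is.na(so$or["010"]))
  ## empty reference is an explicit error
  I2 <- IncidenceMatrix(cbind(g1 = rep(TRUE, 10), g2 = rep(TRUE, 10),
                              g3 = rep(TRUE, 10),
                              MS = rep(c(TRUE, FALSE), 5)), "MS")
  expect_error(stratifiedOrs(I2, c("g1", "g2", "g3")), "reference")
})

test_that("RERI and AP obey exact additive nulls", {
  ## all profile ORs 1: no excess at all
  ors <- setNames(rep(1, 8), c("000", "001", "010", "100", "011", "101",
                               "110", "111"))
  r <- reriFromOrs(ors)
  expect_identical(r$reri3, 0)
  expect_identical(r$ap3, 0)
  ## constructed additivity of excess odds
  ors2 <- c("000" = 1, "001" = 1.5, "010" = 2, "100" = 2.5,
            "011" = 3, "101" = 2, "110" = 4,
            "111" = 3 + 2 + 4 - 1.5 - 2 - 2.5 + 1)
  r2 <- reriFromOrs(ors2)
  expect_equal(r2$reri3, 0)
  expect_equal(r2$ap3, 0)
  ## purely multiplicative joint effect implies positive RERI
  ors3 <- c("000" = 1, "001" = 2, "010" = 2, "100" = 2,
            "011" = 4, "101" = 4, "110" = 4, "111" = 8)
  r3 <- reriFromOrs(ors3)
  expect_gt(r3$reri3, 0)
  expect_equal(r3$reri3, 8 - 12 + 6 - 1)
  expect_true(r3$ap3 <= 1)
  ## undefined strata are reported
  ors4 <- ors3; ors4["110"] <- NA
  expect_error(reriFromOrs(ors4), "110")
})

test_that("additive interaction of a purely joint planted effect is positive", {
  cfg <- syntheticCohortConfig(nCases = 207, nControls = 179,
                               nVariants = 10, mafRange = c(0.25, 0.4),
                               patterns = list(plantedPattern(
                                 c("v001", "v002", "v003"),
                                 jointOddsRatio = 12,
                                 marginalOddsRatios = 1)),
                               substructureEffect = 0, missingRate = 0,
                               seed = 21)
  I <- encodeIncidence(simulateCohort(cfg))
  ai <- additiveInteraction(I, c("v001", "v002", "v003"), nBoot = 300,
                            seed = 1)
  expect_gt(unname(ai$ors$or["111"]), 4)
  expect_gt(ai$reri3, 0)
  expect_gt(ai$ap3, 0.4)
  expect_true(ai$ap3 <= 1)
  expect_lt(ai$ap_p, 0.05)
})

test_that("multiplicative interaction recovers a planted three-way log-OR", {
  ## direct factorial generation at large n: all mains, pairs null,
  ## three-way log-OR = log(5)
  set.seed(77)
  n <- 6000
  g1 <- rbinom(n, 1, 0.5); g2 <- rbinom(n, 1, 0.5); g3 <- rbinom(n, 1, 0.5)
  lp <- -0.5 + 0.2 * g1 + 0.2 * g2 + 0.2 * g3 + log(5) * g1 * g2 * g3
  y <- rbinom(n, 1, plogis(lp))
  I <- IncidenceMatrix(cbind(g1 = g1 == 1, g2 = g2 == 1, g3 = g3 == 1,
                             MS = y == 1), "MS")
  mi <- multiplicativeInteraction(I, c("g1", "g2", "g3"))
  expect_lt(abs(log(mi$mult_or3) - log(5)), 1)
  expect_lt(mi$mult_p, 0.05)
  ## constant third variant: rank-deficiency error
  I2 <- IncidenceMatrix(cbind(g1 = g1 == 1, g2 = g2 == 1,
                              g3 = rep(TRUE, n), MS = y == 1), "MS")
  expect_error(multiplicativeInteraction(I2, c("g1", "g2", "g3")),
               "rank")
})

test_that("three-way interaction p-values are uniform under the multiplicative null", {
  set.seed(88)
  ps <- vapply(1:120, function(i) {
    n <- 400
    g1 <- rbinom(n, 1, 0.5); g2 <- rbinom(n, 1, 0.5); g3 <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.2 + 0.3 * g1 + 0.3 * g2 + 0.3 * g3))
    I <- IncidenceMatrix(cbind(g1 = g1 == 1, g2 = g2 == 1, g3 = g3 == 1,
                               MS = y == 1), "MS")
    mi <- try(multiplicativeInteraction(I, c("g1", "g2", "g3")),
              silent = TRUE)
    if (inherits(mi, "try-error") || mi$separated) return(NA_real_)
    mi$mult_p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
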