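test_that("SNI detection follows the motif-length ladder", {
  expect_false(detectSNI(c(240, 244, 248, 252), 4))
  expect_true(detectSNI(c(240, 244, 249), 4))
  expect_error(detectSNI(c(10, 11), 1), "motifLength")
  expect_error(detectSNI(c(10), 3), "2 alleles")
  # invariance under adding a constant
  set.seed(121)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    sizes <- 150 + k * sample(0:12, 5)
    if (runif(1) < 0.5) sizes[3] <- sizes[3] + 1
    shift <- sample(1:50, 1) * k
    expect_identical(detectSNI(sizes, k), detectSNI(sizes + shift, k))
  }
})

test_that("a planted off-ladder allele at frequency 0.1 is detected in
           nearly all cohorts of 48", {
  set.seed(131)
  hits <- vapply(1:300, function(s) {
    sim <- simulateGenotypes(nPerPop = c(24, 24), nLoci = 1,
                             targetFst = 0, sniLoci = 1, sniFreq = 0.1,
                             missingRate = 0, seed = 3000 + s)
    calls <- alleleCalls(sim$gm, 1)
    k <- lociInfo(sim$gm)$motif_length[1]
    sizes <- unique(c(calls))
    length(unique(sizes %% k)) > 1
  }, NA)
  expect_gte(mean(hits), 0.99)
})

test_that("panel construction reproduces the published marker table", {
  prof <- wftMarkerLoci()
  ps <- buildPanels(prof)
  expect_identical(sort(panelMembers(ps, "SNI")),
                   sort(c("wft4-S22", "wft3-S27", "wft3-S28",
                          "wft4-S30", "wft3-S33", "wft4-S52",
                          "wft3-S53", "wft3-S60")))
  expect_identical(sort(panelMembers(ps, "MP")),
                   sort(c("wft4-S32", "wft3-S01", "wft4-S57",
                          "wft4-S58", "wft3-S21", "wft4-S26",
                          "wft4-S31", "wft3-S43")))
  expect_identical(sort(panelMembers(ps, "SS")),
                   sort(c("wft3-S08", "wft4-S09", "wft4-S13",
                          "wft3-S14", "wft3-S43", "wft4-S45",
                          "wft4-S50", "wft4-S58")))
  expect_identical(length(panelMembers(ps, "ALL")), 30L)
  # ambiguous peaks exclude wft3-S01 from SS despite full amplification
  dec <- panelDecisions(ps)
  s01 <- dec[dec$locus == "wft3-S01" & dec$panel == "SS", ]
  expect_match(s01$rule, "AMBIGUOUS_PEAKS")
  # determinism / idempotence
  expect_identical(buildPanels(prof)@panels, ps@panels)
  # every locus has exactly one decision per panel
  expect_identical(nrow(dec), 30L * 4L)
})

test_that("MP ranking includes all loci tied at the cut", {
  prof <- data.frame(
    locus = sprintf("L%02d", 1:12),
    n_alleles = c(17, 16, 13, 12, 11, 11, 11, 11, 9, 8, 7, 6),
    sni = FALSE, amplified_in_all = TRUE, ambiguous_peaks = FALSE,
    hwe_deviant_all_pops = FALSE)
  ps <- buildPanels(prof, k = 8)
  expect_identical(length(panelMembers(ps, "MP")), 8L)
  # force a tie across the cut: five loci at 11 for ranks 5-9
  prof$n_alleles[9] <- 11
  ps2 <- buildPanels(prof, k = 8)
  expect_identical(length(panelMembers(ps2, "MP")), 9L)
})

test_that("assignment is perfect on fixed differences and
           uninformative on identical populations", {
  A1 <- matrix(100L, 20, 5); A2 <- matrix(130L, 20, 5)
  gm <- genotypeMatrix(rbind(A1, A2), rbind(A1, A2),
                       rep(c("p1", "p2"), each = 20))
  asg <- assignIndividuals(gm, lociNames(gm))
  expect_true(all(asg$correct))
  expect_equal(min(pmax(asg$Q_p1, asg$Q_p2)), 1)

  set.seed(141)
  a <- matrix(sample(c(100L, 104L, 108L), 100, TRUE), 20, 5)
  b <- matrix(sample(c(100L, 104L, 108L), 100, TRUE), 20, 5)
  gm2 <- genotypeMatrix(rbind(pmin(a, b), pmin(a, b)),
                        rbind(pmax(a, b), pmax(a, b)),
                        rep(c("p1", "p2"), each = 20))
  asg2 <- assignIndividuals(gm2, lociNames(gm2))
  expect_lt(abs(mean(asg2$Q_p1) - 0.5), 0.05)
  expect_identical(sum(asg2$correct), 0L)
})

test_that("raising the Q threshold never increases the correct count",
{
  sim <- simulateGenotypes(nLoci = 8, targetFst = 0.10, seed = 151,
                           missingRate = 0)
  counts <- vapply(c(0, 0.5, 0.6, 0.8, 0.95), function(q)
    sum(assignIndividuals(sim$gm, lociNames(sim$gm),
                          qThreshold = q)$correct), 1L)
  expect_true(all(diff(counts) <= 0L))
  # threshold 0 is pure maximum likelihood
  asg0 <- assignIndividuals(sim$gm, lociNames(sim$gm), qThreshold = 0)
  expect_identical(asg0$correct, asg0$assigned == asg0$pop)
})

test_that("clean low-noise panels assign better than noisy ones", {
  set.seed(161)
  rates <- vapply(1:40, function(s) {
    sim <- simulateGenotypes(nPerPop = c(24, 23), nLoci = 8,
                             targetFst = 0.10, missingRate = 0,
                             seed = 5000 + s)
    clean <- mean(assignIndividuals(sim$gm,
                                    lociNames(sim$gm))$correct,
                  na.rm = TRUE)
    # corrupt 20% of genotypes: random allele replacement
    A <- sim$gm@alleleA; B <- sim$gm@alleleB
    noisy <- matrix(runif(length(A)) < 0.2, nrow(A))
    for (j in seq_len(ncol(A))) {
      pool <- unique(c(A[, j], B[, j]))
      idx <- which(noisy[, j])
      if (length(idx)) {
        A[idx, j] <- sample(pool, length(idx), TRUE)
        B[idx, j] <- sample(pool, length(idx), TRUE)
      }
    }
    gmN <- genotypeMatrix(pmin(A, B), pmax(A, B), sim$gm@pop,
                          lociInfo(sim$gm))
    c(clean, mean(assignIndividuals(gmN, lociNames(gmN))$correct,
                  na.rm = TRUE))
  }, numeric(2))
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("Mann-Whitney agrees with full enumeration for small
           samples", {
  expect_equal(mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))$W, 0)
  set.seed(171)
  for (r in 1:30) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:6, m, TRUE); y <- sample(1:6, n, TRUE)  # with ties
    expect_equal(mannWhitneyTest(x, y)$p.value, mwOracle(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
  # identical samples: p in the null region
  expect_equal(mannWhitneyTest(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # 8 vs 8 tie-free: exact path agrees with the enumeration oracle
  set.seed(172)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(mannWhitneyTest(x, y)$p.value, mwOracle(x, y))
})

test_that("picking top-Na panels inflates expected heterozygosity", {
  set.seed(181)
  bias <- vapply(1:100, function(s) {
    sim <- simulateGenotypes(nPerPop = c(24, 23), nLoci = 20,
                             targetFst = 0.02, missingRate = 0,
                             seed = 7000 + s)
    hePerLocus <- vapply(lociNames(sim$gm), function(loc)
      mean(locusSummary(sim$gm, loc)$he), 1)
    naPerLocus <- vapply(lociNames(sim$gm), function(loc) {
      calls <- alleleCalls(sim$gm, loc)
      length(unique(c(calls)[!is.na(c(calls))]))
    }, 1L)
    top <- order(-naPerLocus)[1:8]
    rnd <- sample(20, 8)
    mean(hePerLocus[top]) - mean(hePerLocus[rnd])
  }, 1)
  expect_gt(mean(bias), 0)
  expect_gt(mean(bias > 0), 0.8)
})

test_that("panel comparison produces coherent statistics", {
  sim <- simulateGenotypes(nLoci = 12, targetFst = 0.08, seed = 191,
                           sniLoci = c(2, 5), sniFreq = 0.15,
                           missingRate = 0.02)
  prof <- data.frame(
    locus = lociNames(sim$gm),
    n_alleles = vapply(lociNames(sim$gm), function(loc) {
      calls <- alleleCalls(sim$gm, loc)
      length(unique(c(calls)[!is.na(c(calls))]))
    }, 1L),
    sni = seq_len(12) %in% c(2, 5),
    amplified_in_all = vapply(lociNames(sim$gm), function(loc)
      !anyNA(alleleCalls(sim$gm, loc)[, 1]), NA),
    ambiguous_peaks = FALSE, hwe_deviant_all_pops = FALSE)
  ps <- buildPanels(prof, k = 4)
  cmp <- comparePanels(sim$gm, ps)
  expect_true(all(c("MP", "SNI", "SS", "ALL") %in%
                    cmp$diversity$panel))
  expect_true(all(cmp$diversity$mean_he >= 0 &
                    cmp$diversity$mean_he <= 1, na.rm = TRUE))
  expect_true(all(cmp$tests$p >= 0 & cmp$tests$p <= 1))
  # a panel against itself is at the null: symmetric samples
  x <- cmp$diversity$mean_ar
  mw <- mannWhitneyTest(x, x)
  expect_equal(mw$p.value, 1)
  # PCA sign convention: largest |loading| positive per component
  pca <- cmp$pca$ALL
  expect_true(!is.null(pca$scores))
})

test_that("PCA separates differentiated populations and fixes signs",
{
  sim <- simulateGenotypes(nLoci = 10, targetFst = 0.25, seed = 201,
                           missingRate = 0.05)
  pc <- panelPCA(sim$gm, lociNames(sim$gm))
  pops <- popLabels(sim$gm)
  d1 <- mean(pc$scores[pops == "MT", 1]) -
    mean(pc$scores[pops == "YQ", 1])
  expect_gt(abs(d1), 1)  # populations separate on PC1
  pc2 <- panelPCA(sim$gm, lociNames(sim$gm))
  expect_identical(pc$scores, pc2$scores)  # deterministic incl. sign
})
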