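test_that("heterozygosities match hand-computed values", {
  # genotypes 1/1, 1/2, 2/2, 1/2, 1/1: p = (0.6, 0.4)
  g <- cbind(c(1, 1, 2, 1, 1), c(1, 2, 2, 2, 1))
  gm <- genotypeMatrix(g[, 1, drop = FALSE], g[, 2, drop = FALSE],
                       rep("p1", 5))
  ls <- locusSummary(gm, 1)
  expect_equal(ls$ho, 0.4)
  expect_equal(ls$he, (10 / 9) * (1 - 0.6^2 - 0.4^2))
  expect_identical(ls$na, 2L)
  # monomorphic locus
  gm2 <- genotypeMatrix(matrix(7L, 5), matrix(7L, 5), rep("p1", 5))
  ls2 <- locusSummary(gm2, 1)
  expect_identical(ls2$na, 1L)
  expect_equal(ls2$ho, 0)
  expect_equal(ls2$he, 0)
})

test_that("He is invariant under allele relabeling; Ho complements the
           homozygote fraction", {
  set.seed(61)
  for (r in 1:10) {
    calls <- cbind(sample(1:4, 30, TRUE), sample(1:4, 30, TRUE))
    gm <- genotypeMatrix(pmin(calls[, 1], calls[, 2]),
                         pmax(calls[, 1], calls[, 2]), rep("p", 30))
    ls <- locusSummary(gm, 1)
    shuffled <- c(40, 10, 30, 20)[calls]
    dim(shuffled) <- dim(calls)
    gm2 <- genotypeMatrix(pmin(shuffled[, 1], shuffled[, 2]),
                          pmax(shuffled[, 1], shuffled[, 2]),
                          rep("p", 30))
    expect_equal(locusSummary(gm2, 1)$he, ls$he)
    hom <- mean(calls[, 1] == calls[, 2])
    expect_equal(ls$ho + hom, 1)
  }
})

test_that("allelic richness matches closed-form binomials and bounds", {
  expect_equal(allelicRichness(c(6, 4), g = 2),
               (1 - 6 / 45) + (1 - 15 / 45))
  expect_equal(allelicRichness(c(6, 4), g = 10), 2)  # g = 2n: AR = Na
  # g = 1: one gene, one allele, for any polymorphic locus
  for (cnt in list(c(3, 7), c(1, 1, 8), c(2, 2, 2, 4)))
    expect_equal(allelicRichness(cnt, g = 1), 1)
  expect_error(allelicRichness(c(3, 3), g = 7), "exceeds")
  # brute-force check by enumeration of all g-subsets
  cnt <- c(3, 2, 1)
  genes <- rep(1:3, cnt)
  g <- 3
  subs <- combn(length(genes), g)
  expected <- mean(apply(subs, 2, function(ix)
    length(unique(genes[ix]))))
  expect_equal(allelicRichness(cnt, g), expected)
})

test_that("HWE exact test matches the biallelic enumeration oracle", {
  cases <- list(c(3, 4, 3), c(10, 5, 10), c(1, 8, 1), c(12, 2, 12),
                c(0, 10, 0), c(5, 0, 5))
  for (cs in cases) {
    calls <- rbind(
      if (cs[1]) cbind(rep(1, cs[1]), rep(1, cs[1])),
      if (cs[2]) cbind(rep(1, cs[2]), rep(2, cs[2])),
      if (cs[3]) cbind(rep(2, cs[3]), rep(2, cs[3])))
    expect_equal(hweExactTest(calls, method = "enumeration"),
                 hweBiallelicOracle(cs[1], cs[2], cs[3]),
                 info = paste(cs, collapse = "/"))
  }
  # extreme heterozygote excess
  allHet <- cbind(rep(1, 50), rep(2, 50))
  expect_lt(hweExactTest(allHet), 0.001)
  # monomorphic locus
  expect_identical(hweExactTest(cbind(rep(1, 20), rep(1, 20))), 1)
})

test_that("Monte-Carlo HWE agrees with enumeration and is seed-stable",
{
  set.seed(71)
  calls <- cbind(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE))
  pEnum <- hweExactTest(calls, method = "enumeration")
  pMC1 <- hweExactTest(calls, method = "monte_carlo", reps = 2e4,
                       seed = 5)
  pMC2 <- hweExactTest(calls, method = "monte_carlo", reps = 2e4,
                       seed = 5)
  expect_identical(pMC1, pMC2)
  expect_lt(abs(pMC1 - pEnum), 0.02)
})

test_that("HWE p-values are super-uniform under simulated equilibrium",
{
  set.seed(81)
  nLoci <- 400
  pvals <- vapply(seq_len(nLoci), function(i) {
    p <- runif(1, 0.2, 0.8)
    genes <- matrix(sample(1:2, 2 * 25, TRUE, prob = c(p, 1 - p)),
                    ncol = 2)
    hweExactTest(genes)
  }, 1)
  reject <- mean(pvals <= 0.05)
  # binomial 99% upper bound around nominal 0.05
  expect_lte(reject, 0.05 + 2.58 * sqrt(0.05 * 0.95 / nLoci))
})

test_that("LD permutation test flags a duplicated locus and is
           seed-stable", {
  set.seed(91)
  a <- cbind(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))
  b <- cbind(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))
  A <- cbind(pmin(a[, 1], a[, 2]), pmin(b[, 1], b[, 2]))
  B <- cbind(pmax(a[, 1], a[, 2]), pmax(b[, 1], b[, 2]))
  gm <- genotypeMatrix(cbind(A, A[, 1]), cbind(B, B[, 1]),
                       rep("p", 30))
  reps <- 400
  pDup <- ldTest(gm, 1, 3, reps = reps, seed = 2)
  expect_lte(pDup, 1 / (reps + 1) + 1e-12)
  p1 <- ldTest(gm, 1, 2, reps = reps, seed = 3)
  p2 <- ldTest(gm, 1, 2, reps = reps, seed = 3)
  expect_identical(p1, p2)
  # insufficient data is flagged, not an error
  gmSmall <- genotypeMatrix(A[1:4, ], B[1:4, ], rep("p", 4))
  expect_warning(pNA <- ldTest(gmSmall, 1, 2, reps = 50, seed = 1),
                 "fewer than 5")
  expect_true(is.na(pNA))
})

test_that("LD p-values are roughly uniform for independent loci", {
  set.seed(101)
  nSim <- 150
  pv <- vapply(seq_len(nSim), function(i) {
    a <- cbind(sample(1:3, 25, TRUE), sample(1:3, 25, TRUE))
    b <- cbind(sample(1:4, 25, TRUE), sample(1:4, 25, TRUE))
    gm <- genotypeMatrix(cbind(pmin(a[, 1], a[, 2]),
                               pmin(b[, 1], b[, 2])),
                         cbind(pmax(a[, 1], a[, 2]),
                               pmax(b[, 1], b[, 2])), rep("p", 25))
    ldTest(gm, 1, 2, reps = 300)
  }, 1)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null-allele EM recovers planted frequencies and increases
           the likelihood monotonically", {
  # no-signal case: data at exact Hardy-Weinberg proportions
  g <- rbind(matrix(1L, 25, 2),
             cbind(rep(1L, 50), rep(2L, 50)),
             matrix(2L, 25, 2))
  em <- nullAlleleEM(g)
  expect_lt(em$r, 0.01)
  expect_true(all(diff(em$loglik) > -1e-8))
  # recovery at r = 0.2, n = 200, several seeds
  rs <- vapply(1:5, function(s) {
    sim <- simulateGenotypes(nPerPop = c(100, 100), nLoci = 1,
                             targetFst = 0, nullRate = 0.2,
                             missingRate = 0, seed = 100 + s)
    nullAlleleEM(alleleCalls(sim$gm, 1))$r
  }, 1)
  expect_true(all(rs > 0.12 & rs < 0.28))
  # degenerate saturation: every individual a distinct homozygote
  gd <- cbind(1:20, 1:20)
  emd <- nullAlleleEM(gd)
  expect_gt(emd$r, 0.4)
})

test_that("sequential Bonferroni reproduces Holm's step-down", {
  expect_identical(sequentialBonferroni(0.04), TRUE)
  expect_identical(sequentialBonferroni(0.06), FALSE)
  expect_identical(sequentialBonferroni(c(0.001, 0.02, 0.04)),
                   c(TRUE, TRUE, TRUE))
  expect_identical(sequentialBonferroni(c(0.001, 0.03, 0.04)),
                   c(TRUE, FALSE, FALSE))
  # order independence
  p <- c(0.03, 0.001, 0.04)
  expect_identical(sequentialBonferroni(p),
                   sequentialBonferroni(rev(p))[c(3, 2, 1)])
})

test_that("summarizeLoci assembles a coherent per-locus table", {
  sim <- simulateGenotypes(nLoci = 6, seed = 77)
  s <- summarizeLoci(sim$gm, hweReps = 2000, seed = 1)
  expect_identical(nrow(s$perPop), 12L)
  ok <- s$perPop$n > 0
  expect_true(all(s$perPop$ho[ok] >= 0 & s$perPop$ho[ok] <= 1))
  expect_true(all(s$perPop$he[ok] >= 0 & s$perPop$he[ok] <= 1))
  expect_true(all(s$perPop$ar[ok] <= s$perPop$na[ok] + 1e-9))
  expect_true(all(s$perPop$hwe_p[ok] >= 0 & s$perPop$hwe_p[ok] <= 1))
  expect_identical(nrow(s$perLocus), 6L)
})
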