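test_that("context extraction truncates flanks at scaffold ends", {
  genome <- c(sc = paste(rep("ACGT", 500), collapse = ""))  # 2000 bp
  rec <- data.frame(sequence_id = "sc", start = 501, end = 530)
  ctx <- extractContext(rec, genome)
  expect_identical(nchar(ctx$upstream), 300L)
  expect_identical(nchar(ctx$downstream), 300L)
  expect_false(ctx$upstream_truncated || ctx$downstream_truncated)

  rec2 <- data.frame(sequence_id = "sc", start = 100, end = 130)
  ctx2 <- extractContext(rec2, genome)
  expect_identical(nchar(ctx2$upstream), 99L)
  expect_true(ctx2$upstream_truncated)

  rec3 <- data.frame(sequence_id = "sc", start = 1971, end = 2000)
  ctx3 <- extractContext(rec3, genome)
  expect_identical(nchar(ctx3$downstream), 0L)
  expect_error(extractContext(
    data.frame(sequence_id = "nope", start = 1, end = 10), genome),
    "scaffold not found")
})

test_that("primer design respects length, Tm and pairing constraints", {
  set.seed(41)
  sim <- simulateGenome(list(list(motif = "AGC", units = 12)),
                        scaffoldLength = 2000, gcContent = 0.45,
                        seed = 42)
  rec <- scanGenome(sim$genome)
  ctx <- makeContexts(rec, sim$genome)[[1]]
  pr <- designPrimers(ctx)
  expect_gt(nrow(pr), 0)
  lens <- nchar(c(pr$forward_seq, pr$reverse_seq))
  expect_true(all(lens >= 18 & lens <= 24))
  expect_true(all(pr$forward_tm >= 58 & pr$forward_tm <= 62))
  expect_true(all(pr$reverse_tm >= 58 & pr$reverse_tm <= 62))
  expect_true(all(abs(pr$forward_tm - pr$reverse_tm) < 4))
  # best pair first: rank score is non-decreasing
  sc <- abs(nchar(pr$forward_seq) - 20) + abs(pr$forward_tm - 60) +
    abs(nchar(pr$reverse_seq) - 20) + abs(pr$reverse_tm - 60)
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("all-AT flanks admit no primer windows", {
  ctx <- list(scaffold_id = "s",
              record = data.frame(sequence_id = "s", start = 301,
                                  end = 336, motif = "AGC",
                                  mismatches = 0L),
              upstream = strrep("AT", 150),
              downstream = strrep("TA", 150),
              target = strrep("AGC", 12))
  expect_identical(nrow(designPrimers(ctx)), 0L)
})

# A flank with no SSR, no secondary tandem of >= 4 units and no
# homopolymer >= 8 bp, by rejection sampling.
cleanFlank <- function(len = 300L, gc = 0.45) {
  repeat {
    f <- paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                      prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2,
                               gc / 2)), collapse = "")
    tr <- findTandemRepeats(f, minUnits = 4L)
    homop <- tr$motif_length == 1L & (tr$end - tr$start + 1L) > 7L
    if (nrow(scanSequence(f)) == 0L &&
        !any(tr$motif_length > 1L) && !any(homop)) return(f)
  }
}

# Context built directly from screened flanks; truth is exact.
cleanContext <- function(motif, units, mmOffsets = integer(),
                         downstream = NULL) {
  target <- rep(strsplit(motif, "")[[1]], units)
  for (pos in mmOffsets)
    target[pos] <- setdiff(c("A", "C", "G", "T"), target[pos])[1]
  target <- paste(target, collapse = "")
  if (is.null(downstream)) downstream <- cleanFlank()
  list(scaffold_id = "syn",
       record = data.frame(sequence_id = "syn", start = 301,
                           end = 300 + nchar(target),
                           motif = canonicalMotif(motif),
                           mismatches = length(mmOffsets)),
       upstream = cleanFlank(), downstream = downstream,
       upstream_truncated = FALSE, downstream_truncated = FALSE,
       target = target)
}

test_that("stringent filter passes a clean candidate and audits planted
           violations one rule at a time", {
  set.seed(40)
  audit <- stringentFilter(list(cleanContext("AGC", 12)))
  expect_true(audit$passed)
  expect_identical(audit$failed_rules, "")
  expect_identical(audit$repeats, 12L)

  expect_identical(
    stringentFilter(list(cleanContext("AG", 15)))$failed_rules,
    "MOTIF_CLASS")
  expect_identical(
    stringentFilter(list(cleanContext("AGGC", 7)))$failed_rules,
    "MIN_REPEATS")
  expect_identical(
    stringentFilter(list(cleanContext("AAT", 10,
                                      mmOffsets = 15)))$failed_rules,
    "PERFECT_ONLY")

  # a nanosatellite 15 bp into the downstream flank sits inside every
  # admissible amplicon (reverse 3' end must be > 10 bp away)
  dn <- cleanFlank()
  substr(dn, 15, 30) <- strrep("AC", 8)
  nano <- stringentFilter(list(cleanContext("AGC", 12,
                                            downstream = dn)))
  expect_identical(nano$failed_rules, "SINGLE_TARGET_AMPLICON")

  # homopolymer just after the repeat
  dn2 <- cleanFlank()
  substr(dn2, 15, 24) <- strrep("T", 10)
  homo <- stringentFilter(list(cleanContext("AGC", 12,
                                            downstream = dn2)))
  expect_identical(homo$failed_rules, "SINGLE_TARGET_AMPLICON")
})

test_that("relaxing a threshold never removes a passing locus", {
  set.seed(44)
  sim <- simulateGenome(list(list(motif = "ACT", units = 10),
                             list(motif = "AGAT", units = 9)),
                        scaffoldLength = 4000, gcContent = 0.45,
                        seed = 106)
  ctxs <- makeContexts(scanGenome(sim$genome), sim$genome)
  strict <- stringentFilter(ctxs)
  relaxedUnits <- stringentFilter(ctxs, minUnits = 5L)
  relaxedMotif <- stringentFilter(ctxs, motifClasses = 2:5)
  expect_true(all(strict$passed <= relaxedUnits$passed))
  expect_true(all(strict$passed <= relaxedMotif$passed))
})

test_that("failure audits are reproducible from the stored context", {
  set.seed(45)
  sim <- simulateGenome(list(list(motif = "AG", units = 15)),
                        scaffoldLength = 2000, gcContent = 0.45,
                        seed = 107)
  ctxs <- makeContexts(scanGenome(sim$genome), sim$genome)
  audit <- stringentFilter(ctxs)
  # re-check the named rule independently
  k <- nchar(ctxs[[1]]$record$motif)
  expect_identical(audit$failed_rules == "MOTIF_CLASS",
                   !(k %in% c(3L, 4L)))
})

test_that("nearest-neighbor Tm increases with GC content and length", {
  expect_lt(primerTm(strrep("AT", 10)), primerTm(strrep("GC", 10)))
  expect_lt(primerTm("ACGTACGTACGTACGTAC"),
            primerTm("ACGTACGTACGTACGTACGTACGT"))
  expect_error(primerTm("ACGT"), "too short")
})
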