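# Independent brute-force oracles used to validate the fast
# implementations, plus small sequence generators.

# Exhaustive SSR scan: enumerate every (start, end, motif-length)
# triple with the pattern anchored at the start, apply the reportable-
# locus rules directly, then resolve overlaps by the stated ordering.
# Written for clarity, not speed; use on short sequences only.
bruteScan <- function(seq, params = scanParams()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  pen <- params@mismatchPenalty
  rows <- list()
  for (k in params@motifLengths) {
    for (i in seq_len(max(0L, L - 2L * k + 1L))) {
      pat <- chars[i:(i + k - 1L)]
      if (any(pat == "N")) next
      if (primitivePeriod(paste(pat, collapse = "")) != k) next
      for (j in (i + 2L * k - 1L):L) {
        window <- chars[i:j]
        if (any(window == "N")) break
        expd <- pat[((seq_along(window) - 1L) %% k) + 1L]
        mm <- window != expd
        if (mm[length(mm)]) next                       # end anchored
        runs <- rle(mm)
        if (any(runs$values & runs$lengths > params@maxInterruptionRun))
          break                                        # split locus
        seedLen <- max(c(0L, runs$lengths[!runs$values]))
        if (seedLen < max(2L * k, params@minSeedLength)) next
        score <- length(window) - pen * sum(mm)
        if (score < params@minScore) next
        rows[[length(rows) + 1L]] <-
          data.frame(start = i, end = j, k = k,
                     mismatches = sum(mm), score = score,
                     pattern = paste(pat, collapse = ""))
      }
    }
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      length = integer(), mismatches = integer(),
                      score = integer(), perfect = logical()))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$score, cand$k, cand$start, cand$end), ]
  chosen <- cand[0, ]
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    chosen <- rbind(chosen, top)
    cand <- cand[cand$end < top$start | cand$start > top$end, ,
                 drop = FALSE]
  }
  chosen <- chosen[order(chosen$start), ]
  data.frame(sequence_id = "oracle", start = chosen$start,
             end = chosen$end,
             motif = vapply(chosen$pattern, canonicalMotif, ""),
             length = chosen$end - chosen$start + 1L,
             mismatches = chosen$mismatches, score = chosen$score,
             perfect = chosen$mismatches == 0L, row.names = NULL)
}

# Random sequence with planted repeats. Mismatch offsets are kept
# interior and spaced at least one seed length apart so planted loci
# stay single records.
randomSSRSequence <- function(len = 150L, nPlant = 1L,
                              allowMismatch = TRUE) {
  bg <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (nPlant == 0L) return(paste(bg, collapse = ""))
  for (u in seq_len(nPlant)) {
    k <- sample(1:6, 1L)
    repeat {
      motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
      if (primitivePeriod(motif) == k) break
    }
    guard <- max(2L * k, 8L)
    units <- ceiling((2L * guard + 6L) / k) + sample(0:4, 1L)
    rep_ <- rep(strsplit(motif, "")[[1]], units)
    if (allowMismatch && runif(1) < 0.5 &&
        length(rep_) > 2L * guard + 2L) {
      pos <- sample((guard + 1L):(length(rep_) - guard), 1L)
      rep_[pos] <- sample(setdiff(c("A", "C", "G", "T"), rep_[pos]), 1L)
    }
    start <- sample(seq_len(max(1L, len - length(rep_) + 1L)), 1L)
    bg[start:(start + length(rep_) - 1L)] <- rep_
  }
  paste(bg[seq_len(len)], collapse = "")
}

# Exact HWE p-value for a biallelic locus by direct enumeration over
# heterozygote counts (Levene's conditional distribution).
hweBiallelicOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  m1 <- 2L * nAA + nAa
  m2 <- 2L * naa + nAa
  hs <- seq(m1 %% 2L, min(m1, m2), by = 2L)
  logp <- vapply(hs, function(h) {
    n11 <- (m1 - h) / 2; n22 <- (m2 - h) / 2
    lfactorial(n) + lfactorial(m1) + lfactorial(m2) + h * log(2) -
      lfactorial(2 * n) - lfactorial(n11) - lfactorial(h) -
      lfactorial(n22)
  }, 1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(nAa, hs)]
  sum(p[p <= obs + 1e-12])
}

# Exact two-sided Mann-Whitney p by enumerating every split of the
# combined sample.
mwOracle <- function(x, y) {
  m <- length(x)
  comb <- c(x, y)
  u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u(x, y)
  ids <- combn(length(comb), m)
  us <- apply(ids, 2L, function(ix) u(comb[ix], comb[-ix]))
  min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
}

# Simple two-population genotype draw at explicit allele frequencies.
drawGenotypes <- function(freqsByPop, nPerPop, sizes) {
  pops <- rep(seq_along(nPerPop), nPerPop)
  n <- sum(nPerPop)
  A <- B <- matrix(NA_integer_, n, 1L)
  for (i in seq_len(n)) {
    f <- freqsByPop[[pops[i]]]
    g <- sample(sizes, 2L, replace = TRUE, prob = f)
    A[i, 1L] <- min(g); B[i, 1L] <- max(g)
  }
  genotypeMatrix(A, B, factor(paste0("p", pops)))
}
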