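## Exact conditional test of Hardy-Weinberg proportions.
##
## Conditional on the observed allele counts, the probability of a
## genotype array {n_ij} is
##   P = n! * prod_a(m_a!) * 2^h / ((2n)! * prod_{i<=j}(n_ij!))
## with h the number of heterozygous individuals. The p-value is the
## total probability of arrays no more probable than the observed one
## (probability ordering). Small array spaces are enumerated
## exhaustively; larger ones are sampled by random pairing of the gene
## vector, which draws arrays from exactly this conditional law.

.genoTable <- function(calls) {
  a <- pmin(calls[, 1L], calls[, 2L])
  b <- pmax(calls[, 1L], calls[, 2L])
  keep <- !is.na(a)
  a <- a[keep]; b <- b[keep]
  alleles <- sort(unique(c(a, b)))
  k <- length(alleles)
  tab <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_along(a)) {
    ia <- match(a[i], alleles); ib <- match(b[i], alleles)
    tab[ia, ib] <- tab[ia, ib] + 1L
  }
  tab
}

.logArrayProb <- function(tab) {
  n <- sum(tab)
  k <- nrow(tab)
  m <- integer(k)
  for (i in seq_len(k))
    m[i] <- sum(tab[i, ]) + sum(tab[, i])  # diagonal counted twice
  h <- n - sum(diag(tab))
  lfactorial(n) + sum(lfactorial(m)) + h * log(2) -
    lfactorial(2L * n) - sum(lfactorial(tab[upper.tri(tab, diag = TRUE)]))
}

## Exhaustive enumeration of genotype arrays with fixed allele margins.
## Returns matrix of (logprob) per array, or NULL if more than `cap`
## arrays exist.
.enumArrays <- function(m, cap = 1e6) {
  k <- length(m)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  np <- nrow(pairs)
  logs <- numeric(0)
  count <- 0L
  nodes <- 0L
  rec <- function(idx, rem, cur) {
    nodes <<- nodes + 1L
    if (count > cap || nodes > 20L * cap) return(FALSE)
    if (idx > np) {
      if (all(rem == 0L)) {
        count <<- count + 1L
        if (count > cap) return(FALSE)
        tab <- matrix(0L, k, k)
        tab[upper.tri(tab, diag = TRUE)] <- 0L
        for (q in seq_len(np)) tab[pairs[q, 1L], pairs[q, 2L]] <- cur[q]
        logs[count] <<- .logArrayProb(tab)
      }
      return(TRUE)
    }
    i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
    hi <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:hi) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * v
      else { rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v }
      cur[idx] <- v
      if (!rec(idx + 1L, rem2, cur)) return(FALSE)
    }
    TRUE
  }
  ok <- rec(1L, as.integer(m), integer(np))
  if (!ok) return(NULL)
  logs
}

## Random pairing of the gene vector induces the conditional law on
## genotype arrays; per replicate only h and the cell factorials vary.
.mcLogProbs <- function(genes, k, reps) {
  n <- length(genes) %/% 2L
  diagIdx <- (seq_len(k) - 1L) * k + seq_len(k)
  vapply(seq_len(reps), function(r) {
    g <- sample(genes)
    a <- g[seq(1L, length(g), by = 2L)]
    b <- g[seq(2L, length(g), by = 2L)]
    cell <- (pmin(a, b) - 1L) * k + pmax(a, b)
    tab <- tabulate(cell, k * k)
    h <- n - sum(tab[diagIdx])
    h * log(2) - sum(lfactorial(tab))
  }, 1)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test with probability ordering: the p-value is the
#' summed probability, given the observed allele counts, of all genotype
#' arrays no more probable than the observed one. The array space is
#' enumerated exhaustively when it contains at most `enumCap` arrays;
#' otherwise a Monte-Carlo sample of arrays is drawn by random pairing
#' of the gene vector.
#'
#' @param calls two-column matrix of allele calls (one row per
#'   individual, `NA` rows ignored).
#' @param method `"auto"` (enumerate when feasible), `"enumeration"`, or
#'   `"monte_carlo"`.
#' @param reps Monte-Carlo replicates (used only by the MC path).
#' @param seed optional RNG seed for the MC path.
#' @param enumCap maximum number of arrays for full enumeration.
#' @return p-value; exactly 1 for a monomorphic locus.
#' @examples
#' g <- cbind(c(1, 1, 1, 2, 2), c(1, 2, 2, 2, 2))
#' hweExactTest(g)
#' @export
hweExactTest <- function(calls, method = c("auto", "enumeration",
                                           "monte_carlo"),
                         reps = 1e5, seed = NULL, enumCap = 1e6) {
  method <- match.arg(method)
  tab <- .genoTable(calls)
  k <- nrow(tab)
  if (k < 2L) return(1)
  m <- integer(k)
  for (i in seq_len(k)) m[i] <- sum(tab[i, ]) + sum(tab[, i])
  obs <- .logArrayProb(tab)
  tol <- 1e-9
  tryEnum <- method == "enumeration" ||
    (method == "auto" && k <= 3L)  # larger spaces exceed the cap anyway
  if (tryEnum) {
    logs <- .enumArrays(m, cap = enumCap)
    if (!is.null(logs)) {
      probs <- exp(logs - max(logs))
      return(sum(probs[logs <= obs + tol]) / sum(probs))
    }
    if (method == "enumeration")
      stop("array space exceeds enumCap; use monte_carlo", call. = FALSE)
  }
  genes <- rep(seq_len(k), times = m)
  n <- sum(tab)
  obsRel <- obs - (lfactorial(n) + sum(lfactorial(m)) -
                     lfactorial(2L * n))
  .withSeed(seed, {
    lps <- .mcLogProbs(genes, k, reps)
    (sum(lps <= obsRel + tol) + 1L) / (reps + 1L)
  })
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Log-likelihood-ratio G statistic on the genotype x genotype
#' contingency table of two loci, with the null distribution generated
#' by permuting one locus's genotypes across individuals.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param locusA,locusB locus ids or indices.
#' @param pop optional population label to restrict to.
#' @param reps number of permutations.
#' @param seed optional RNG seed.
#' @return p-value, or `NA` (with a warning) when fewer than 5
#'   individuals have both loci typed.
#' @export
ldTest <- function(gm, locusA, locusB, pop = NULL, reps = 1e4,
                   seed = NULL) {
  keep <- if (is.null(pop)) rep(TRUE, nIndividuals(gm)) else gm@pop == pop
  ca <- alleleCalls(gm, locusA)[keep, , drop = FALSE]
  cb <- alleleCalls(gm, locusB)[keep, , drop = FALSE]
  gA <- paste(pmin(ca[, 1], ca[, 2]), pmax(ca[, 1], ca[, 2]))
  gB <- paste(pmin(cb[, 1], cb[, 2]), pmax(cb[, 1], cb[, 2]))
  ok <- !is.na(ca[, 1]) & !is.na(cb[, 1])
  if (sum(ok) < 5L) {
    warning("fewer than 5 complete individuals; LD test undefined")
    return(NA_real_)
  }
  gA <- factor(gA[ok]); gB <- factor(gB[ok])
  gstat <- function(a, b) {
    o <- table(a, b)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    nz <- o > 0
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  obs <- gstat(gA, gB)
  .withSeed(seed, {
    hits <- 0L
    for (r in seq_len(reps))
      if (gstat(gA, sample(gB)) >= obs - 1e-12) hits <- hits + 1L
    (hits + 1L) / (reps + 1L)
  })
}
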