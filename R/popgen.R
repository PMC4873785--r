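## Per-locus population-genetic statistics for codominant diploid data.

## Evaluate expr with a local RNG state seeded by `seed` (NULL = use the
## current stream). All randomized entry points funnel through this.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## allele counts (genes) at one locus from a two-column call matrix
.alleleCounts <- function(calls) {
  v <- c(calls[, 1L], calls[, 2L])
  v <- v[!is.na(v)]
  if (!length(v)) return(integer(0))
  table(v)
}

#' Nei's unbiased expected heterozygosity
#'
#' \eqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)} with allele
#' frequencies estimated from the `2n` genes of `n` complete genotypes.
#'
#' @param counts table or named vector of allele counts (genes).
#' @return unbiased expected heterozygosity in `[0, 1]`.
#' @export
expectedHet <- function(counts) {
  counts <- as.numeric(counts)
  ngenes <- sum(counts)
  if (ngenes < 2) return(NA_real_)
  p <- counts / ngenes
  (ngenes / (ngenes - 1)) * (1 - sum(p^2))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `g`
#' genes: \eqn{A_R = \sum_a \left[1 - \binom{2n - c_a}{g} /
#' \binom{2n}{g}\right]} where \eqn{c_a} is the count of allele `a`
#' among the `2n` sampled genes.
#'
#' @param counts table or named vector of allele counts (genes).
#' @param g standardized gene count, `g <= sum(counts)`.
#' @return rarefied allele count.
#' @examples
#' allelicRichness(c(6, 4), g = 2)   # 1.5333
#' allelicRichness(c(6, 4), g = 10)  # 2 (no rarefaction)
#' @export
allelicRichness <- function(counts, g) {
  counts <- as.numeric(counts)
  ngenes <- sum(counts)
  if (g > ngenes) stop("g exceeds the number of sampled genes",
                       call. = FALSE)
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  miss <- ifelse(ngenes - counts < g, 0,
                 exp(lchoose(ngenes - counts, g) - lchoose(ngenes, g)))
  sum(1 - miss)
}

#' Per-population summary of one locus
#'
#' @param gm a [GenotypeMatrix-class].
#' @param locus locus id or index.
#' @return data.frame with one row per population: `n` (complete
#'   genotypes), `na` (alleles), `ho`, `he`.
#' @export
locusSummary <- function(gm, locus) {
  calls <- alleleCalls(gm, locus)
  pops <- levels(gm@pop)
  rows <- lapply(pops, function(p) {
    cp <- calls[gm@pop == p, , drop = FALSE]
    cp <- cp[!is.na(cp[, 1L]), , drop = FALSE]
    n <- nrow(cp)
    if (n == 0L)
      return(data.frame(pop = p, n = 0L, na = NA_integer_,
                        ho = NA_real_, he = NA_real_))
    cnt <- .alleleCounts(cp)
    data.frame(pop = p, n = n, na = length(cnt),
               ho = mean(cp[, 1L] != cp[, 2L]),
               he = if (length(cnt) == 1L) 0 else expectedHet(cnt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm sequential Bonferroni correction
#'
#' Step-down multiple-testing flags: sort p-values ascending and declare
#' \eqn{p_{(i)}} significant iff \eqn{p_{(j)} \le \alpha/(m-j+1)} for
#' all \eqn{j \le i}.
#'
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector of significance flags, in input order.
#' @examples
#' sequentialBonferroni(c(0.001, 0.03, 0.04))  # TRUE FALSE FALSE
#' @export
sequentialBonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "holm") <= alpha
}

#' Full per-locus evaluation of a genotype matrix
#'
#' For every locus and population: sample size, allele count, observed
#' and unbiased expected heterozygosity, allelic richness rarefied to
#' the smallest per-population gene count at that locus, the exact HWE
#' p-value and its Holm-corrected significance flag (family = all
#' locus x population pairs), and the null-allele frequency estimated by
#' EM. Per-locus Weir-Cockerham \eqn{\theta} (FST) and \eqn{f} (FIS)
#' are attached from [wcFstats()].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param alpha family-wise error rate for the HWE flags.
#' @param hweReps Monte-Carlo replicates for large HWE arrays.
#' @param seed seed for the Monte-Carlo HWE fallback.
#' @return list with elements `perPop` (locus x population data.frame)
#'   and `perLocus` (locus-level data.frame with theta and fis).
#' @export
summarizeLoci <- function(gm, alpha = 0.05, hweReps = 1e5, seed = NULL) {
  loci <- lociNames(gm)
  pops <- levels(gm@pop)
  perPop <- vector("list", 0L)
  for (loc in loci) {
    base <- locusSummary(gm, loc)
    gmin <- 2L * min(base$n[base$n > 0L])
    calls <- alleleCalls(gm, loc)
    for (ri in seq_len(nrow(base))) {
      p <- base$pop[ri]
      cp <- calls[gm@pop == p, , drop = FALSE]
      cpc <- cp[!is.na(cp[, 1L]), , drop = FALSE]
      ar <- hwp <- nullf <- NA_real_
      if (nrow(cpc) > 0L) {
        cnt <- .alleleCounts(cpc)
        ar <- allelicRichness(cnt, g = gmin)
        hwp <- hweExactTest(cpc, reps = hweReps, seed = seed)
        nullf <- if (length(cnt) >= 2L)
          tryCatch(nullAlleleEM(cp)$r, error = function(e) NA_real_)
        else NA_real_
      }
      perPop[[length(perPop) + 1L]] <- cbind(
        data.frame(locus = loc), base[ri, , drop = FALSE],
        data.frame(ar = ar, null_freq = nullf, hwe_p = hwp))
    }
  }
  perPop <- do.call(rbind, perPop)
  rownames(perPop) <- NULL
  perPop$hwe_significant <- NA
  ok <- !is.na(perPop$hwe_p)
  perPop$hwe_significant[ok] <-
    sequentialBonferroni(perPop$hwe_p[ok], alpha)
  fs <- wcFstats(gm)
  list(perPop = perPop, perLocus = fs$perLocus,
       theta = fs$theta, fis = fs$fis)
}
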