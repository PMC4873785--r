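## Weir & Cockerham (1984) variance-component estimators of F-statistics.

## Per-locus variance components summed over alleles. Populations with
## no data at the locus are dropped; needs >= 2 populated samples.
.wcComponents <- function(calls, pop) {
  pops <- levels(pop)
  byPop <- lapply(pops, function(p) {
    cp <- calls[pop == p, , drop = FALSE]
    cp[!is.na(cp[, 1L]), , drop = FALSE]
  })
  nvec <- vapply(byPop, nrow, 1L)
  use <- nvec > 0L
  if (sum(use) < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  byPop <- byPop[use]; nvec <- nvec[use]
  r <- length(nvec)
  alleles <- sort(unique(unlist(lapply(byPop, function(cp)
    c(cp[, 1L], cp[, 2L])))))
  nbar <- mean(nvec)
  nsum <- sum(nvec)
  nc <- (nsum - sum(nvec^2) / nsum) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- vapply(byPop, function(cp)
      mean(c(cp[, 1L], cp[, 2L]) == al), 1)
    h_i <- vapply(byPop, function(cp)
      mean((cp[, 1L] == al) != (cp[, 2L] == al)), 1)
    pbar <- sum(nvec * p_i) / nsum
    s2 <- sum(nvec * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nvec * h_i) / nsum
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
         (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Weir-Cockerham F-statistics
#'
#' Variance-component estimators \eqn{\theta} (FST) and \eqn{f} (FIS),
#' per locus and multi-locus (ratios of summed components).
#'
#' @param gm a [GenotypeMatrix-class] with at least two populations.
#' @param loci optional subset of locus ids; default all.
#' @return list with `perLocus` (data.frame: locus, a, b, c, theta,
#'   fis), and multi-locus `theta`, `fis`, `fit`.
#' @export
wcFstats <- function(gm, loci = NULL) {
  if (nlevels(droplevels(gm@pop)) < 2L)
    stop("at least two populations required for F-statistics",
         call. = FALSE)
  if (is.null(loci)) loci <- lociNames(gm)
  comp <- t(vapply(loci, function(loc)
    .wcComponents(alleleCalls(gm, loc), gm@pop), numeric(3L)))
  perLocus <- data.frame(
    locus = loci,
    a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
    theta = comp[, "a"] / (comp[, "a"] + comp[, "b"] + comp[, "c"]),
    fis = 1 - comp[, "c"] / (comp[, "b"] + comp[, "c"]),
    row.names = NULL
  )
  ok <- stats::complete.cases(comp)
  sa <- sum(comp[ok, "a"]); sb <- sum(comp[ok, "b"])
  sc <- sum(comp[ok, "c"])
  list(perLocus = perLocus,
       theta = sa / (sa + sb + sc),
       fis = 1 - sc / (sb + sc),
       fit = 1 - sc / (sa + sb + sc))
}
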