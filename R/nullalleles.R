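## EM estimation of the null-allele frequency at one locus.
##
## Model: a non-amplifying (null) allele of frequency r segregates with
## the visible alleles under Hardy-Weinberg proportions. A visible
## homozygote i/i is observed with probability p_i^2 + 2 p_i r (true
## homozygote or i/null heterozygote); a visible heterozygote i/j with
## 2 p_i p_j; an individual missing at the locus is attributed to the
## null/null genotype (probability r^2).

#' Null-allele frequency by EM
#'
#' @param calls two-column matrix of allele calls at one locus; rows
#'   with `NA` are treated as whole-genotype amplification failures
#'   (null homozygotes) when `includeMissing = TRUE`.
#' @param includeMissing attribute missing genotypes to the null/null
#'   class (default TRUE).
#' @param tol convergence tolerance on the change in `r`.
#' @param maxIter maximum EM iterations; non-convergence is an error
#'   carrying the last iterate in its `data` field.
#' @return list with `p` (named visible-allele frequencies), `r` (null
#'   frequency), `iterations`, and `loglik` (the observed-data
#'   log-likelihood trace, non-decreasing by construction of EM).
#' @examples
#' g <- cbind(rep(c(1, 1, 2), 20), rep(c(1, 2, 2), 20))
#' nullAlleleEM(g)$r  # ~0: data at HW proportions
#' @export
nullAlleleEM <- function(calls, includeMissing = TRUE, tol = 1e-6,
                         maxIter = 1e4) {
  obs <- calls[!is.na(calls[, 1L]), , drop = FALSE]
  nMiss <- if (includeMissing) sum(is.na(calls[, 1L])) else 0L
  if (nrow(obs) == 0L) stop("no observed genotypes", call. = FALSE)
  alleles <- sort(unique(c(obs[, 1L], obs[, 2L])))
  k <- length(alleles)
  if (k < 2L) stop("need >= 2 visible alleles for EM", call. = FALSE)
  ia <- match(obs[, 1L], alleles); ib <- match(obs[, 2L], alleles)
  het <- ia != ib
  nTot <- nrow(obs) + nMiss
  cnt <- tabulate(c(ia, ib), k)
  r <- max(0.05, nMiss / nTot)
  p <- cnt / sum(cnt) * (1 - r)
  ll <- numeric(0)
  for (it in seq_len(maxIter)) {
    # E-step: expected gene counts
    gc <- numeric(k); gnull <- 2 * nMiss
    if (any(het)) {
      th <- tabulate(c(ia[het], ib[het]), k)
      gc <- gc + th
    }
    hom <- which(!het)
    if (length(hom)) {
      i <- ia[hom]
      w <- p[i]^2 / (p[i]^2 + 2 * p[i] * r)  # P(true homozygote)
      for (u in seq_along(hom)) {
        gc[i[u]] <- gc[i[u]] + 2 * w[u] + (1 - w[u])
        gnull <- gnull + (1 - w[u])
      }
    }
    rNew <- gnull / (2 * nTot)
    pNew <- gc / (2 * nTot)
    llv <- sum(log(2 * pNew[ia[het]] * pNew[ib[het]])) +
      sum(log(pNew[ia[hom]]^2 + 2 * pNew[ia[hom]] * rNew)) +
      nMiss * ifelse(rNew > 0, 2 * log(rNew), -Inf)
    ll <- c(ll, llv)
    done <- abs(rNew - r) < tol
    r <- rNew; p <- pNew
    if (done)
      return(list(p = setNames(p, alleles), r = r, iterations = it,
                  loglik = ll))
  }
  cond <- simpleError("null-allele EM did not converge")
  cond$data <- list(p = setNames(p, alleles), r = r,
                    iterations = maxIter, loglik = ll)
  stop(cond)
}
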