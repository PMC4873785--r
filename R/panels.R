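## Marker panel construction and comparison.

#' Detect single-nucleotide-insertion (SNI) alleles at a locus
#'
#' A locus carries an SNI when its allele sizes are not all congruent
#' modulo the motif length, i.e. at least one allele sits off the
#' motif-length ladder (e.g. a +1 bp allele at a tetranucleotide locus).
#'
#' @param alleleSizes numeric vector of distinct (or repeated) allele
#'   sizes in bp; `NA` ignored.
#' @param motifLength motif length in bp (>= 2).
#' @return TRUE when an off-ladder allele is present.
#' @examples
#' detectSNI(c(240, 244, 248), 4)  # FALSE
#' detectSNI(c(240, 244, 249), 4)  # TRUE
#' @export
detectSNI <- function(alleleSizes, motifLength) {
  if (motifLength < 2L)
    stop("SNI detection needs motifLength >= 2", call. = FALSE)
  s <- unique(alleleSizes[!is.na(alleleSizes)])
  if (length(s) < 2L)
    stop("need >= 2 alleles to assess SNI", call. = FALSE)
  length(unique(s %% motifLength)) > 1L
}

#' Per-locus marker profiles from a genotype matrix
#'
#' Derives the per-locus attributes that drive panel construction:
#' allele number, genotyping completeness, SNI status, and
#' Holm-corrected HWE deviance per population (with the count of
#' deviant populations).
#'
#' @param gm a [GenotypeMatrix-class] whose `loci` table carries motif
#'   lengths.
#' @param alpha family-wise error rate for HWE flags.
#' @param ambiguousPeaks optional character vector of locus ids flagged
#'   as having ambiguous electropherogram peaks (genotyping metadata;
#'   cannot be computed from allele calls).
#' @param seed seed for any Monte-Carlo HWE test.
#' @return data.frame with columns `locus`, `motif_length`, `n_alleles`,
#'   `n_genotyped`, `amplified_in_all`, `sni`, `hwe_deviant_pops`,
#'   `hwe_deviant_all_pops`, `ambiguous_peaks`.
#' @export
markerProfiles <- function(gm, alpha = 0.05, ambiguousPeaks = character(),
                           seed = NULL) {
  loci <- lociNames(gm)
  info <- lociInfo(gm)
  summ <- summarizeLoci(gm, alpha = alpha, seed = seed)
  pp <- summ$perPop
  rows <- lapply(loci, function(loc) {
    calls <- alleleCalls(gm, loc)
    sizes <- unique(c(calls[, 1L], calls[, 2L]))
    ml <- info$motif_length[match(loc, info$locus)]
    sub <- pp[pp$locus == loc, , drop = FALSE]
    ndev <- sum(sub$hwe_significant, na.rm = TRUE)
    npops <- sum(!is.na(sub$hwe_significant))
    data.frame(
      locus = loc, motif_length = ml,
      n_alleles = length(sizes[!is.na(sizes)]),
      n_genotyped = sum(!is.na(calls[, 1L])),
      amplified_in_all = !anyNA(calls[, 1L]),
      sni = if (!is.na(ml) && ml >= 2L &&
                length(unique(sizes[!is.na(sizes)])) >= 2L)
        detectSNI(sizes, ml) else NA,
      hwe_deviant_pops = ndev,
      hwe_deviant_all_pops = npops > 0L && ndev == npops,
      ambiguous_peaks = loc %in% ambiguousPeaks
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the MP / SNI / SS / ALL marker panels
#'
#' Panel rules: SNI collects every locus flagged for
#' single-nucleotide-insertion alleles; MP takes the top `k` non-SNI
#' loci ranked by allele number, including all loci tied at the cut;
#' SS keeps loci that amplified in every individual, show no SNI, have
#' unambiguous peaks, and do not deviate from Hardy-Weinberg
#' equilibrium (by default: deviant in every surveyed population
#' excludes, `hweExclude = "all"`; set `"any"` to exclude on a single
#' deviant population); ALL contains every profiled locus. Every
#' inclusion or exclusion is recorded with its rule.
#'
#' @param profiles data.frame of per-locus profiles, e.g. from
#'   [markerProfiles()] or [wftMarkerLoci()]: columns `locus`,
#'   `n_alleles`, `sni`, `amplified_in_all`, `ambiguous_peaks`, and
#'   `hwe_deviant_all_pops` (or `hwe_deviant_pops` when
#'   `hweExclude = "any"`).
#' @param k target MP panel size (default 8).
#' @param hweExclude `"all"` or `"any"`: whether a locus is barred from
#'   SS when HWE-deviant in all populations or in at least one.
#' @return a [PanelSet-class].
#' @examples
#' buildPanels(wftMarkerLoci())
#' @export
buildPanels <- function(profiles, k = 8L, hweExclude = c("all", "any")) {
  hweExclude <- match.arg(hweExclude)
  stopifnot(all(c("locus", "n_alleles", "sni", "amplified_in_all",
                  "ambiguous_peaks") %in% names(profiles)))
  pr <- profiles
  dec <- list()
  note <- function(locus, panel, included, rule)
    dec[[length(dec) + 1L]] <<- data.frame(
      locus = locus, panel = panel, included = included, rule = rule)

  sni <- pr$locus[isTRUE_v(pr$sni)]
  for (l in pr$locus)
    note(l, "SNI", l %in% sni,
         if (l %in% sni) "SNI_ALLELES_PRESENT" else "NO_SNI_ALLELES")

  nonSni <- pr[!isTRUE_v(pr$sni), , drop = FALSE]
  nonSni <- nonSni[order(-nonSni$n_alleles, nonSni$locus), ,
                   drop = FALSE]
  if (nrow(nonSni) > k) {
    cut <- nonSni$n_alleles[k]
    mp <- nonSni$locus[nonSni$n_alleles >= cut]
  } else mp <- nonSni$locus
  for (l in pr$locus) {
    if (l %in% sni) note(l, "MP", FALSE, "EXCLUDED_SNI")
    else note(l, "MP", l %in% mp,
              if (l %in% mp) "TOP_NA_RANK" else "BELOW_NA_CUT")
  }

  hweBar <- if (hweExclude == "all") isTRUE_v(pr$hwe_deviant_all_pops)
            else pr$hwe_deviant_pops > 0L
  ss <- character()
  for (i in seq_len(nrow(pr))) {
    l <- pr$locus[i]
    fails <- c(
      if (!isTRUE(pr$amplified_in_all[i])) "NOT_FULLY_AMPLIFIED",
      if (isTRUE_v(pr$sni)[i]) "SNI_ALLELES_PRESENT",
      if (hweBar[i]) "HWE_DEVIANT",
      if (isTRUE(pr$ambiguous_peaks[i])) "AMBIGUOUS_PEAKS"
    )
    if (is.null(fails)) {
      ss <- c(ss, l)
      note(l, "SS", TRUE, "ALL_CRITERIA_MET")
    } else note(l, "SS", FALSE, paste(fails, collapse = "+"))
  }

  for (l in pr$locus) note(l, "ALL", TRUE, "DEVELOPED_MARKER")

  new("PanelSet",
      panels = list(MP = mp, SNI = sni, SS = ss, ALL = pr$locus),
      decisions = do.call(rbind, dec))
}

## vectorized isTRUE: NA -> FALSE
isTRUE_v <- function(x) !is.na(x) & x

#' Leave-one-out likelihood assignment of individuals
#'
#' For each individual, per-population allele frequencies at the panel
#' loci are recomputed excluding that individual; zero frequencies are
#' smoothed to 1/(2n+1). The multilocus genotype log-likelihood under
#' Hardy-Weinberg proportions is computed per population and normalized
#' into membership probabilities Q. An individual is correctly assigned
#' when the highest-Q population matches its true label and Q reaches
#' `qThreshold`.
#'
#' @param gm a [GenotypeMatrix-class] with >= 2 populations.
#' @param panel character vector of panel locus ids.
#' @param qThreshold posterior membership threshold (default 0.60).
#' @return data.frame: one row per individual with `id`, `pop`, one `Q_`
#'   column per population, `assigned`, `correct`; individuals with no
#'   typed panel locus get `NA` and `correct = NA`.
#' @export
assignIndividuals <- function(gm, panel, qThreshold = 0.60) {
  stopifnot(length(panel) >= 1L, nlevels(droplevels(gm@pop)) >= 2L)
  pops <- levels(gm@pop)
  nInd <- nIndividuals(gm)
  Q <- matrix(NA_real_, nInd, length(pops),
              dimnames = list(rownames(gm@alleleA), pops))
  for (ind in seq_len(nInd)) {
    loglik <- setNames(numeric(length(pops)), pops)
    informative <- FALSE
    for (loc in panel) {
      calls <- alleleCalls(gm, loc)
      a <- calls[ind, 1L]; b <- calls[ind, 2L]
      if (is.na(a)) next
      informative <- TRUE
      for (p in pops) {
        sel <- which(gm@pop == p)
        sel <- sel[sel != ind]
        cp <- calls[sel, , drop = FALSE]
        cp <- cp[!is.na(cp[, 1L]), , drop = FALSE]
        genes <- c(cp[, 1L], cp[, 2L])
        n2 <- length(genes)
        freq <- function(al) {
          if (n2 == 0L) return(1 / (n2 + 1))
          f <- sum(genes == al) / n2
          if (f == 0) 1 / (n2 + 1) else f
        }
        loglik[p] <- loglik[p] +
          if (a == b) 2 * log(freq(a))
          else log(2) + log(freq(a)) + log(freq(b))
      }
    }
    if (informative) {
      w <- exp(loglik - max(loglik))
      Q[ind, ] <- w / sum(w)
    }
  }
  assigned <- pops[max.col(ifelse(is.na(Q), -Inf, Q), "first")]
  assigned[!stats::complete.cases(Q)] <- NA_character_
  qmax <- apply(Q, 1L, function(x) if (anyNA(x)) NA_real_ else max(x))
  out <- data.frame(id = rownames(gm@alleleA),
                    pop = as.character(gm@pop), Q,
                    assigned = assigned,
                    correct = assigned == as.character(gm@pop) &
                      qmax >= qThreshold,
                    row.names = NULL, check.names = FALSE)
  names(out)[2L + seq_along(pops)] <- paste0("Q_", pops)
  out
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact by complete enumeration of all rank splits when
#' `m + n <= exactMax` (ties handled exactly); exact via
#' [stats::wilcox.test()] for tie-free samples when both sizes are at
#' most 12; the normal approximation with tie and continuity
#' correction otherwise. `W` is the Mann-Whitney U statistic of `x`
#' versus `y` (number of (x, y) pairs with x > y, ties counting 1/2).
#' The exact two-sided p-value is `min(1, 2 * min(P(U <= w),
#' P(U >= w)))`.
#'
#' @param x,y numeric samples.
#' @param exactMax largest combined size for full enumeration.
#' @return list with `W` and `p.value`.
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))  # W = 0, p = 0.1
#' @export
mannWhitneyTest <- function(x, y, exactMax = 14L) {
  m <- length(x); n <- length(y)
  stopifnot(m >= 1L, n >= 1L)
  uStat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  W <- uStat(x, y)
  if (m + n <= exactMax) {
    comb <- c(x, y)
    splits <- combn(m + n, m)
    us <- apply(splits, 2L, function(ix) uStat(comb[ix], comb[-ix]))
    pv <- min(1, 2 * min(mean(us <= W + 1e-9), mean(us >= W - 1e-9)))
    return(list(W = W, p.value = pv))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  wt <- suppressWarnings(wilcox.test(x, y,
                                     exact = !ties && m <= 12L &&
                                       n <= 12L,
                                     correct = TRUE))
  list(W = unname(wt$statistic), p.value = wt$p.value)
}

#' PCA of individuals on allele-indicator counts
#'
#' Builds the individuals x alleles count matrix (0/1/2 copies per
#' allele across the panel loci), fills missing genotypes with locus
#' means, and performs centered covariance PCA. The sign of each
#' component is fixed by forcing its largest-magnitude loading positive.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param panel character vector of locus ids.
#' @param nComp number of components returned.
#' @return list with `scores` (individuals x components), `sdev`, and
#'   `varExplained`.
#' @export
panelPCA <- function(gm, panel, nComp = 2L) {
  cols <- list()
  for (loc in panel) {
    calls <- alleleCalls(gm, loc)
    alleles <- sort(unique(c(calls[, 1L], calls[, 2L])))
    alleles <- alleles[!is.na(alleles)]
    for (al in alleles) {
      v <- (calls[, 1L] == al) + (calls[, 2L] == al)
      cols[[paste(loc, al, sep = ".")]] <- v
    }
  }
  X <- do.call(cbind, cols)
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mj
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  nComp <- min(nComp, ncol(pc$rotation))
  for (j in seq_len(nComp)) {
    lj <- pc$rotation[, j]
    if (lj[which.max(abs(lj))] < 0) {
      pc$rotation[, j] <- -lj
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x[, seq_len(nComp), drop = FALSE],
       sdev = pc$sdev,
       varExplained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Compare marker panels
#'
#' Per panel and population: mean allelic richness and mean unbiased
#' expected heterozygosity over the panel loci, multi-locus
#' Weir-Cockerham FIS and pairwise FST; for every panel pair and
#' statistic, the two-sided Mann-Whitney test on the per-locus values;
#' per-panel leave-one-out assignment summaries and PCA coordinates.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param panels a [PanelSet-class].
#' @param qThreshold assignment membership threshold.
#' @return list with `diversity` (panel x population means),
#'   `fst` (per panel), `tests` (panel pair x statistic W and p),
#'   `assignment` (per panel: rate and per-individual table), `pca`
#'   (per panel scores).
#' @export
comparePanels <- function(gm, panels, qThreshold = 0.60) {
  panelNames <- c("MP", "SNI", "SS", "ALL")
  pops <- levels(gm@pop)
  perLocusStats <- function(panel) {
    do.call(rbind, lapply(panel, function(loc) {
      ls <- locusSummary(gm, loc)
      gmin <- 2L * min(ls$n[ls$n > 0L])
      ls$ar <- vapply(seq_len(nrow(ls)), function(i) {
        if (ls$n[i] == 0L) return(NA_real_)
        cp <- alleleCalls(gm, loc)[gm@pop == ls$pop[i], , drop = FALSE]
        cp <- cp[!is.na(cp[, 1L]), , drop = FALSE]
        allelicRichness(.alleleCounts(cp), g = gmin)
      }, 1)
      cbind(locus = loc, ls)
    }))
  }
  statsByPanel <- lapply(setNames(panelNames, panelNames), function(p) {
    members <- panels@panels[[p]]
    if (!length(members)) return(NULL)
    perLocusStats(members)
  })
  diversity <- do.call(rbind, lapply(panelNames, function(p) {
    st <- statsByPanel[[p]]
    if (is.null(st)) return(NULL)
    do.call(rbind, lapply(pops, function(pp) {
      sub <- st[st$pop == pp, , drop = FALSE]
      fs <- tryCatch(wcFstats(gm, loci = panels@panels[[p]]),
                     error = function(e) list(fis = NA_real_))
      data.frame(panel = p, pop = pp,
                 mean_ar = mean(sub$ar, na.rm = TRUE),
                 mean_he = mean(sub$he, na.rm = TRUE),
                 fis = fs$fis)
    }))
  }))
  fst <- vapply(panelNames, function(p) {
    if (!length(panels@panels[[p]])) return(NA_real_)
    tryCatch(wcFstats(gm, loci = panels@panels[[p]])$theta,
             error = function(e) NA_real_)
  }, 1)
  pairs <- combn(panelNames, 2L)
  tests <- list()
  for (q in seq_len(ncol(pairs))) {
    p1 <- pairs[1L, q]; p2 <- pairs[2L, q]
    s1 <- statsByPanel[[p1]]; s2 <- statsByPanel[[p2]]
    if (is.null(s1) || is.null(s2)) next
    for (pp in pops) for (stat in c("ar", "he")) {
      x <- s1[s1$pop == pp, stat]; y <- s2[s2$pop == pp, stat]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      mw <- mannWhitneyTest(x, y)
      tests[[length(tests) + 1L]] <- data.frame(
        panel1 = p1, panel2 = p2, pop = pp, statistic = stat,
        W = mw$W, p = mw$p.value)
    }
  }
  assignment <- lapply(setNames(panelNames, panelNames), function(p) {
    members <- panels@panels[[p]]
    if (!length(members)) return(NULL)
    tab <- assignIndividuals(gm, members, qThreshold = qThreshold)
    list(rate = mean(tab$correct, na.rm = TRUE), table = tab)
  })
  pca <- lapply(setNames(panelNames, panelNames), function(p) {
    members <- panels@panels[[p]]
    if (!length(members)) return(NULL)
    panelPCA(gm, members)
  })
  list(diversity = diversity, fst = fst,
       tests = do.call(rbind, tests),
       assignment = assignment, pca = pca)
}
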