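## Synthetic inputs with ground truth: genomes with planted SSRs and
## two-population diploid genotype datasets under the Balding-Nichols
## differentiation model.

.randomBackground <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

## Build the repeat sequence for one planted locus description:
## list(motif=, units=, mismatches= bp offsets within the repeat).
.buildRepeat <- function(motif, units, mismatches = integer()) {
  chars <- strsplit(toupper(motif), "")[[1]]
  k <- length(chars)
  rep_ <- rep(chars, units)
  guard <- max(2L * k, 8L)
  if (length(mismatches)) {
    mm <- sort(as.integer(mismatches))
    if (any(mm <= guard) || any(mm > length(rep_) - guard))
      stop("mismatch positions must be > ", guard,
           " bp from either end of the repeat", call. = FALSE)
    if (length(mm) > 1L && any(diff(mm) < guard))
      stop("mismatch positions must be >= ", guard, " bp apart",
           call. = FALSE)
    for (pos in mm) {
      alt <- setdiff(c("A", "C", "G", "T"), rep_[pos])
      rep_[pos] <- sample(alt, 1L)
    }
  }
  rep_
}

#' Simulate a genome with planted microsatellites
#'
#' Generates random-background scaffolds with planted perfect or
#' imperfect SSRs of known motif, length and mismatch count, spaced at
#' least `spacing` bp apart. Junction bases are chosen to break the
#' repeat periodicity so planted coordinates are exact, and the
#' background is rejection-sampled until the scanner finds nothing but
#' the planted loci at the given parameters.
#'
#' @param plantedLoci list of loci, each a list with `motif`, `units`,
#'   and optional `mismatches` (bp offsets within the repeat, interior
#'   and spaced; see Details in the vignette). Assigned to scaffolds
#'   round-robin.
#' @param nScaffolds number of scaffolds.
#' @param scaffoldLength scaffold length in bp.
#' @param gcContent background GC fraction.
#' @param spacing minimum distance between planted loci, bp.
#' @param params scan parameters used for background screening.
#' @param seed RNG seed (deterministic output under a fixed seed).
#' @param maxTries background rejection-sampling attempts.
#' @return list with `genome` (named character vector) and `truth`
#'   (data.frame of planted records: sequence_id, start, end, motif,
#'   length, mismatches, score, perfect).
#' @examples
#' sim <- simulateGenome(list(list(motif = "AGC", units = 8)),
#'                       scaffoldLength = 2000, seed = 1)
#' scanGenome(sim$genome)
#' @export
simulateGenome <- function(plantedLoci = list(),
                           nScaffolds = 1L, scaffoldLength = 10000L,
                           gcContent = 0.4, spacing = 50L,
                           params = scanParams(), seed = NULL,
                           maxTries = 100L) {
  nScaffolds <- as.integer(nScaffolds)
  scaffoldLength <- as.integer(scaffoldLength)
  spacing <- as.integer(spacing)
  .withSeed(seed, {
    assign_ <- rep(seq_len(nScaffolds), length.out = length(plantedLoci))
    reps <- lapply(plantedLoci, function(pl)
      .buildRepeat(pl$motif, pl$units,
                   if (is.null(pl$mismatches)) integer()
                   else pl$mismatches))
    genome <- character(nScaffolds)
    names(genome) <- sprintf("scaffold%02d", seq_len(nScaffolds))
    truthRows <- list()
    for (sc in seq_len(nScaffolds)) {
      mine <- which(assign_ == sc)
      lens <- vapply(reps[mine], length, 1L)
      need <- sum(lens) + (length(mine) + 1L) * spacing
      if (need > scaffoldLength)
        stop("planted loci do not fit in scaffold of ",
             scaffoldLength, " bp (need >= ", need, ")", call. = FALSE)
      free <- scaffoldLength - sum(lens)
      gap <- free %/% (length(mine) + 1L)
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        chars <- .randomBackground(scaffoldLength, gcContent)
        pos <- integer(length(mine))
        cursor <- gap + 1L
        for (u in seq_along(mine)) {
          pos[u] <- cursor
          seg <- reps[[mine[u]]]
          k <- nchar(plantedLoci[[mine[u]]]$motif)
          chars[cursor:(cursor + length(seg) - 1L)] <- seg
          # break periodicity at the junctions
          if (cursor > 1L) {
            bad <- chars[cursor + k - 1L]
            chars[cursor - 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 bad), 1L)
          }
          e <- cursor + length(seg) - 1L
          if (e < scaffoldLength) {
            bad <- chars[e - k + 1L]
            chars[e + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                            bad), 1L)
          }
          cursor <- e + gap + 1L
        }
        cand <- paste(chars, collapse = "")
        found <- scanSequence(cand, id = names(genome)[sc],
                              params = params)
        planted <- data.frame(
          start = pos,
          end = pos + vapply(reps[mine], length, 1L) - 1L)
        extraneous <- nrow(found) > 0L &&
          any(!vapply(seq_len(nrow(found)), function(i)
            any(found$start[i] <= planted$end &
                  found$end[i] >= planted$start), NA))
        if (!extraneous) {
          genome[sc] <- cand
          for (u in seq_along(mine)) {
            pl <- plantedLoci[[mine[u]]]
            nmm <- if (is.null(pl$mismatches)) 0L
                   else length(pl$mismatches)
            len <- length(reps[[mine[u]]])
            truthRows[[length(truthRows) + 1L]] <- data.frame(
              sequence_id = names(genome)[sc],
              start = pos[u], end = pos[u] + len - 1L,
              motif = canonicalMotif(pl$motif), length = len,
              mismatches = nmm,
              score = scoreRun(len, nmm, params),
              perfect = nmm == 0L)
          }
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not generate SSR-free background in ", maxTries,
             " tries", call. = FALSE)
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
             else .emptyScan()
    list(genome = genome, truth = truth)
  })
}

.rdirichlet1 <- function(n) {
  g <- rgamma(n, shape = 1)
  g / sum(g)
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate two-population diploid microsatellite genotypes
#'
#' Per locus: ancestral allele frequencies are drawn Dirichlet(1, ..,
#' 1) over `nAlleles` sizes on the motif-length ladder starting at
#' `ladderOffset`; population frequencies follow the Balding-Nichols
#' model with differentiation parameter `targetFst`; diploid genotypes
#' are drawn under Hardy-Weinberg proportions. A null allele of
#' frequency `nullRate` hides single copies (apparent homozygotes) or
#' whole genotypes (null homozygotes appear missing); loci listed in
#' `sniLoci` carry an off-ladder +1 bp allele at frequency `sniFreq`;
#' `missingRate` further masks random genotypes after the null-allele
#' logic.
#'
#' @param nPerPop individuals per population (length-2 integer).
#' @param nLoci number of loci.
#' @param targetFst Balding-Nichols differentiation parameter.
#' @param alleleRange range of allele counts per locus.
#' @param motifLengths candidate motif lengths per locus (sampled).
#' @param ladderOffset smallest allele size, bp.
#' @param nullRate per-locus null-allele frequency (scalar or vector).
#' @param sniLoci indices of loci carrying an off-ladder allele.
#' @param sniFreq frequency of the off-ladder allele.
#' @param missingRate random missing-genotype rate.
#' @param popNames population labels.
#' @param seed RNG seed.
#' @return list with `gm` (a [GenotypeMatrix-class]) and `truth`
#'   (list: per-locus ancestral and per-population frequencies, motif
#'   lengths, realized null/missing/SNI events).
#' @export
simulateGenotypes <- function(nPerPop = c(23L, 24L), nLoci = 30L,
                              targetFst = 0.05,
                              alleleRange = c(4L, 17L),
                              motifLengths = c(3L, 4L),
                              ladderOffset = 150L,
                              nullRate = 0, sniLoci = integer(),
                              sniFreq = 0.1, missingRate = 0.02,
                              popNames = c("MT", "YQ"), seed = NULL) {
  stopifnot(length(nPerPop) == 2L, targetFst >= 0, targetFst < 1,
            all(nullRate >= 0 & nullRate <= 1),
            missingRate >= 0, missingRate <= 1)
  nullRate <- rep(nullRate, length.out = nLoci)
  .withSeed(seed, {
    nInd <- sum(nPerPop)
    pop <- factor(rep(popNames, nPerPop), levels = popNames)
    A <- B <- matrix(NA_integer_, nInd, nLoci)
    lociML <- sample(motifLengths, nLoci, replace = TRUE)
    truthLoci <- vector("list", nLoci)
    nullEvents <- matrix(FALSE, nInd, nLoci)
    missEvents <- matrix(FALSE, nInd, nLoci)
    for (l in seq_len(nLoci)) {
      k <- lociML[l]
      na <- sample(alleleRange[1L]:alleleRange[2L], 1L)
      sizes <- ladderOffset + k * (seq_len(na) - 1L)
      anc <- .rdirichlet1(na)
      labels <- sizes
      freqs <- anc
      if (l %in% sniLoci) {
        labels <- c(labels, sizes[ceiling(na / 2)] + 1L)
        freqs <- c(freqs * (1 - sniFreq), sniFreq)
      }
      r <- nullRate[l]
      if (r > 0) {
        labels <- c(labels, -1L)  # null allele sentinel
        freqs <- c(freqs * (1 - r), r)
      }
      popFreqs <- lapply(seq_len(2L), function(p) {
        if (targetFst == 0) return(freqs)
        .rdirichlet(freqs * (1 - targetFst) / targetFst)
      })
      for (i in seq_len(nInd)) {
        f <- popFreqs[[as.integer(pop[i])]]
        g <- sample(labels, 2L, replace = TRUE, prob = f)
        if (all(g == -1L)) {
          nullEvents[i, l] <- TRUE          # null homozygote: missing
        } else if (any(g == -1L)) {
          vis <- g[g != -1L]
          A[i, l] <- vis; B[i, l] <- vis    # apparent homozygote
          nullEvents[i, l] <- TRUE
        } else {
          A[i, l] <- min(g); B[i, l] <- max(g)
        }
      }
      truthLoci[[l]] <- list(motif_length = k, sizes = labels,
                             ancestral = freqs, popFreqs = popFreqs)
    }
    if (missingRate > 0) {
      mask <- matrix(runif(nInd * nLoci) < missingRate, nInd, nLoci)
      missEvents <- mask & !is.na(A)
      A[mask] <- NA_integer_; B[mask] <- NA_integer_
    }
    lociDf <- data.frame(locus = sprintf("L%02d", seq_len(nLoci)),
                         motif_length = lociML)
    colnames(A) <- colnames(B) <- lociDf$locus
    rownames(A) <- rownames(B) <-
      sprintf("%s_%02d", rep(popNames, nPerPop),
              unlist(lapply(nPerPop, seq_len)))
    gm <- genotypeMatrix(A, B, pop, lociDf)
    list(gm = gm,
         truth = list(loci = truthLoci, pop = pop,
                      motif_lengths = lociML,
                      null_events = nullEvents,
                      missing_events = missEvents,
                      sni_loci = sniLoci, target_fst = targetFst))
  })
}
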