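## Microsatellite scanner: fixed-penalty mismatch scoring.
##
## A locus is an interval [i, j] read against the periodic extension of
## the motif anchored at i (the pattern is the first k bases of the
## interval). Score = length - mismatchPenalty * mismatches; intervals
## must start and end on a matching base, span >= 2 motif units,
## contain a perfect seed stretch (two full units and >= minSeedLength
## bp), contain no N and no interruption longer than
## maxInterruptionRun, and score at least minScore. Overlaps are
## resolved greedily by (score desc, motif length asc, start asc, end
## asc).

VALID_BASES <- c("A", "C", "G", "T")

.checkAlphabet <- function(chars, allowN = TRUE) {
  ok <- chars %in% c(VALID_BASES, if (allowN) "N")
  if (!all(ok))
    stop("invalid character(s) in DNA sequence: ",
         paste(unique(chars[!ok]), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

.revcompChars <- function(chars) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A")[chars]))
}

#' Primitive period of a motif
#'
#' Smallest `d` dividing `nchar(motif)` such that the motif is a tandem
#' repetition of its first `d` bases ("AGAG" has primitive period 2).
#'
#' @param motif DNA string (ACGT).
#' @return integer period length.
#' @export
primitivePeriod <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  k <- length(chars)
  for (d in seq_len(k)) {
    if (k %% d != 0L) next
    if (all(chars == chars[((seq_len(k) - 1L) %% d) + 1L])) return(d)
  }
  k
}

#' Canonical representative of a motif class
#'
#' Motifs are grouped into equivalence classes under cyclic rotation and
#' reverse complementation, so that e.g. "GA", "CT" and "TC" all name the
#' same dinucleotide class as "AG". The input is first reduced to its
#' primitive period; the class representative is the lexicographically
#' smallest string among all rotations of the motif and of its reverse
#' complement.
#'
#' @param motif DNA string over ACGT (case-insensitive), 1-6 bp typical
#'   but any length is accepted.
#' @return canonical motif string.
#' @examples
#' canonicalMotif("GA")     # "AG"
#' canonicalMotif("GGGGC")  # "CCCCG"
#' canonicalMotif("AGAG")   # "AG" (primitive period reduction first)
#' @export
canonicalMotif <- function(motif) {
  if (length(motif) != 1L || is.na(motif) || nchar(motif) == 0L)
    stop("motif must be a single non-empty string", call. = FALSE)
  chars <- strsplit(toupper(motif), "")[[1]]
  .checkAlphabet(chars, allowN = FALSE)
  k <- primitivePeriod(paste(chars, collapse = ""))
  chars <- chars[seq_len(k)]
  rots <- function(x) {
    vapply(seq_along(x) - 1L, function(r)
      paste(x[((seq_along(x) - 1L + r) %% length(x)) + 1L],
            collapse = ""), "")
  }
  min(c(rots(chars), rots(.revcompChars(chars))))
}

#' Score a repeat run
#'
#' @param length run length in bp.
#' @param mismatches number of mismatching positions.
#' @param params a [ScanParams-class].
#' @return integer score, `length - mismatchPenalty * mismatches`.
#' @examples
#' scoreRun(30, 1)  # 25 at default penalty 5
#' @export
scoreRun <- function(length, mismatches, params = scanParams()) {
  stopifnot(all(length >= 1), all(mismatches >= 0))
  as.integer(length - params@mismatchPenalty * mismatches)
}

## Candidate enumeration for one period k over one region of a character
## vector. Returns a data.frame of qualifying intervals.
.enumCandidates <- function(chars, k, from, to, params) {
  L <- length(chars)
  out <- vector("list", 0L)
  maxrun <- params@maxInterruptionRun
  if (to - from + 1L < 2L * k) return(NULL)
  for (i in from:(to - 2L * k + 1L)) {
    pat <- chars[i:(i + k - 1L)]
    if (any(pat == "N")) next
    if (k > 1L) {
      # pattern must be primitive at this period
      prim <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d != 0L) next
        if (all(pat == pat[((seq_len(k) - 1L) %% d) + 1L])) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
    }
    span <- i:to
    segN <- which(chars[span] == "N")
    if (length(segN)) span <- span[seq_len(segN[1L] - 1L)]
    if (length(span) < 2L * k) next
    expd <- pat[((span - i) %% k) + 1L]
    mm <- chars[span] != expd
    # interruption limit: truncate before any run of > maxrun mismatches
    r <- rle(mm)
    bad <- which(r$values & r$lengths > maxrun)
    if (length(bad)) {
      cut <- cumsum(r$lengths)[bad[1L] - 1L] + maxrun  # last legal offset
      span <- span[seq_len(cut)]
      mm <- mm[seq_len(cut)]
    }
    if (length(span) < 2L * k) next
    cmm <- cumsum(mm)
    lens <- seq_along(span)
    scores <- lens - params@mismatchPenalty * cmm
    # every record must contain a perfect seed stretch
    need <- max(2L * k, params@minSeedLength)
    zrun <- numeric(length(mm))
    run <- 0L
    for (t in seq_along(mm)) {
      run <- if (mm[t]) 0L else run + 1L
      zrun[t] <- run
    }
    hasSeed <- cummax(zrun) >= need
    keep <- !mm & lens >= 2L * k & scores >= params@minScore & hasSeed
    if (!any(keep)) next
    jj <- span[keep]
    out[[length(out) + 1L]] <- data.frame(
      start = i, end = jj, k = k,
      mismatches = cmm[keep], score = scores[keep],
      pattern = paste(pat, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## Seed regions for one period k: perfect stretches of >= max(2k,
## minSeedLength) bp, expanded outwards while the k-periodicity does not
## fail at more than `slack` consecutive positions, hard-stopping at N.
.seedRegions <- function(chars, k, params, slack = 8L) {
  L <- length(chars)
  if (L < 2L * k) return(NULL)
  p <- seq_len(L - k)
  M <- chars[p] == chars[p + k] & chars[p] != "N" & chars[p + k] != "N"
  r <- rle(M)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- max(k, max(2L * k, params@minSeedLength) - k)
  sel <- which(r$values & r$lengths >= need)
  if (!length(sel)) return(NULL)
  regs <- matrix(0L, nrow = length(sel), ncol = 2L)
  for (si in seq_along(sel)) {
    a <- starts[sel[si]]; b <- ends[sel[si]] + k
    lo <- a; fails <- 0L
    while (lo > 1L && fails < slack) {
      q <- lo - 1L
      if (chars[q] == "N") break
      if (q + k <= L && chars[q + k] != "N" && chars[q] == chars[q + k])
        fails <- 0L else fails <- fails + 1L
      lo <- q
    }
    hi <- b; fails <- 0L
    while (hi < L && fails < slack) {
      q <- hi + 1L
      if (chars[q] == "N") break
      if (q - k >= 1L && chars[q - k] != "N" && chars[q] == chars[q - k])
        fails <- 0L else fails <- fails + 1L
      hi <- q
    }
    regs[si, ] <- c(lo, hi)
  }
  # merge overlapping regions
  o <- order(regs[, 1L])
  regs <- regs[o, , drop = FALSE]
  merged <- regs[1L, , drop = FALSE]
  if (nrow(regs) > 1L) for (ri in 2:nrow(regs)) {
    last <- nrow(merged)
    if (regs[ri, 1L] <= merged[last, 2L] + 1L)
      merged[last, 2L] <- max(merged[last, 2L], regs[ri, 2L])
    else merged <- rbind(merged, regs[ri, , drop = FALSE])
  }
  merged
}

.emptyScan <- function() {
  data.frame(sequence_id = character(), start = integer(),
             end = integer(), motif = character(), length = integer(),
             mismatches = integer(), score = integer(),
             perfect = logical(), stringsAsFactors = FALSE)
}

## Greedy non-overlap resolution shared ordering: score desc, shorter
## motif, leftmost start, earliest end.
.resolveCandidates <- function(cand) {
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$score, cand$k, cand$start, cand$end), ,
               drop = FALSE]
  keptS <- integer(); keptE <- integer()
  keep <- logical(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    s <- cand$start[ci]; e <- cand$end[ci]
    if (!length(keptS) || all(e < keptS | s > keptE)) {
      keep[ci] <- TRUE
      keptS <- c(keptS, s); keptE <- c(keptE, e)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Scan one DNA sequence for microsatellites
#'
#' Detects tandem repeats of 1-6 bp motifs under the fixed-penalty
#' scoring model: perfect seed runs are located for every motif length,
#' extended in both directions tolerating isolated mismatches, and all
#' qualifying intervals in the surrounding region are enumerated; the
#' final report is the greedy non-overlapping selection by (score,
#' shorter motif, leftmost). Motifs are reported canonically (see
#' [canonicalMotif()]). Records never span an `N`.
#'
#' @param seq DNA string over ACGTN (case-insensitive) or a single
#'   [Biostrings::DNAString].
#' @param id sequence identifier for the report.
#' @param params a [ScanParams-class].
#' @return data.frame with columns `sequence_id`, `start`, `end` (1-based
#'   inclusive), `motif`, `length`, `mismatches`, `score`, `perfect`,
#'   sorted by start. Zero rows when nothing qualifies.
#' @examples
#' scanSequence(strrep("AGC", 8), "toy")
#' @export
scanSequence <- function(seq, id = "seq1", params = scanParams()) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) return(.emptyScan())
  chars <- strsplit(seq, "")[[1]]
  .checkAlphabet(chars, allowN = TRUE)
  cands <- vector("list", 0L)
  for (k in params@motifLengths) {
    regs <- .seedRegions(chars, k, params)
    if (is.null(regs)) next
    for (ri in seq_len(nrow(regs))) {
      cc <- .enumCandidates(chars, k, regs[ri, 1L], regs[ri, 2L], params)
      if (!is.null(cc)) cands[[length(cands) + 1L]] <- cc
    }
  }
  if (!length(cands)) return(.emptyScan())
  cand <- unique(do.call(rbind, cands))
  res <- .resolveCandidates(cand)
  if (is.null(res)) return(.emptyScan())
  res <- res[order(res$start), , drop = FALSE]
  data.frame(
    sequence_id = id,
    start = res$start,
    end = res$end,
    motif = vapply(res$pattern, canonicalMotif, ""),
    length = res$end - res$start + 1L,
    mismatches = res$mismatches,
    score = res$score,
    perfect = res$mismatches == 0L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Scan a set of sequences (a genome) for microsatellites
#'
#' @param x a named character vector, a [Biostrings::DNAStringSet], or a
#'   path to a FASTA file.
#' @param params a [ScanParams-class].
#' @return data.frame of records as in [scanSequence()], sorted by
#'   (sequence_id, start).
#' @export
scanGenome <- function(x, params = scanParams()) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x))
    x <- readFasta(x)
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  out <- lapply(names(seqs), function(id)
    scanSequence(seqs[[id]], id = id, params = params))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(.emptyScan())
  out[order(out$sequence_id, out$start), , drop = FALSE]
}
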