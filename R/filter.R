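## Stringent marker-candidate filtering with a per-rule audit trail.

#' Find perfect tandem repeats in a sequence
#'
#' Utility scan for secondary repeats: reports every maximal perfect
#' tandem run of a 1-6 bp primitive motif with at least `minUnits`
#' complete units (no score threshold). Used to audit amplicons for
#' nanosatellites and homopolymers.
#'
#' @param seq DNA string.
#' @param minUnits minimum complete tandem units (default 4).
#' @param motifLengths motif lengths considered.
#' @return data.frame with `start`, `end`, `motif_length`, `motif`,
#'   `units`.
#' @export
findTandemRepeats <- function(seq, minUnits = 4L, motifLengths = 1:6) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  L <- length(chars)
  out <- list()
  for (k in motifLengths) {
    if (L < k * (minUnits)) next
    p <- seq_len(L - k)
    M <- chars[p] == chars[p + k] & chars[p] != "N" & chars[p + k] != "N"
    r <- rle(M)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- which(r$values & (r$lengths + k) >= k * minUnits)
    for (si in sel) {
      a <- starts[si]; b <- ends[si] + k
      pat <- paste(chars[a:(a + k - 1L)], collapse = "")
      if (primitivePeriod(pat) != k) next
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, motif_length = k,
        motif = canonicalMotif(pat), units = (b - a + 1L) %/% k)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif_length = integer(), motif = character(),
                      units = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_length), , drop = FALSE]
}

#' Stringent filter of marker candidates
#'
#' Applies the full candidate rule set to each locus context and
#' records every violated rule. A locus passes when: the motif is tri-
#' or tetranucleotide (`MOTIF_CLASS`); it has more than `minUnits - 1`
#' complete repeat units, i.e. at least 8 by default (`MIN_REPEATS`);
#' it is perfect (`PERFECT_ONLY`); at least one primer pair can be
#' designed in the flanks (`PRIMER_DESIGN`); both primer 3' ends lie
#' more than `min3prime` bp from the repeat (`MIN_3PRIME_DISTANCE`);
#' and the best amplicon contains the target as its only
#' microsatellite, with no secondary tandem of >= 4 units and no
#' homopolymer of >= 8 bp (`SINGLE_TARGET_AMPLICON`).
#'
#' @param contexts list of locus contexts from [extractContext()].
#' @param params a [ScanParams-class] used to re-scan amplicons.
#' @param motifClasses admissible motif lengths (default 3:4).
#' @param minUnits minimum complete repeat units (default 8, the strict
#'   reading of "more than seven").
#' @param min3prime minimum primer-3'-end to repeat distance, bp.
#' @param secondaryMinUnits secondary-repeat unit threshold.
#' @param homopolymerMax longest tolerated homopolymer, bp.
#' @param ... passed to [designPrimers()].
#' @return data.frame audit: `locus_id`, `scaffold`, `start`, `end`,
#'   `motif`, `repeats`, `passed`, `failed_rules` (comma-joined),
#'   primer columns for the retained best pair (NA when none).
#' @export
stringentFilter <- function(contexts, params = scanParams(),
                            motifClasses = c(3L, 4L), minUnits = 8L,
                            min3prime = 10L, secondaryMinUnits = 4L,
                            homopolymerMax = 7L, ...) {
  rows <- lapply(contexts, function(ctx) {
    rec <- ctx$record
    k <- nchar(rec$motif)
    units <- as.integer((rec$end - rec$start + 1L) %/% k)
    fails <- character()
    if (!k %in% motifClasses) fails <- c(fails, "MOTIF_CLASS")
    if (units < minUnits) fails <- c(fails, "MIN_REPEATS")
    if (rec$mismatches > 0L) fails <- c(fails, "PERFECT_ONLY")
    primers <- designPrimers(ctx, ...)
    best <- NULL
    if (nrow(primers) == 0L) {
      fails <- c(fails, "PRIMER_DESIGN")
    } else {
      ok3 <- primers$dist3_forward > min3prime &
        primers$dist3_reverse > min3prime
      if (!any(ok3)) {
        fails <- c(fails, "MIN_3PRIME_DISTANCE")
        best <- primers[1L, , drop = FALSE]
      } else {
        best <- primers[which(ok3)[1L], , drop = FALSE]
        # audit the amplicon of the best admissible pair; product
        # coordinates are relative to the context (flank+repeat+flank)
        full <- paste0(ctx$upstream, .contextRepeat(ctx),
                       ctx$downstream)
        ampl <- substr(full, best$product_start, best$product_end)
        amplRecords <- scanSequence(ampl, id = "amplicon",
                                    params = params)
        tandems <- findTandemRepeats(ampl, minUnits = secondaryMinUnits)
        upOff <- nchar(ctx$upstream) - best$product_start + 1L
        targetStart <- upOff + 1L
        targetEnd <- upOff + (rec$end - rec$start + 1L)
        isTarget <- function(s, e)
          s <= targetEnd && e >= targetStart
        secTandems <- tandems[!vapply(seq_len(nrow(tandems)),
          function(i) isTarget(tandems$start[i], tandems$end[i]), NA), ,
          drop = FALSE]
        homop <- secTandems[secTandems$motif_length == 1L &
          (secTandems$end - secTandems$start + 1L) > homopolymerMax, ,
          drop = FALSE]
        secOther <- secTandems[secTandems$motif_length > 1L, ,
                               drop = FALSE]
        nTargetRecords <- sum(vapply(seq_len(nrow(amplRecords)),
          function(i) isTarget(amplRecords$start[i],
                               amplRecords$end[i]), NA))
        extraRecords <- nrow(amplRecords) - nTargetRecords
        if (extraRecords > 0L || nrow(secOther) > 0L ||
            nrow(homop) > 0L)
          fails <- c(fails, "SINGLE_TARGET_AMPLICON")
      }
    }
    base <- data.frame(
      locus_id = sprintf("%s_%d_%d", ctx$scaffold_id, rec$start,
                         rec$end),
      scaffold = ctx$scaffold_id, start = rec$start, end = rec$end,
      motif = rec$motif, repeats = units,
      passed = length(fails) == 0L,
      failed_rules = paste(fails, collapse = ","))
    if (is.null(best)) {
      base$forward <- base$reverse <- NA_character_
      base$forward_tm <- base$reverse_tm <- NA_real_
      base$product_size <- NA_integer_
    } else {
      base$forward <- best$forward_seq
      base$reverse <- best$reverse_seq
      base$forward_tm <- best$forward_tm
      base$reverse_tm <- best$reverse_tm
      base$product_size <- best$product_size
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## the repeat's own sequence is not stored in the context; rebuild it
## from the flanks' host scaffold is not possible here, so contexts are
## expected to carry it as `target` when produced by pipeline helpers.
.contextRepeat <- function(ctx) {
  if (!is.null(ctx$target)) return(ctx$target)
  stop("context lacks the target repeat sequence; use makeContexts()",
       call. = FALSE)
}

#' Build locus contexts for a set of records
#'
#' Convenience wrapper calling [extractContext()] per record and
#' attaching the repeat's own sequence (`target`), which the amplicon
#' audit in [stringentFilter()] needs.
#'
#' @param records SSR record data.frame.
#' @param genome named character vector or DNAStringSet.
#' @param flank flank length in bp.
#' @return list of contexts.
#' @export
makeContexts <- function(records, genome, flank = 300L) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- as.character(genome)
  lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    ctx <- extractContext(rec, genome, flank = flank)
    ctx$target <- toupper(substr(genome[[rec$sequence_id]], rec$start,
                                 rec$end))
    ctx
  })
}
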