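## Primer design over SSR flanking sequences.
##
## Melting temperatures use the unified nearest-neighbor thermodynamic
## parameters (SantaLucia 1998), a 0.368 * (N-1) * ln[Na+] entropy salt
## correction at 50 mM monovalent cation, and 0.25 uM primer:
##   Tm = 1000 * dH / (dS_corrected + R * ln(C/4)) - 273.15.

.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbor primer melting temperature
#'
#' @param seq primer sequence 5'->3' (ACGT).
#' @param Na monovalent salt concentration, mol/L (default 0.05).
#' @param conc primer concentration, mol/L (default 2.5e-7).
#' @return melting temperature in degrees Celsius.
#' @examples
#' primerTm("ACGTGCATGCATGCATGCAT")
#' @export
primerTm <- function(seq, Na = 0.05, conc = 2.5e-7) {
  chars <- strsplit(toupper(seq), "")[[1]]
  .checkAlphabet(chars, allowN = FALSE)
  n <- length(chars)
  if (n < 8L) stop("primer too short for NN model", call. = FALSE)
  steps <- paste0(chars[-n], chars[-1L])
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  # initiation terms per terminal base
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(Na)
  1000 * dH / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Locus context: a repeat with its flanking sequence
#'
#' Extracts the target repeat and up to `flank` bp of sequence on each
#' side, truncated (never padded) at scaffold boundaries.
#'
#' @param record one-row SSR record data.frame (see [scanSequence()]).
#' @param genome named character vector or DNAStringSet of scaffolds.
#' @param flank flank length in bp (default 300).
#' @return list with `scaffold_id`, `record`, `upstream`, `downstream`
#'   (DNA strings), `upstream_truncated`, `downstream_truncated`.
#' @export
extractContext <- function(record, genome, flank = 300L) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- as.character(genome)
  sid <- record$sequence_id
  if (!sid %in% names(genome))
    stop("scaffold not found: ", sid, call. = FALSE)
  seq <- toupper(genome[[sid]])
  L <- nchar(seq)
  stopifnot(record$start >= 1L, record$end <= L)
  upFrom <- max(1L, record$start - flank)
  dnTo <- min(L, record$end + flank)
  list(
    scaffold_id = sid,
    record = record,
    upstream = substr(seq, upFrom, record$start - 1L),
    downstream = substr(seq, record$end + 1L, dnTo),
    upstream_truncated = (record$start - upFrom) < flank,
    downstream_truncated = (dnTo - record$end) < flank
  )
}

#' Design primer pairs for a locus context
#'
#' Enumerates candidate windows of `lenRange` bp in both flanks (the
#' reverse primer is the reverse complement of a downstream-flank
#' window), keeps those whose nearest-neighbor Tm lies in `tmRange`,
#' pairs them subject to the pairwise Tm difference limit, and ranks
#' pairs by the summed deviation from the optimal length (20 bp) and
#' optimal Tm (60 C). An empty result means no design is possible, not
#' an error.
#'
#' @param context a locus context from [extractContext()].
#' @param lenRange primer length range in bp.
#' @param tmRange allowed Tm range in degrees C.
#' @param tmMaxDiff maximum |forward Tm - reverse Tm|.
#' @param lenOpt,tmOpt optimal length and Tm used in ranking.
#' @param maxPerSide candidate windows retained per flank before
#'   pairing (best by rank score).
#' @return data.frame of pairs, best first: `forward_seq`,
#'   `reverse_seq`, `forward_tm`, `reverse_tm`, `product_start`,
#'   `product_end` (1-based within the context = flanks + repeat),
#'   `product_size`, `dist3_forward`, `dist3_reverse` (3' end to repeat,
#'   bp).
#' @export
designPrimers <- function(context, lenRange = c(18L, 24L),
                          tmRange = c(58, 62), tmMaxDiff = 4,
                          lenOpt = 20L, tmOpt = 60, maxPerSide = 25L) {
  empty <- data.frame(forward_seq = character(),
                      reverse_seq = character(),
                      forward_tm = numeric(), reverse_tm = numeric(),
                      product_start = integer(),
                      product_end = integer(), product_size = integer(),
                      dist3_forward = integer(),
                      dist3_reverse = integer())
  up <- context$upstream; dn <- context$downstream
  windows <- function(flankSeq) {
    L <- nchar(flankSeq)
    out <- list()
    for (len in lenRange[1L]:lenRange[2L]) {
      if (L < len) next
      for (s in 1L:(L - len + 1L)) {
        w <- substr(flankSeq, s, s + len - 1L)
        if (grepl("N", w, fixed = TRUE)) next
        tm <- primerTm(w)
        if (tm < tmRange[1L] || tm > tmRange[2L]) next
        out[[length(out) + 1L]] <- data.frame(
          seq = w, start = s, end = s + len - 1L, tm = tm,
          rank = abs(len - lenOpt) + abs(tm - tmOpt))
      }
    }
    if (!length(out)) return(NULL)
    o <- do.call(rbind, out)
    o <- o[order(o$rank, o$start), , drop = FALSE]
    head(o, maxPerSide)
  }
  fw <- windows(up)
  rv <- windows(dn)
  if (is.null(fw) || is.null(rv)) return(empty)
  upLen <- nchar(up)
  repLen <- context$record$end - context$record$start + 1L
  pairs <- list()
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    if (abs(fw$tm[i] - rv$tm[j]) >= tmMaxDiff) next
    prodStart <- fw$start[i]
    prodEnd <- upLen + repLen + rv$end[j]
    pairs[[length(pairs) + 1L]] <- data.frame(
      forward_seq = fw$seq[i],
      reverse_seq = paste(.revcompChars(strsplit(rv$seq[j], "")[[1]]),
                          collapse = ""),
      forward_tm = fw$tm[i], reverse_tm = rv$tm[j],
      product_start = prodStart, product_end = prodEnd,
      product_size = prodEnd - prodStart + 1L,
      dist3_forward = upLen - fw$end[i],
      dist3_reverse = rv$start[j] - 1L,
      rank = fw$rank[i] + rv$rank[j])
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out <- out[order(out$rank, out$product_start), , drop = FALSE]
  out$rank <- NULL
  rownames(out) <- NULL
  out
}
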