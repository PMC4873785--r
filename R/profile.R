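## Genome characterization statistics over a set of scanned SSR records.

#' Relative abundance of microsatellites
#'
#' Number of SSR loci per megabase of genome.
#'
#' @param count number of loci.
#' @param genomeLength genome length in bp.
#' @return loci per Mb.
#' @examples
#' relativeAbundance(132251, 410700254)  # 322.01 loci/Mb
#' @export
relativeAbundance <- function(count, genomeLength) {
  stopifnot(genomeLength > 0)
  count / (genomeLength / 1e6)
}

#' Relative density of microsatellites
#'
#' Total SSR length, reported in Kb, per megabase of genome.
#'
#' @param totalBp summed SSR length in bp.
#' @param genomeLength genome length in bp.
#' @return Kb of repeat sequence per Mb of genome.
#' @examples
#' relativeDensity(132251 * 28.18, 410700254)  # ~9.07 Kb/Mb
#' @export
relativeDensity <- function(totalBp, genomeLength) {
  stopifnot(genomeLength > 0)
  (totalBp / 1e3) / (genomeLength / 1e6)
}

#' Genome-level microsatellite profile
#'
#' Summary container produced by [profileGenome()].
#'
#' @slot totalCount total number of loci.
#' @slot perfectCount number of mismatch-free loci.
#' @slot genomeLength genome length in bp (denominator for abundance and
#'   density; includes N runs).
#' @slot relativeAbundance loci per Mb.
#' @slot relativeDensity Kb of repeat per Mb.
#' @slot meanLength mean locus length in bp.
#' @slot lengthQuantiles named numeric, locus length quantiles.
#' @slot perCategoryCounts named integer, loci per motif length 1..6.
#' @slot motifRanking data.frame (motif, count, fraction) sorted by
#'   decreasing count, ties alphabetical.
#' @slot lengthHistogram data.frame (motif_length, bin_start, bin_end,
#'   count).
#' @slot mismatchByLength data.frame from [mismatchLengthTable()].
#' @export
setClass("SSRProfile",
  representation(
    totalCount = "integer", perfectCount = "integer",
    genomeLength = "numeric",
    relativeAbundance = "numeric", relativeDensity = "numeric",
    meanLength = "numeric", lengthQuantiles = "numeric",
    perCategoryCounts = "integer",
    motifRanking = "data.frame",
    lengthHistogram = "data.frame",
    mismatchByLength = "data.frame"
  )
)

setMethod("show", "SSRProfile", function(object) {
  cat("SSRProfile\n")
  cat(sprintf("  loci: %d (%d perfect, %.1f%%)\n", object@totalCount,
              object@perfectCount,
              if (object@totalCount) 100 * object@perfectCount /
                object@totalCount else 0))
  cat(sprintf("  genome: %s bp\n",
              format(object@genomeLength, big.mark = ",")))
  cat(sprintf("  relative abundance: %.2f loci/Mb\n",
              object@relativeAbundance))
  cat(sprintf("  relative density:   %.2f Kb/Mb\n",
              object@relativeDensity))
  if (nrow(object@motifRanking)) {
    top <- head(object@motifRanking, 5)
    cat("  top motifs:", paste(sprintf("(%s)n %d", top$motif, top$count),
                               collapse = ", "), "\n")
  }
})

.lengthBins <- function(lengths, binWidth = 3L, from = 12L, to = 70L) {
  lo <- pmin(pmax(from + ((lengths - from) %/% binWidth) * binWidth,
                  from), to)
  lo
}

#' Mismatch and imperfection by locus length
#'
#' Tabulates, per motif length and locus-length bin, the mean mismatch
#' count and the fraction of imperfect loci. Following the perfect
#' versus imperfect analysis convention, only loci between `minLen` and
#' `maxLen` bp (default 20-70) are included: shorter loci are always
#' perfect under the default scan parameters.
#'
#' @param records data.frame of SSR records (as from [scanGenome()]).
#' @param binWidth bin width in bp (default 3).
#' @param minLen,maxLen length range analysed, bp.
#' @return data.frame with columns `motif_length`, `bin_start`,
#'   `bin_end`, `count`, `mean_mismatches`, `imperfect_fraction`.
#' @export
mismatchLengthTable <- function(records, binWidth = 3L, minLen = 20L,
                                maxLen = 70L) {
  stopifnot(binWidth >= 1L)
  empty <- data.frame(motif_length = integer(), bin_start = integer(),
                      bin_end = integer(), count = integer(),
                      mean_mismatches = numeric(),
                      imperfect_fraction = numeric())
  if (nrow(records) == 0L) return(empty)
  rec <- records[records$length >= minLen & records$length <= maxLen, ,
                 drop = FALSE]
  if (nrow(rec) == 0L) return(empty)
  ml <- nchar(rec$motif)
  bin <- minLen + ((rec$length - minLen) %/% binWidth) * binWidth
  key <- paste(ml, bin, sep = ":")
  agg <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    data.frame(
      motif_length = ml[idx[1L]],
      bin_start = bin[idx[1L]],
      bin_end = bin[idx[1L]] + binWidth - 1L,
      count = length(idx),
      mean_mismatches = mean(rec$mismatches[idx]),
      imperfect_fraction = mean(rec$mismatches[idx] > 0L)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$motif_length, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile a genome's microsatellite content
#'
#' Computes the genome-characterization summary from a set of scanned
#' records: total and perfect counts, relative abundance (loci/Mb),
#' relative density (Kb/Mb), length statistics, counts per motif-length
#' category, canonical-motif ranking, a length histogram (3-bp bins)
#' and the mismatch-by-length table.
#'
#' @param records data.frame of SSR records as returned by
#'   [scanGenome()] (columns `motif`, `length`, `mismatches`, ...).
#' @param genomeLength total genome length in bp (including N runs).
#' @param binWidth histogram bin width in bp.
#' @return An [SSRProfile-class] object.
#' @examples
#' rec <- scanSequence(paste0(strrep("AGC", 8), strrep("T", 40),
#'                            strrep("AC", 10)), "s1")
#' profileGenome(rec, genomeLength = 1e4)
#' @export
profileGenome <- function(records, genomeLength, binWidth = 3L) {
  stopifnot(genomeLength > 0)
  n <- nrow(records)
  if (n == 0L) {
    return(new("SSRProfile",
      totalCount = 0L, perfectCount = 0L,
      genomeLength = as.numeric(genomeLength),
      relativeAbundance = 0, relativeDensity = 0,
      meanLength = NaN, lengthQuantiles = numeric(),
      perCategoryCounts = setNames(integer(6L), as.character(1:6)),
      motifRanking = data.frame(motif = character(), count = integer(),
                                fraction = numeric()),
      lengthHistogram = data.frame(motif_length = integer(),
                                   bin_start = integer(),
                                   bin_end = integer(),
                                   count = integer()),
      mismatchByLength = mismatchLengthTable(records)))
  }
  ml <- nchar(records$motif)
  cat_counts <- setNames(integer(6L), as.character(1:6))
  tb <- table(factor(ml, levels = 1:6))
  cat_counts[names(tb)] <- as.integer(tb)
  mt <- table(records$motif)
  rank <- data.frame(motif = names(mt), count = as.integer(mt),
                     stringsAsFactors = FALSE)
  rank <- rank[order(-rank$count, rank$motif), , drop = FALSE]
  rank$fraction <- rank$count / n
  rownames(rank) <- NULL
  bins <- .lengthBins(records$length, binWidth)
  hk <- paste(ml, bins, sep = ":")
  ht <- table(hk)
  parts <- do.call(rbind, strsplit(names(ht), ":"))
  hist <- data.frame(motif_length = as.integer(parts[, 1L]),
                     bin_start = as.integer(parts[, 2L]),
                     count = as.integer(ht))
  hist$bin_end <- hist$bin_start + binWidth - 1L
  hist <- hist[order(hist$motif_length, hist$bin_start),
               c("motif_length", "bin_start", "bin_end", "count")]
  rownames(hist) <- NULL
  new("SSRProfile",
    totalCount = as.integer(n),
    perfectCount = as.integer(sum(records$mismatches == 0L)),
    genomeLength = as.numeric(genomeLength),
    relativeAbundance = relativeAbundance(n, genomeLength),
    relativeDensity = relativeDensity(sum(records$length), genomeLength),
    meanLength = mean(records$length),
    lengthQuantiles = stats::quantile(records$length,
                                      c(.25, .5, .75, .95)),
    perCategoryCounts = cat_counts,
    motifRanking = rank,
    lengthHistogram = hist,
    mismatchByLength = mismatchLengthTable(records, binWidth))
}

#' Write profile tables to a directory
#'
#' Emits `summary.tsv`, `motif_ranking.tsv`, `length_histogram.tsv` and
#' `mismatch_by_length.tsv`.
#'
#' @param profile an [SSRProfile-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
writeProfile <- function(profile, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- data.frame(
    statistic = c("total_count", "perfect_count", "genome_length",
                  "relative_abundance_per_mb", "relative_density_kb_per_mb",
                  "mean_length"),
    value = c(profile@totalCount, profile@perfectCount,
              profile@genomeLength, profile@relativeAbundance,
              profile@relativeDensity, profile@meanLength)
  )
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(summ, "summary.tsv")
  wt(profile@motifRanking, "motif_ranking.tsv")
  wt(profile@lengthHistogram, "length_histogram.tsv")
  wt(profile@mismatchByLength, "mismatch_by_length.tsv")
  invisible(dir)
}
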