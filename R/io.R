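## File formats: FASTA (via Biostrings), SSR report TSV/BED, GENEPOP.

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences and keeps only the first whitespace-delimited token of each
#' header as the id.
#'
#' @param path FASTA file (wrapped or unwrapped, case-insensitive).
#' @return a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @param width line width.
#' @return invisibly, the path.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Write / read an SSR report
#'
#' Tab-separated report with 1-based inclusive coordinates, or BED
#' (0-based half-open) when `format = "bed"`.
#'
#' @param records SSR record data.frame (see [scanSequence()]).
#' @param path output path.
#' @param format "tsv" or "bed".
#' @return invisibly, the path.
#' @export
writeSSR <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(chrom = records$sequence_id,
                      chromStart = records$start - 1L,
                      chromEnd = records$end,
                      name = sprintf("(%s)n", records$motif),
                      score = records$score)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeSSR
#' @export
readSSR <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

## ---- GENEPOP ---------------------------------------------------------

#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separators, then
#' `id , g1 g2 ...` rows where each genotype is a concatenation of two
#' 2- or 3-digit allele codes. Allele codes are taken as allele sizes in
#' bp; `00`/`000` codes mean missing.
#'
#' @param path GENEPOP file.
#' @param popNames optional character vector naming the populations in
#'   order; defaults to `pop1`, `pop2`, ...
#' @return a [GenotypeMatrix-class].
#' @export
readGenepop <- function(path, popNames = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("malformed GENEPOP file: too short",
                               call. = FALSE)
  body <- lines[-1L]
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("malformed GENEPOP file: no Pop line",
                            call. = FALSE)
  lociLines <- body[seq_len(popIdx[1L] - 1L)]
  loci <- unlist(strsplit(lociLines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  nloc <- length(loci)
  popOf <- findInterval(seq_along(body), popIdx)
  indLines <- which(popOf >= 1L & !(seq_along(body) %in% popIdx))
  ids <- character(); pops <- integer()
  A <- NULL; B <- NULL
  rows <- vector("list", length(indLines))
  for (w in seq_along(indLines)) {
    ln <- body[indLines[w]]
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed GENEPOP row (no comma): ", ln, call. = FALSE)
    id <- trimws(parts[1L])
    geno <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                     "\\s+")[[1L]]
    if (length(geno) != nloc)
      stop(sprintf(
        "individual '%s': %d genotype fields, expected %d",
        id, length(geno), nloc), call. = FALSE)
    w2 <- nchar(geno)
    if (!all(w2 %in% c(4L, 6L)))
      stop(sprintf("individual '%s': unsupported allele code width", id),
           call. = FALSE)
    half <- w2 / 2L
    a <- as.integer(substr(geno, 1L, half))
    b <- as.integer(substr(geno, half + 1L, w2))
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    miss <- is.na(a) | is.na(b)
    a[miss] <- NA_integer_; b[miss] <- NA_integer_
    rows[[w]] <- list(id = id, pop = popOf[indLines[w]], a = a, b = b)
  }
  ids <- vapply(rows, `[[`, "", "id")
  pops <- vapply(rows, `[[`, 1L, "pop")
  A <- do.call(rbind, lapply(rows, `[[`, "a"))
  B <- do.call(rbind, lapply(rows, `[[`, "b"))
  rownames(A) <- rownames(B) <- make.unique(ids)
  colnames(A) <- colnames(B) <- loci
  if (is.null(popNames)) popNames <- sprintf("pop%d", seq_len(max(pops)))
  genotypeMatrix(A, B, factor(popNames[pops], levels = popNames))
}

#' Write a GenotypeMatrix to a GENEPOP file
#'
#' Allele sizes are written as 3-digit codes (6-character genotypes);
#' missing genotypes as `000000`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @param title title line content.
#' @return invisibly, the path.
#' @export
writeGenepop <- function(gm, path, title = "ssrforge export") {
  A <- gm@alleleA; B <- gm@alleleB
  if (any(!is.na(A) & A > 999L) || any(!is.na(B) & B > 999L))
    stop("allele sizes exceed 3-digit GENEPOP coding", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(A), con)
  fmt <- function(a, b) {
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
    sprintf("%03d%03d", a, b)
  }
  for (p in levels(gm@pop)) {
    writeLines("Pop", con)
    for (i in which(gm@pop == p)) {
      writeLines(paste0(rownames(A)[i], " , ",
                        paste(fmt(A[i, ], B[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

## ---- packaged marker table ------------------------------------------

#' Published microsatellite marker table for the western flower thrips
#'
#' Loads the packaged characterization table of 30 polymorphic
#' microsatellite loci developed for *Frankliniella occidentalis* from
#' its draft genome: locus id, source scaffold, repeat motif and unit
#' count, allele-size range, number of alleles (`n_alleles`), number of
#' individuals successfully genotyped out of the 48-insect cohort
#' (`n_genotyped`), fluorescent label, published panel membership, the
#' number of populations (of two surveyed) in which the locus deviated
#' from Hardy-Weinberg equilibrium after sequential Bonferroni
#' correction, and whether its electropherogram peaks were ambiguous.
#'
#' @param cohortSize the genotyping cohort size used to define full
#'   amplification (default 47, the largest `n_genotyped` observed).
#' @return data.frame with one row per locus, including derived columns
#'   `motif_length`, `sni` (single-nucleotide-insertion panel flag),
#'   `amplified_in_all` and `hwe_deviant_all_pops`.
#' @examples
#' head(wftMarkerLoci())
#' @export
wftMarkerLoci <- function(cohortSize = 47L) {
  path <- system.file("extdata", "wft_marker_loci.tsv",
                      package = "ssrforge", mustWork = TRUE)
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$motif_length <- nchar(x$motif)
  panels <- strsplit(x$panel, ",")
  x$sni <- vapply(panels, function(p) "SNI" %in% p, NA)
  x$amplified_in_all <- x$n_genotyped >= cohortSize
  x$hwe_deviant_all_pops <- x$hwe_deviant_pops >= 2L
  x$ambiguous_peaks <- as.logical(x$ambiguous_peaks)
  x
}

#' Pipeline configuration defaults
#'
#' Every tunable of the pipeline with its default value: scan score
#' threshold and penalty, flank length, candidate-filter thresholds,
#' primer constraints, test settings and panel parameters.
#'
#' @return named list of defaults.
#' @export
runDefaults <- function() {
  list(
    min_score = 15L, mismatch_penalty = 5L, motif_lengths = 1:6,
    flank = 300L,
    candidate_motif_lengths = c(3L, 4L), min_repeat_units = 8L,
    primer_len = c(18L, 24L), primer_len_opt = 20L,
    tm_range = c(58, 62), tm_opt = 60, tm_max_diff = 4,
    min_3prime_distance = 10L,
    secondary_min_units = 4L, homopolymer_max = 7L,
    alpha = 0.05, hwe_reps = 1e5, ld_reps = 1e4,
    panel_k = 8L, q_threshold = 0.60
  )
}
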