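#' @import methods
#' @importFrom stats p.adjust pchisq prcomp rbinom rgamma rnorm runif
#'   setNames wilcox.test complete.cases
#' @importFrom utils head read.delim write.table combn
NULL

#' Scan parameters for microsatellite discovery
#'
#' Container for the fixed-penalty scoring parameters of the repeat
#' scanner. A detected repeat of length \eqn{L} bp with \eqn{m}
#' mismatches against the periodic expectation scores
#' \eqn{L - \mathrm{penalty} \times m}; only runs scoring at least
#' `minScore` are reported.
#'
#' @slot minScore integer, minimum reported score (default 15).
#' @slot mismatchPenalty integer, score penalty per mismatch (default 5).
#' @slot motifLengths integer vector, motif lengths to scan (subset of 1:6).
#' @slot minSeedLength integer, minimum perfect seed length in bp; a seed
#'   must also span at least two complete motif units.
#' @slot maxInterruptionRun integer, maximum number of consecutive
#'   interrupting bases tolerated inside a single locus.
#'
#' @export
setClass("ScanParams",
  representation(
    minScore = "integer",
    mismatchPenalty = "integer",
    motifLengths = "integer",
    minSeedLength = "integer",
    maxInterruptionRun = "integer"
  )
)

setValidity("ScanParams", function(object) {
  msg <- character()
  if (length(object@minScore) != 1L || object@minScore <= 0L)
    msg <- c(msg, "minScore must be a single positive integer")
  if (length(object@mismatchPenalty) != 1L || object@mismatchPenalty <= 0L)
    msg <- c(msg, "mismatchPenalty must be a single positive integer")
  if (length(object@motifLengths) == 0L ||
      !all(object@motifLengths %in% 1:6))
    msg <- c(msg, "motifLengths must be a non-empty subset of 1:6")
  if (anyDuplicated(object@motifLengths))
    msg <- c(msg, "motifLengths must be unique")
  if (object@minSeedLength < 2L)
    msg <- c(msg, "minSeedLength must be >= 2")
  if (object@maxInterruptionRun < 1L)
    msg <- c(msg, "maxInterruptionRun must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct scan parameters
#'
#' @param minScore minimum score for a reported locus.
#' @param mismatchPenalty penalty per mismatch in score units.
#' @param motifLengths motif lengths (bp) to scan, subset of 1:6.
#' @param minSeedLength minimum perfect seed length in bp.
#' @param maxInterruptionRun maximum consecutive interrupting bases.
#'
#' @return A [ScanParams-class] object.
#' @examples
#' scanParams()
#' scanParams(minScore = 20, motifLengths = 2:4)
#' @export
scanParams <- function(minScore = 15L, mismatchPenalty = 5L,
                       motifLengths = 1:6, minSeedLength = 8L,
                       maxInterruptionRun = 3L) {
  new("ScanParams",
    minScore = as.integer(minScore),
    mismatchPenalty = as.integer(mismatchPenalty),
    motifLengths = as.integer(sort(unique(motifLengths))),
    minSeedLength = as.integer(minSeedLength),
    maxInterruptionRun = as.integer(maxInterruptionRun)
  )
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams\n")
  cat("  minScore:           ", object@minScore, "\n")
  cat("  mismatchPenalty:    ", object@mismatchPenalty, "\n")
  cat("  motifLengths:       ", paste(object@motifLengths, collapse = ","),
      "\n")
  cat("  minSeedLength:      ", object@minSeedLength, "\n")
  cat("  maxInterruptionRun: ", object@maxInterruptionRun, "\n")
})

#' Diploid genotype matrix with population labels
#'
#' Holds codominant allele-size calls (bp) for a set of individuals at a
#' set of microsatellite loci. Each call is an unordered pair of allele
#' sizes; missing genotypes carry `NA` in both allele slots.
#'
#' @slot alleleA integer matrix, individuals x loci, first allele size.
#' @slot alleleB integer matrix, individuals x loci, second allele size.
#' @slot pop factor of population labels, one per individual.
#' @slot loci data.frame with columns `locus` and `motif_length`.
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    pop = "factor",
    loci = "data.frame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  dA <- dim(object@alleleA); dB <- dim(object@alleleB)
  if (!identical(dA, dB))
    msg <- c(msg, "alleleA and alleleB must have identical dimensions")
  if (length(object@pop) != dA[1L])
    msg <- c(msg, "pop must have one label per individual (row)")
  if (!all(c("locus", "motif_length") %in% names(object@loci)))
    msg <- c(msg, "loci must have columns 'locus' and 'motif_length'")
  if (nrow(object@loci) != dA[2L])
    msg <- c(msg, "loci must describe every column")
  if (!identical(is.na(object@alleleA), is.na(object@alleleB)))
    msg <- c(msg, "missing calls must be NA in both allele slots")
  av <- c(object@alleleA, object@alleleB)
  if (any(!is.na(av) & av <= 0))
    msg <- c(msg, "allele sizes must be positive")
  if (nlevels(droplevels(object@pop)) < 1L)
    msg <- c(msg, "at least one population required")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param alleleA,alleleB integer matrices (individuals x loci) of allele
#'   sizes in bp; `NA` (in both) marks a missing genotype. Column names
#'   are taken as locus ids, row names as individual ids.
#' @param pop character or factor of population labels per individual.
#' @param loci optional data.frame with columns `locus`, `motif_length`;
#'   when omitted, motif lengths are set to `NA`.
#'
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(alleleA, alleleB, pop, loci = NULL) {
  alleleA <- as.matrix(alleleA); alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  if (is.null(colnames(alleleA)))
    colnames(alleleA) <- colnames(alleleB) <-
      sprintf("L%02d", seq_len(ncol(alleleA)))
  if (is.null(rownames(alleleA)))
    rownames(alleleA) <- rownames(alleleB) <-
      sprintf("ind%03d", seq_len(nrow(alleleA)))
  if (is.null(loci))
    loci <- data.frame(locus = colnames(alleleA),
                       motif_length = NA_integer_)
  new("GenotypeMatrix", alleleA = alleleA, alleleB = alleleB,
      pop = as.factor(pop), loci = loci)
}

#' @describeIn GenotypeMatrix-class number of individuals
#' @param gm a [GenotypeMatrix-class]
#' @export
nIndividuals <- function(gm) nrow(gm@alleleA)

#' @describeIn GenotypeMatrix-class number of loci
#' @export
nLoci <- function(gm) ncol(gm@alleleA)

#' @describeIn GenotypeMatrix-class population labels (factor)
#' @export
popLabels <- function(gm) gm@pop

#' @describeIn GenotypeMatrix-class locus ids
#' @export
lociNames <- function(gm) colnames(gm@alleleA)

#' @describeIn GenotypeMatrix-class locus metadata data.frame
#' @export
lociInfo <- function(gm) gm@loci

#' @describeIn GenotypeMatrix-class allele calls at one locus as a
#'   two-column matrix (NA rows are missing genotypes)
#' @param locus locus id or column index
#' @export
alleleCalls <- function(gm, locus) {
  cbind(a = gm@alleleA[, locus], b = gm@alleleB[, locus])
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nIndividuals(object), "individuals x",
      nLoci(object), "loci\n")
  tab <- table(object@pop)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  miss <- mean(is.na(object@alleleA))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

#' Marker panel set
#'
#' The four marker panels built from per-locus profiles: MP (most
#' polymorphic non-SNI loci by allele number), SNI (loci with
#' single-nucleotide-insertion alleles), SS (stringently selected loci),
#' and ALL (every profiled locus), with the rule that placed or excluded
#' each locus from each panel.
#'
#' @slot panels named list of character vectors (MP, SNI, SS, ALL).
#' @slot decisions data.frame with one row per locus x panel decision.
#'
#' @export
setClass("PanelSet",
  representation(panels = "list", decisions = "data.frame")
)

setValidity("PanelSet", function(object) {
  msg <- character()
  if (!all(c("MP", "SNI", "SS", "ALL") %in% names(object@panels)))
    msg <- c(msg, "panels must contain MP, SNI, SS and ALL")
  else {
    all_ <- object@panels$ALL
    for (p in c("MP", "SNI", "SS"))
      if (!all(object@panels[[p]] %in% all_))
        msg <- c(msg, sprintf("panel %s is not a subset of ALL", p))
    if (length(intersect(object@panels$MP, object@panels$SNI)))
      msg <- c(msg, "MP and SNI must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PanelSet-class member loci of one panel
#' @param x a `PanelSet`
#' @param panel one of "MP", "SNI", "SS", "ALL"
#' @export
panelMembers <- function(x, panel) x@panels[[match.arg(panel,
  c("MP", "SNI", "SS", "ALL"))]]

#' @describeIn PanelSet-class per-locus inclusion/exclusion decisions
#' @export
panelDecisions <- function(x) x@decisions

setMethod("show", "PanelSet", function(object) {
  cat("PanelSet\n")
  for (p in c("MP", "SNI", "SS", "ALL")) {
    m <- object@panels[[p]]
    cat(sprintf("  %-3s (%2d): %s\n", p, length(m),
                paste(head(m, 8), collapse = ", ")))
  }
})
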