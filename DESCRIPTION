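Package: ssrforge
Title: Genome-Wide Microsatellite Discovery and Stringent Marker Panel
    Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide discovery of microsatellites (simple
    sequence repeats) with fixed-penalty mismatch scoring and motif
    canonicalization, genome characterization statistics (relative
    abundance and density, motif and length spectra), marker-candidate
    filtering with primer design constraints and a per-rule audit trail,
    population-genetic evaluation of codominant loci (heterozygosities,
    allelic richness by rarefaction, Weir-Cockerham F-statistics, exact
    Hardy-Weinberg and linkage-disequilibrium tests, null-allele EM
    estimation), and rule-based construction and comparison of marker
    panels (most-polymorphic, single-nucleotide-insertion, stringently
    selected, and all-marker sets) including leave-one-out likelihood
    assignment of individuals. Synthetic genome and two-population
    genotype simulators provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, PopulationGenetics, Software
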