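---
title: "Microsatellite discovery and stringent marker selection with ssrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite discovery and stringent marker selection with ssrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrforge)
```

## Overview

`ssrforge` implements a complete microsatellite (SSR) marker pipeline
for non-model genomes, of the kind used to develop codominant markers
for population-genetic studies of invasive insects such as the western
flower thrips *Frankliniella occidentalis*: genome-wide repeat
discovery under a fixed-penalty mismatch score, genome
characterization, stringent filtering of marker candidates, per-locus
population-genetic evaluation, and rule-based construction of four
marker panels (most polymorphic, SNI-bearing, stringently selected,
and all markers) whose behaviour can be compared on diversity,
differentiation and individual assignment. Synthetic genome and
genotype generators provide planted ground truth for every stage, so
the whole pipeline is testable without any external download.

## The repeat scanner

A microsatellite is scored against the periodic extension of a 1-6 bp
motif. A candidate locus is an interval read against the pattern
anchored at its start (its first `k` bases), with

\[ \mathrm{score} = \mathrm{length} - \mathrm{penalty} \times
   \mathrm{mismatches}, \]

and is reportable when it

* scores at least `minScore` (default 15, with `penalty` 5 — so any
  locus shorter than 20 bp is necessarily perfect, a property the test
  suite asserts);
* starts and ends on a matching base and spans at least two complete
  motif units;
* contains a perfect seed stretch of at least two full units and
  `minSeedLength` (8) bp;
* contains no `N` and no interruption longer than
  `maxInterruptionRun` (3) bp — longer interruptions split a region
  into separate loci.

Overlapping candidates (within and across motif lengths) are resolved
greedily by highest score, then shorter motif, then leftmost start,
then earliest end, which makes the output deterministic. The reported
motif is the canonical class representative: the lexicographically
smallest cyclic rotation of the primitive motif or of its reverse
complement, so `GA`, `CT` and `TC` all report as `AG`.

Two design points deserve a note. First, the seed is defined as two
complete units and at least 8 bp (rather than three units): a single
interior substitution in a five-unit hexanucleotide repeat leaves no
three-unit perfect stretch, yet such a locus passes the score
threshold, so a three-unit seed would silently miss loci the scoring
semantics admit. Second, when extending by five extra bases buys
exactly one extra mismatch the score is unchanged; records are trimmed
to the shortest maximal-score extent, keeping reported boundaries on
matching bases.

The scanner is validated against an exhaustive oracle that enumerates
every (interval, motif length) pair under the same reportable-locus
definition and performs the same greedy resolution; on generated
sequences up to 200 bp the two agree record-for-record. The sequence
generator used for this comparison plants repeats whose interruptions
are isolated and at least one seed length apart — the regime the
scoring model is designed for; densely or adversarially interrupted
repeats are split or trimmed rather than recovered whole, which is the
intended behaviour but means the equivalence statement is about this
regime, not about arbitrary sequence.

```{r scan-demo}
sim <- simulateGenome(list(list(motif = "AAG", units = 10,
                                mismatches = 13)),
                      scaffoldLength = 2000, seed = 7)
scanGenome(sim$genome)
```

## Genome characterization

`profileGenome()` summarizes a record set into the survey statistics:
relative abundance (loci/Mb), relative density (Kb of repeat per Mb),
counts per motif-length category, the canonical-motif ranking, a 3-bp
length histogram, and a mismatch-by-length table restricted to the
20-70 bp range (below 20 bp every locus is perfect by construction, so
shorter bins carry no information about imperfection). The genome
length used as denominator is the raw assembly total including N runs,
matching how published survey denominators are defined.

## Marker-candidate filtering

`stringentFilter()` turns scanned loci into marker candidates with a
per-rule audit trail. The rules, each with its identifier in the
audit:

* `MOTIF_CLASS` — only tri- and tetranucleotide motifs are eligible
  (di-nucleotides stutter during amplification);
* `MIN_REPEATS` — more than seven complete units, read strictly, i.e.
  at least eight;
* `PERFECT_ONLY` — no interruptions in the repeat region;
* `PRIMER_DESIGN` — at least one admissible primer pair exists in the
  300 bp flanks: length 18-24 bp (optimum 20), nearest-neighbor Tm
  58-62 °C (optimum 60), pairwise Tm difference < 4 °C;
* `MIN_3PRIME_DISTANCE` — both primer 3' ends more than 10 bp from the
  repeat;
* `SINGLE_TARGET_AMPLICON` — the amplicon of the best admissible pair
  contains the target as its only microsatellite, with no secondary
  tandem of four or more units of any 1-6 bp motif ("nanosatellites")
  and no homopolymer of eight or more bases.

Melting temperatures use the unified nearest-neighbor parameters
(SantaLucia 1998) with the 0.368·(N−1)·ln[Na⁺] entropy salt correction
at 50 mM monovalent cation and 0.25 µM primer; the model is fixed and
documented rather than matched bit-for-bit to any particular design
program, whose internal settings are not reproducible from published
descriptions. "Nanosatellite" and "homopolymer" have no standard
quantitative definition; the thresholds above (≥ 4 units, ≥ 8 bp) are
the package's operationalization and are exposed as arguments.

Ranked primer pairs minimize the summed deviation from the optimal
length and temperature; one best pair per locus feeds the amplicon
audit, and relaxing any single threshold never removes a previously
passing locus (tested).

## Population-genetic evaluation

For a diploid codominant `GenotypeMatrix` (read and written in
GENEPOP format, 3-digit allele-size codes, `000000` missing):

* observed heterozygosity and Nei's unbiased expected heterozygosity
  \(H_E = \frac{2n}{2n-1}(1-\sum p_i^2)\);
* allelic richness by rarefaction to `g` genes,
  \(A_R = \sum_a [1 - \binom{2n-c_a}{g}/\binom{2n}{g}]\), with `g`
  taken as twice the smallest per-population complete sample at the
  locus;
* the exact conditional Hardy-Weinberg test with probability ordering:
  the p-value is the summed conditional probability of genotype arrays
  no more probable than the observed one. Arrays are enumerated
  exhaustively when the space is small (attempted for up to three
  alleles, capped at 10^6 arrays); otherwise arrays are sampled by
  random pairing of the gene vector, which draws from exactly the
  conditional law (10^5 replicates by default, seeded);
* linkage disequilibrium by a log-likelihood-ratio G statistic on the
  genotype-by-genotype table with a seeded permutation null
  (10^4 permutations by default);
* Weir-Cockerham variance-component estimators θ (FST) and f (FIS),
  multi-locus values as ratios of summed components;
* the null-allele frequency by EM under the model where a null allele
  of frequency `r` makes visible homozygotes of probability
  \(p_i^2 + 2p_ir\) and whole-genotype failures of probability
  \(r^2\); the EM trace is returned and is monotone non-decreasing in
  the observed-data likelihood (asserted per step in tests);
* Holm's sequential Bonferroni correction, applied per family: HWE
  over locus-by-population pairs, LD over locus pairs within
  populations.

Missing data are handled by pairwise-complete deletion per statistic;
nothing is imputed.

## Panels and their comparison

`detectSNI()` flags a locus when its allele sizes are not all
congruent modulo the motif length — a single +1 bp allele breaks the
ladder. `buildPanels()` then constructs:

* **SNI** — all flagged loci;
* **MP** — the top-`k` (default 8) non-SNI loci by allele number,
  including every locus tied at the cut (the packaged marker table
  produces exactly a four-way tie at 11 alleles filling ranks 5-8);
* **SS** — loci that amplified in every individual, show no SNI, have
  unambiguous electropherogram peaks (an input flag: peak quality is
  genotyping metadata and cannot be computed from allele calls), and
  are not Hardy-Weinberg deviant. The deviance criterion defaults to
  *deviant in every surveyed population*: on the packaged table this
  reproduces the published SS membership, which retains a locus
  flagged in one of the two populations; the stricter any-population
  reading is available as `hweExclude = "any"`;
* **ALL** — every profiled locus.

Every inclusion and exclusion is recorded with its rule, and
construction is deterministic and idempotent.

`assignIndividuals()` replaces Bayesian MCMC clustering with
leave-one-out likelihood assignment: per-population allele frequencies
are recomputed excluding the focal individual (zero frequencies
smoothed to \(1/(2n+1)\)), the multilocus genotype log-likelihood is
computed under Hardy-Weinberg proportions, and the normalized
likelihoods serve as membership coefficients Q, scored correct at the
conventional 0.60 threshold. This gives the per-individual membership
probabilities the Q-threshold evaluation needs without an MCMC
dependency; it ignores admixture priors, so its absolute Q values are
not comparable to clustering posteriors, only its ranking behaviour
is used. Panel comparisons use a two-sided Mann-Whitney test, exact
by complete enumeration of rank splits (ties handled exactly) when
the combined sample is at most 14, the normal approximation with tie
correction otherwise. PCA operates on centered allele-indicator
counts with locus-mean imputation of missing genotypes and a
deterministic sign convention (largest-magnitude loading positive).

```{r panels-demo}
prof <- wftMarkerLoci()
buildPanels(prof)
```

## The synthetic generators

`simulateGenome()` plants perfect or imperfect repeats (with mismatch
offsets constrained to be interior and at least one seed length apart,
so planted truth is exact) in rejection-sampled random background that
contains no unplanted reportable locus; junction bases are chosen to
break periodicity so planted coordinates are recovered exactly.
`simulateGenotypes()` draws two-population diploid data: ancestral
frequencies Dirichlet(1, ..., 1) over 4-17 allele sizes on a
motif-length ladder starting at 150 bp, population frequencies from
the Balding-Nichols model at a target FST, genotypes under
Hardy-Weinberg proportions, with optional null alleles (hiding one
copy or the whole genotype), off-ladder +1 bp SNI alleles, and random
missingness applied after the null-allele logic so the two causes of
absence stay distinguishable in the truth record.

Default generator conditions mirror the empirical design the package
emulates: cohorts of 23 + 24 individuals, 30 loci of 4-17 alleles on
tri-/tetranucleotide ladders, 2% missing data. The default
differentiation parameter is 0.05 — a realistic value for conspecific
populations sampled tens of kilometres apart — and recovery tests use
an explicit 0.10. Balding-Nichols was chosen over coalescent
simulation because it gives a closed-form differentiation target with
no external simulator. What the generators do *not* emulate: stepwise
mutation dynamics, allele-size homoplasy, linkage, genotyping error
beyond the modelled null/SNI/missing processes, and real flanking
sequence composition. Passing recovery tests therefore demonstrate
estimator correctness under the stated models, not robustness to
every artefact of real electropherograms.

## Numerical choices and problem sizes

Convergence of the null-allele EM is declared at |Δr| < 10⁻⁶ (at most
10⁴ iterations; non-convergence is an error carrying the last
iterate). Exact-test ties in probability ordering are compared with a
10⁻⁹ log-tolerance. Permutation p-values use the (hits+1)/(reps+1)
estimator. The test suite sizes its simulations to what the checked
property needs: 1,000 equilibrium loci for the HWE type-I error rate,
20 seeds of 20 loci × 100 individuals for θ recovery at FST 0.10,
n = 200 for null-allele recovery at r = 0.2, 300 cohorts for SNI
detection power, and 100 replicate pools for the polymorphism
ascertainment-bias property; these sizes give comfortable margins for
the stated tolerances while keeping the default run fast.

## Known limitations

* The scanner is defined by its own explicit semantics, validated
  against an exhaustive oracle — not guaranteed to be bit-identical
  to any published scanning binary, whose seed/extension internals
  are undocumented; genome-wide totals from real assemblies will
  differ at the margins (merge/split decisions for gapped repeats).
* The primer picker checks composition constraints only — no
  specificity screening, hairpin/dimer checks, or tail chemistry.
* Assignment is leave-one-out maximum likelihood, not Bayesian
  admixture clustering; no ΔK-style model selection is provided.
* FST-outlier scanning and bootstrap confidence intervals over loci
  are out of scope.
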