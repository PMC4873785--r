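# ssrforge

Genome-wide microsatellite discovery and stringent marker-panel
selection for population genetics.

Microsatellites (simple sequence repeats, SSRs) remain the workhorse
codominant marker for population-genetic studies of non-model
organisms, and draft genomes make it possible to pick a handful of
markers from tens of thousands of candidates. Which ones to pick is
the hard part: the most polymorphic loci inflate diversity estimates,
loci with single-nucleotide insertions (SNI) are hard to bin, and
loci that fail to amplify or deviate from Hardy-Weinberg equilibrium
(HWE) degrade assignment. `ssrforge` implements the full workflow —
discovery, characterization, candidate filtering, per-locus
evaluation, and panel construction/comparison — with synthetic
ground-truth generators so every stage is testable offline.

## What it computes

* **Discovery** — a fixed-penalty scan of 1–6 bp motifs:
  `score = length − penalty × mismatches`, reported when
  `score ≥ 15` (penalty 5), so any locus under 20 bp is perfect by
  construction. Motifs are canonicalized over cyclic rotation and
  reverse complement (`GA`, `CT`, `TC` → `AG`). Validated
  record-for-record against an exhaustive oracle.
* **Characterization** — relative abundance (loci/Mb), relative
  density (Kb/Mb), motif ranking, length and mismatch spectra.
* **Candidate filtering** — tri-/tetranucleotide motifs, > 7 repeat
  units, perfect only, nearest-neighbor-Tm primer design (18–24 bp,
  58–62 °C, ΔTm < 4 °C), 3′ ends > 10 bp from the repeat,
  single-target amplicons; every failure is audited by rule.
* **Evaluation** — Ho, Nei's unbiased He, rarefied allelic richness,
  exact HWE test (enumeration or conditional Monte Carlo), permutation
  LD test, Weir–Cockerham θ (FST) and f (FIS), null-allele EM, Holm
  sequential Bonferroni.
* **Panels** — MP (top-8 non-SNI by allele count, ties kept), SNI,
  SS (fully amplifying, SNI-free, HWE-conforming, clean peaks), ALL;
  leave-one-out likelihood assignment with the 0.60 Q-threshold;
  Mann–Whitney panel comparisons; PCA.
* **Simulation** — genomes with planted repeats and Balding–Nichols
  two-population genotype datasets with null alleles, SNI alleles and
  missing data.

## Worked example

```r
library(ssrforge)

sim <- simulateGenome(list(list(motif = "AGC", units = 12)),
                      scaffoldLength = 2000, gcContent = 0.45,
                      seed = 21)
scanGenome(sim$genome)
#>   sequence_id start  end motif length mismatches score perfect
#> 1  scaffold01   983 1018   AGC     36          0    36    TRUE

audit <- stringentFilter(makeContexts(scanGenome(sim$genome),
                                      sim$genome))
audit[, c("motif", "repeats", "passed", "forward_tm", "product_size")]
#>   motif repeats passed forward_tm product_size
#> 1   AGC      12   TRUE    59.9749          171
```

A perfect 12-unit AGC repeat (36 bp, score 36) passes every candidate
rule; the chosen primer pair sits at ~60 °C and amplifies a 171 bp
single-target product. The packaged 30-locus marker table for the
western flower thrips reconstructs the published panels:

```r
buildPanels(wftMarkerLoci())
#> PanelSet
#>   MP  ( 8): wft4-S32, wft3-S01, wft4-S57, wft4-S58, wft3-S21, ...
#>   SNI ( 8): wft4-S22, wft3-S27, wft3-S28, wft4-S30, wft3-S33, ...
#>   SS  ( 8): wft3-S08, wft4-S09, wft4-S13, wft3-S14, wft3-S43, ...
#>   ALL (30): wft3-S01, wft3-S03, wft3-S06, wft3-S08, wft4-S09, ...
```

A thin CLI over the same functions is at
`inst/scripts/ssrforge.R` (subcommands `scan`, `profile`,
`candidates`, `simulate-genome`, `simulate-genotypes`, `popgen`,
`panels`).

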