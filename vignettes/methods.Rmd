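---
title: "Methods: allele-specific expression of an exon-skipped isoform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression of an exon-skipped isoform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseskip)
```

## The question the pipeline answers

A diploid tumor heterozygous for a splice-disrupting lesion can still express
the aberrant isoform almost exclusively, if transcription favors the lesioned
haplotype. Detecting that requires tying together three measurements on the
same gene: (i) which SNV sites are *germline heterozygous* (from DNA), (ii)
whether RNA at those sites is *allelically imbalanced*, and (iii) how much of
the transcript pool *skips the cassette exon* (from junction reads). This
package implements each step as a small, testable operation on tidy tables
and chains them in `run_pipeline()`.

## Models and assumptions

**Zygosity.** At a site with `ref` and `alt` read counts from DNA, the
alternate-allele fraction is `f_D = alt/(ref+alt)`. A germline heterozygote
should sit near 1:1; we quantify "near" as `f_D` inside a window
(default `[0.2, 0.8]`) *and* non-rejection of an exact binomial test of
`alt ~ Binomial(ref+alt, 0.5)` at `alpha = 0.001`. The window guards against
high-depth sites where trivial deviations become "significant"; the test
guards against low-depth sites where the window alone is noise. Homozygous
calls require `f_D < 0.02` (or `> 0.98`), tolerating stray error bases;
everything else, including sites under 14 informative reads, is ambiguous.
When a matched normal is available, `run_pipeline()` genotypes from the
normal DNA (germline by construction); otherwise tumor DNA is used and the
report records the caveat.

**Allelic imbalance.** The RNA alternate fraction `f_R` at heterozygous
sites is the core readout. "Close to 0% or 100%" becomes: exact binomial
p-value against 0.5, Benjamini–Hochberg adjustment *within the sample* (the
unit of the per-sample panels a practitioner inspects), and a verdict of
imbalanced only when `q < 0.05` **and** `|f_R − 0.5| ≥ 0.15`. The effect
floor exists because at RNA depths of hundreds of reads, biologically
irrelevant deviations (e.g. 53%) reject the point null. The exact binomial
two-sided p is the minimum-likelihood ("minlike") convention — the summed
probability of all outcomes no likelier than the observed one — which at a
0.5 null reduces to `min(1, 2·P(X ≤ min(k, n−k)))`; we state the convention
explicitly because two-sided exact tests differ between implementations.

Pooling across sites sums ref/alt counts. The sites of one gene lie on a
single haplotype pair, but phase between sites is *not* inferred — allele
labels (ref/alt) are per site, so the pooled fraction is interpretable as
"non-reference fraction", not "haplotype fraction", exactly like the per-site
values. The sample verdict requires both the pooled test to reject and at
least half the informative sites to be individually imbalanced; the pooled
p-value is a single test, so no further adjustment is applied to it. No
overdispersion (beta-binomial) term is fitted by default: a single gene
offers too few sites to estimate a dispersion, and the ratio-based procedure
this formalizes uses none.

**Percent skipping.** For a cassette exon with inclusion junctions counting
`I₁` (upstream→cassette) and `I₂` (cassette→downstream) and exclusion
junction counting `E` (upstream→downstream), `ψ_skip = E / (E + (I₁+I₂)/2)`.
The flank mean is the standard two-junction averaging of junction-based
splicing quantifiers; exon-body reads are ignored because only
junction-spanning reads identify the isoform unambiguously. A read supports
a junction only if its alignment gap matches the donor/acceptor coordinates
exactly with ≥ 6 aligned bases on each side; `ψ_skip` is reported only when
total junction support reaches 10 reads.

**Tumor vs normal.** Per shared site, Fisher's exact test on the
(alt, ref) × (tumor, normal) table; the tumor-specific flag is deliberately
simple — tumor imbalanced and normal balanced — because that conjunction is
the scientific claim of interest.

**Viability.** Day-8 luminescence is divided by the mean of the four Day-0
technical replicates of the same line *and biological replicate* (each
biological replicate is plated and measured on its own Day-0 plate). Group
comparisons use a Mann–Whitney test with midranks; the two-sided p doubles
the smaller tail (capped at 1) and is exact — computed by
dynamic-programming enumeration of the rank-sum distribution over all
labelings, ties included — up to a combined n of 20, with a tie-corrected
normal approximation beyond. By default all normalized technical replicates
enter the test (mirroring per-well plotting); `aggregate = "biological"`
averages to biological replicates first for a conservative alternative.

## What the generator emulates — and what it does not

`sim_truth()` holds the generative parameters; its defaults are the study
conditions the package targets: germline heterozygosity `θ_D = 0.5`,
whole-exome-like DNA depth 80×, RNA depth 150× (junction coverage follows
RNA depth), Illumina-like substitution error `ε = 0.001`, and balanced
expression / no skipping unless configured. Depths are Poisson per site (the
simplest parameter-recoverable count model); the alternate-read count is
binomial with error-adjusted success probability
`θ(1−ε) + (1−θ)·ε/3` (errors substitute uniformly to the three other
bases); junction reads are a haplotype mixture with exclusion fraction
`θ_R·ψ_alt + (1−θ_R)·ψ_ref`, each isoform covering its own junction(s) at
the configured junction depth. `simulate_alignments()` realizes the same
model as spliced single-end SAM reads (skipping encoded as `N` CIGAR gaps)
plus a truth VCF and JSON sidecar, so the pileup and junction-extraction
code paths are exercised end to end.

The default `example_gene_model()` places its eight SNV sites in
constitutive exons only, so per-site RNA depth does not depend on the
skipping rate and pooled fractions estimate `θ_R` directly; sites inside the
cassette exon would couple the two, which is realistic but conflates the
quantities the tests are calibrating.

Deliberately *not* emulated: paired-end inserts and fragment-length
distributions, mapping bias and reference bias, indels, copy-number change,
and overdispersed (beta-binomial) allele counts. Passing recovery tests on
this generator therefore demonstrates the statistics and the plumbing are
correct under the stated model — not that real tumor data are free of
mapping bias or overdispersion, which typically widen allele-fraction
spread beyond binomial.

## Numerical choices and edge cases

- Coordinates are 0-based half-open for exon/junction arithmetic and 1-based
  at every SAM/VCF/table boundary, matching the formats' own conventions.
- Zero-depth sites are records, not errors: ambiguous in genotyping,
  insufficient in imbalance testing.
- The alt base at a site defaults to the most frequent non-reference base;
  exact ties go to the lexicographically smallest base and are flagged.
- Bases other than a site's ref/alt (sequencing noise, third alleles) are
  excluded from `f_R`'s denominator and reported as `noise_count`.
- A discrete exact test is conservative: its attained size at nominal
  `alpha = 0.05` is strictly below 0.05 at finite depth (about 0.041 when
  depth is Poisson with mean 150, by direct enumeration of the rejection
  region). The null-calibration rate reported by `scripts/acceptance.R`
  reflects this; it is a property of exact binomial tests, not a
  miscalibration.
- `rank_sum_test()` keeps midranks integral by doubling ranks before the
  subset-sum enumeration, so tied exact p-values are computed without
  floating-point accumulation.
- Determinism: all simulation draws run under `withr::with_seed(truth$seed)`;
  identical truth objects give byte-identical count tables, SAM text, VCF
  and JSON sidecars.

## Design decisions that were genuinely open

- *Thresholds.* No numeric heterozygosity window, depth cutoff, or imbalance
  criterion is inherent to the ratio-reading procedure this formalizes; the
  defaults (window `[0.2, 0.8]`, `min_depth = 14`, candidate-scan minor
  fraction 0.2, effect floor 0.15, `min_overhang = 6`, `min_total = 10`)
  follow common allele-specific-expression and junction-quantification
  practice and are all exposed as arguments and pipeline `params`.
- *Read filtering.* Duplicates, secondary and supplementary alignments are
  excluded; base and mapping quality thresholds default to 20. Browser-based
  inspection has no explicit thresholds, so these are this package's
  choices.
- *Interface shape.* Counts and results are plain tibbles so the pipeline
  composes with dplyr; the one structured object (`tn_contrast`) carries
  `tidy()`/`glance()`/`autoplot()` methods. `run_pipeline()` plus a thin
  Rscript wrapper (`inst/scripts/run_pipeline.R`) serve as the batch
  interface.

## Problem sizes used by the test-suite

The suite favors many small, seeded simulations: oracle-equivalence checks
use ≥ 100 randomized fixtures per statistic; null calibration uses 10,000
simulated balanced sites; parameter recovery uses 500 replicate simulations
of 8 sites at RNA depth 150 (junction depth 300 for ψ); distributional
round-trips between the count-table and alignment generators use 12
replicate libraries at reduced depth. These sizes give Monte-Carlo standard
errors small enough for 3-SE assertions while keeping the suite quick to
run.

## Known limitations

Single-gene, single-cassette scope; no phasing, so multi-site imbalance is
summarized per allele label, not per haplotype; no mapping-bias or
overdispersion correction; junction-only ψ ignores exon-body evidence;
count-based zygosity is not a full genotype-likelihood model and excludes
multi-allelic sites. These match the package's role: a focused, auditable
re-implementation of a targeted analysis, not a genome-wide caller.
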