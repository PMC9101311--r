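---
title: "Methods: measuring mutational signatures and selection in gut metagenomes"
author: "microvarsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring mutational signatures and selection in gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvarsig)
```

## The problem

Chemotherapeutic agents such as 5-fluorouracil and oxaliplatin reach the gut
at cytotoxic concentrations, and besides reshaping community composition they
mutagenise the resident microbes. Detecting that effect from shotgun
metagenomes requires a chain of steps, each with its own failure modes: a
non-redundant reference genome set (otherwise reads from one species call
spurious "variants" against close relatives), careful variant filtering
(metagenomic allele frequencies are intrinsically low), a substitution-
spectrum summary that can be compared between treatment groups, and a
selection analysis that separates mutational pressure from adaptive
consequence. microvarsig implements that chain, together with a synthetic
data generator that plants every quantity of interest, so each stage is
validated against known truth rather than against another pipeline.

## Reference dereplication

Genome pairs are compared by the median percent identity of their shared
single-copy marker genes (about 40 such genes exist in nearly all
prokaryotes), which is a cheap, robust proxy for average nucleotide identity.
Clustering thresholds this proxy at the operational species boundary of 95%.

Two choices are deliberately explicit because a flat partition from a
threshold underdetermines them:

* **Linkage.** Single linkage (connected components of the at-or-above-
  threshold graph) is the default: it is the only flat thresholding whose
  result does not depend on genome input order. Complete linkage is one flag
  away for sensitivity analysis.
* **Missing pairs.** Pairs with no shared marker identity stay undefined and
  contribute no edge — conservative non-merging.

Each cluster is represented by its highest-coverage member, ties broken to
the lexicographically smallest genome id for determinism.

## Variant classification and filtering

Size classes: single-base substitutions are SNPs; length differences of
1–50 bp are InDels (inclusive at 50); larger events are structural variants.
Equal-length multi-base substitutions are decomposed into per-base SNPs,
because the spectrum is defined over single-nucleotide events.

The filter thresholds are read literally: allele frequency strictly greater
than 1%, support strictly greater than five reads (so kept at ≥ 6), at
least one supporting read per strand for InDels, at least three supporting
reads for SVs. A genome enters downstream analyses only with at least three
kept SNPs; this rule is evaluated cohort-wide by default (a per-sample
option exists) because the data that motivated it pooled samples per genome.
All thresholds live in a single `paper_defaults` config block so that any
deviation is visible in the run manifest.

The false-positive rate is estimated inside single-copy marker gene regions.
On real data this relies on an invariant-site argument; on synthetic runs
the package computes the truth-based analogue — the fraction of kept
marker-region calls absent from the planted truth — and makes no claim of
reproducing any particular cohort value.

## Substitution spectra and shift tests

Spectra use the 12 ordered `ref>alt` classes (4 bases × 3 alternatives)
without reverse-complement collapsing; a strand-collapsed 6-class view is a
presentation option only. Rates are per kilobase of included reference
sequence; the denominator is the total length of genomes passing the
inclusion rule for the sample set, recorded in the output, because the
natural alternative (positions at sufficient depth) requires a depth track
that is not always available.

Group/timepoint shifts in transition rate, transversion rate, Ts/Tv or any
single-type rate are tested with the classic pooled-variance two-sample
Student t-test (Welch by flag), and all (comparison × metric) p-values
emitted in one run are Benjamini–Hochberg adjusted together — the adjustment
family is printed with the results since "adjusted p" is meaningless without
it. Comparisons are unpaired by default with a subject-paired option.

## Dn/Ds and positive selection

The per-family selection statistic is tree-free, pairwise, NG86-style — a
deliberate replacement for a maximum-likelihood codon-model chain
(alignment → tree → ML ω), whose external tooling is out of scope here.
Outputs are labelled "pairwise NG86-style" to avoid conflation with ML
estimates.

* `count_codon_changes()` averages synonymous/nonsynonymous step counts over
  all orderings of the differing positions (≤ 6 paths), discarding paths
  through stop codons; `dn + ds` equals the number of differing positions
  whenever any path survives.
* `count_sites()` classifies the nine single-nucleotide neighbours of each
  codon, excluding stop neighbours from the denominator; translation table
  11 (bacteria/archaea) throughout.
* `family_counts()` sums changes over all unordered sequence pairs and all
  codon columns gap-free in both sequences (gapped columns are skipped
  pairwise, standing in for low-confidence-position masking); site totals
  are averaged over sequences then summed over columns. Internally the
  pairwise sum is computed as a quadratic form over per-column codon-type
  counts, which is algebraically identical to pair enumeration and much
  faster.
* ω = (dn / N) / (ds / S); undefined (flagged, never infinite) when no
  synonymous changes are observed.

**Enrichment testing and pseudo-replication.** Each family is tested for
excess nonsynonymous changes against the pooled background with a one-sided
Fisher exact test, BH-adjusted at FDR 5%. Summed pairwise counts replicate
every underlying substitution up to `n_seqs − 1` times, so feeding raw sums
to an exact test would shrink its effective variance by an order of
magnitude and flag most neutral families. The test is therefore fed
*per-pair average* counts (rounded half away from zero; raw fractional sums
are preserved in the output). This choice is what makes the neutral
simulation behave: at ω = 1 across 200 families the flagged fraction stays
near zero, while families at ω ≥ 5 against an ω = 0.1 background are still
detected essentially always. The background excludes the focal family by
default (leave-one-out) to avoid self-contamination; inclusion is a flag.
Because "positively selected" can reasonably mean either the Fisher/FDR
criterion or above-mean Dn with below-mean Ds rates, both flags and their
conjunction are reported separately.

## Abundance, density, enrichment

Relative gene abundance is RPKM-like: `NG_i` = count / length, renormalised
to `RNG_i = NG_i / Σ NG_j` within each sample (sums to 1 within 1e-9;
all-zero samples are flagged, not silently NaN). Per-gene SNP density is
kept SNPs per kilobase of gene span, computed only where mean depth over the
gene is at least 10× (boundary inclusive; mean rather than median by
default, switchable). Paired day-0/day-30 density differences use the
Wilcoxon signed-rank test: zero differences dropped before ranking
(Wilcoxon's treatment; Pratt as option), midranks for ties, and an exact
two-sided p for up to 25 pairs computed by convolution over doubled
midranks — `stats::wilcox.test` cannot produce exact p-values with ties or
zeros, which these data always contain. Above 25 pairs a normal
approximation with tie-exact variance `Σr²/4` and continuity correction is
used. KO/pathway enrichment is the upper-tail hypergeometric test,
BH-adjusted across pathways.

## The synthetic-data generator

The generator is first-class, tested code; its defaults emulate the study
conditions the analysis stack is meant for:

* **Community**: a handful of genomes (demo: 6 genomes × 60 kb) with
  non-overlapping CDS gene models on both strands, gene lengths multiples of
  3, 40 single-copy marker genes per genome with marker slots comparable
  across genomes, and KO labels from a configurable pool.
* **Samples**: paired day-0/day-30 designs per drug group, mirroring a
  longitudinal chemotherapy cohort; subjects shared across timepoints.
* **SNPs**: positions uniform over the genome; the alternate allele is drawn
  from the condition's 12-type weights conditioned on the reference base
  (the three types with that source base, renormalised) — this guarantees
  reference consistency and honours the 12-type target marginally when base
  composition is uniform. The "oxaliplatin day 30" demo condition multiplies
  the eight transversion weights by 1.5.
* **Allele frequencies**: Beta(2, 8) by default — a low-frequency-skewed
  stand-in, since no published distribution exists for real metagenomic
  calls; tests that assert exact kept-versus-truth bookkeeping use
  Beta(5, 5) so that no legitimate call drifts below the 1% filter by
  chance and the comparison stays exact.
* **Read support**: Poisson totals with a binomial(total, 1/2) strand
  split; planted violations (allele frequency at 0.5%, support ≤ 5,
  single-strand InDels, SV support < 3) exercise every filter rule, and
  every planted call records whether it should survive the default policy.
* **Codon families**: sequences evolve independently from a stop-free
  common ancestor; proposals are uniform over the nine neighbours of a
  codon, stop-creating proposals are rejected, synonymous proposals are
  accepted with probability min(1, 1/ω) and nonsynonymous ones with
  min(1, ω). A literal "accept nonsynonymous with probability ω" cannot
  exceed 1; the symmetric min-rule reproduces site-normalised dN/dS = ω on
  both sides of 1, which the neutral-recovery and power tests confirm.
* **Identity matrices**: within-cluster marker identities strictly above,
  between-cluster strictly below, the 95% threshold; overlapping ranges are
  a configuration error, so planted partitions are recoverable exactly.

What the generator does **not** emulate: read-level sequencing error,
mapping ambiguity, assembly artefacts, strain mixtures within a species,
codon-usage bias, or recombination. Passing tests therefore demonstrate
correctness of the statistics and bookkeeping on well-specified input — not
robustness to upstream noise in real cohorts.

## Numerical and design notes

* Coordinates are 1-based inclusive everywhere (VCF/GFF3 convention).
* Exact tests: Fisher and hypergeometric p-values come from the exact
  hypergeometric tail; fractional change counts are integerised by rounding
  half away from zero only at the test boundary.
* Degenerate inputs return flagged `NA` or p = 1 rather than silent zeros:
  Ts/Tv with no transversions, ω with no synonymous changes, false-positive
  rate with an empty denominator, all-zero abundance samples, all-zero
  Wilcoxon differences, zero-margin Fisher tables.
* Determinism: every stage takes an explicit seed; the pipeline derives
  per-stage seeds from the run seed and records md5 checksums of every
  output in its manifest, so reruns are verifiably bit-identical.
* Problem sizes in the test-suite simulations (200 neutral families of 20 ×
  500 codons; 50-family power runs at 10 × 300; 20 vs 20 samples at ~1,100
  SNPs each; 12-genome dereplication matrices) were chosen as the smallest
  configurations at which the relevant asymptotics are comfortably reached;
  the acceptance script uses the same configurations.

## Known limitations

* Pairwise NG86-style counting underestimates divergence at high mutation
  loads (multiple hits per codon) and has no notion of phylogenetic
  dependence between sequences; the per-pair averaging guard corrects the
  test's variance, not the correlation structure itself.
* The marker-identity estimator bundled for synthetic genomes is a k-mer
  sketch, not an aligner; real identity tables should come from BLAST-class
  alignment.
* The spectrum denominator ignores per-position depth unless a depth track
  is supplied; absolute per-kb rates are therefore comparable within a run,
  not across studies.
* Cohort-scale headline values from real data (millions of SNPs, hundreds
  of genome clusters, specific adjusted p-values) depend on deep sequencing
  of hundreds of samples and thousands of reference genomes and are outside
  what the bundled synthetic configurations reproduce.
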