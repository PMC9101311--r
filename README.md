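# microvarsig

Within-species genomic variation in gut metagenomes: who is mutating, in
which direction, and under what selection pressure?

Chemotherapy drugs (and other mutagens) reaching the gut leave fingerprints
in the genomes of resident microbes. Reading those fingerprints from shotgun
metagenomes takes a chain of analyses, and `microvarsig` implements the whole
chain as a tested R package:

* **Reference dereplication** — per-pair median identity of ~40 universal
  single-copy marker genes as a proxy for average nucleotide identity (ANI),
  single-linkage clustering at the operational 95% species threshold, and
  coverage-based representative selection.
* **Variant handling** — VCF parsing, size classification (SNP / InDel 1–50 bp
  / SV >50 bp), the filter set *AF > 1%*, *support > 5 reads*, *≥1 read per
  strand for InDels*, *≥3 reads for SVs*, the *≥3 SNPs per genome* inclusion
  rule, and a marker-gene false-positive-rate estimate against simulation
  truth.
* **Mutational signatures** — per-sample spectra over the 12 ordered
  `ref>alt` substitution types, per-kilobase rates, transition/transversion
  aggregates, and Student-t group/timepoint shift tests with
  Benjamini–Hochberg adjustment.
* **Selection** — tree-free pairwise NG86-style Dn/Ds per KO gene family:
  path-averaged codon change counts, site normalisation
  ω = (Dn/N)/(Ds/S), one-sided Fisher enrichment against the pooled
  background, and BH FDR at 5%.
* **Abundance & density** — RPKM-like relative gene abundance
  (RNG<sub>i</sub> = NG<sub>i</sub>/ΣNG<sub>j</sub>, NG = count/length),
  per-gene SNP density under a ≥10× valid-coverage rule, exact paired
  Wilcoxon signed-rank density tests, and hypergeometric KO/pathway
  enrichment.
* **Synthetic data with planted truth** — genomes with gene models, variant
  sets drawn from condition-specific 12-type spectra (with planted filter
  violations), codon families evolved at known ω, and marker-identity
  matrices with planted clusters; every downstream result can be checked
  against what was planted.

All stages are deterministic under a seed; `run_pipeline()` ties them into a
single run whose manifest records per-stage counts and md5 checksums of every
output.

## Worked example

Run the bundled demo end to end (6 genomes in 4 planted clusters, two drug
groups × two timepoints × 4 subjects, planted filter violations, 12 codon
families of which 2 evolve at ω = 5 against an ω = 0.2 background):

```r
library(microvarsig)
cfg <- system.file("extdata", "demo_config.yaml", package = "microvarsig")
m <- run_pipeline(cfg, out_dir = "demo_out", seed = 1)
str(m$counts)
#> $ genomes          : int 6
#> $ clusters         : int 4        # planted 2+2+1+1 recovered
#> $ planted_calls    : int 8755
#> $ calls_kept       : int 7783     # equals the planted expect_kept count
#> $ calls_rejected   : int 972
#> $ genomes_passing  : int 4
#> $ families         : int 12
#> $ families_positive: int 2        # exactly the two planted omega = 5 families
m$false_positive_rate
#> [1] 0                             # no errors injected, none found
```

The selection table ranks families by FDR-adjusted enrichment of
nonsynonymous changes; the two planted positives surface with ω ≈ 4 and
q < 0.001 while the ω = 0.2 background stays flat:

```r
head(read.delim("demo_out/selection.tsv"), 3)
#>    ko_id dn_changes ds_changes omega  q_value positive true_omega
#> 1 K90001        456       36.5 4.339 0.000336     TRUE        5.0
#> 2 K90002        440       43.0 3.614 0.000957     TRUE        5.0
#> 3 K90004        112      153.5 0.254 0.979325    FALSE        0.2
```

The demo plants a 1.5× transversion-weight boost in the `Oxi` group at day
30; the shift tests pick it up as a drop in transition share and Ts/Tv:

```r
read.delim("demo_out/shift_tests.tsv")[4:6, c("comparison", "metric", "mean_a", "mean_b", "p_adjusted")]
#>           comparison  metric mean_a mean_b p_adjusted
#> 4 Oxi: day0 vs day30 ts_rate  0.634  0.484     0.0016
#> 5 Oxi: day0 vs day30 tv_rate  1.268  1.327     0.1827
#> 6 Oxi: day0 vs day30    tstv  0.500  0.366     0.0016
```

`vignettes/microvarsig-methods.Rmd` documents the models, parameter choices
and their rationale. A thin CLI over the same functions lives at
`inst/scripts/microvarsig.R` (`run` / `simulate` / `validate` subcommands).

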