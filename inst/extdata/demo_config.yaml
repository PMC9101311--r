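# Demo configuration: a small synthetic community sized to run end-to-end in
# seconds while exercising every pipeline stage.
seed: 1
community:
  n_genomes: 6
  genome_length: 60000
  n_genes_per_genome: 60
  n_marker_genes: 40
  gc_content: 0.45
clusters:
  sizes: [2, 2, 1, 1]
  within_range: [96, 99]
  between_range: [78, 90]
groups:
  - {group: FU, timepoint: day0, n_samples: 4}
  - {group: FU, timepoint: day30, n_samples: 4}
  - {group: Oxi, timepoint: day0, n_samples: 4}
  - {group: Oxi, timepoint: day30, n_samples: 4}
spectrum_weights:
  # order: A>C A>G A>T C>A C>G C>T G>A G>C G>T T>A T>C T>G
  default: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  # transversion weights x1.5 after 30 days of oxaliplatin
  "Oxi:day30": [1.5, 1, 1.5, 1.5, 1.5, 1, 1, 1.5, 1.5, 1.5, 1, 1.5]
variants:
  snp_rate: 2
  depth_mean: 60
  af_shape: [2, 8]
  frac_low_af: 0.05
  frac_low_support: 0.05
  indel_rate: 0.2
  frac_indel_single_strand: 0.1
  sv_rate: 0.05
  frac_sv_low_support: 0.2
selection:
  n_families: 12
  n_seqs: 8
  n_codons: 150
  subs_per_codon: 0.08
  omega: {default: 0.2}
  n_positive: 2
  positive_omega: 5
  background: loo
density:
  depth_mean: 60
  frac_low_depth: 0.1
paper_defaults:
  ani_threshold: 95
  min_af: 0.01
  min_support: 5
  sv_min_support: 3
  min_snps_per_genome: 3
  min_depth: 10
  alpha: 0.05
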