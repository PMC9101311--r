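# End-to-end orchestration: simulate -> dereplicate -> filter -> spectrum ->
# density/abundance -> Dn/Ds, with config validation, a run manifest and
# deterministic outputs under a fixed seed.

#' Default pipeline configuration
#'
#' All operational thresholds live in the `paper_defaults` block (95% ANI,
#' 1% allele frequency, >5 supporting reads, >=3 reads for SVs, >=3 SNPs per
#' genome, 10x valid coverage, FDR level 5%) so that deviations are visible
#' in the run manifest.
#'
#' @param seed Integer seed recorded in the config.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  tv <- setdiff(substitution_types(), transition_types())
  w_default <- stats::setNames(rep(1, 12), substitution_types())
  w_oxi <- w_default
  w_oxi[tv] <- 1.5
  list(
    seed = seed,
    community = list(n_genomes = 6, genome_length = 60000,
                     n_genes_per_genome = 60, n_marker_genes = 40,
                     gc_content = 0.45),
    clusters = list(sizes = c(2, 2, 1, 1), within_range = c(96, 99),
                    between_range = c(78, 90)),
    groups = data.frame(
      group = rep(c("FU", "Oxi"), each = 2),
      timepoint = rep(c("day0", "day30"), 2),
      n_samples = rep(4, 4), stringsAsFactors = FALSE),
    spectrum_weights = list(default = as.list(w_default),
                            `Oxi:day30` = as.list(w_oxi)),
    variants = list(snp_rate = 2, depth_mean = 60, af_shape = c(2, 8),
                    frac_low_af = 0.05, frac_low_support = 0.05,
                    indel_rate = 0.2, frac_indel_single_strand = 0.1,
                    sv_rate = 0.05, frac_sv_low_support = 0.2),
    selection = list(n_families = 12, n_seqs = 8, n_codons = 150,
                     subs_per_codon = 0.08,
                     omega = list(default = 0.2),
                     n_positive = 2, positive_omega = 5,
                     background = "loo"),
    density = list(depth_mean = 60, frac_low_depth = 0.1),
    paper_defaults = list(ani_threshold = 95, min_af = 0.01,
                          min_support = 5, sv_min_support = 3,
                          min_snps_per_genome = 3, min_depth = 10,
                          alpha = 0.05)
  )
}

.known_config_keys <- c("seed", "community", "clusters", "groups",
                        "spectrum_weights", "variants", "selection",
                        "density", "paper_defaults")

#' Validate a pipeline configuration
#'
#' Checks field presence, types and ranges before any stage runs. Unknown
#' top-level keys give a warning (forward compatibility), not an error.
#'
#' @param config Configuration list, or path to a YAML file.
#' @return data.frame of violations (`field`, `value`, `constraint`); zero
#'   rows means the configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not readable: ", config)
    config <- yaml::read_yaml(config)
  }
  v <- list()
  bad <- function(field, value, constraint) {
    v[[length(v) + 1L]] <<- data.frame(
      field = field, value = paste(format(value), collapse = ","),
      constraint = constraint, stringsAsFactors = FALSE)
  }
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown) > 0) {
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  }
  chk_num <- function(field, value, lo = -Inf, hi = Inf,
                      lo_open = FALSE, hi_open = FALSE) {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L ||
        is.na(value) ||
        (if (lo_open) value <= lo else value < lo) ||
        (if (hi_open) value >= hi else value > hi)) {
      bad(field, value %||% "<missing>",
          sprintf("numeric in %s%s, %s%s", if (lo_open) "(" else "[",
                  lo, hi, if (hi_open) ")" else "]"))
    }
  }
  for (block in c("community", "groups", "spectrum_weights",
                  "paper_defaults")) {
    if (is.null(config[[block]])) bad(block, "<missing>", "required block")
  }
  cm <- config$community
  if (!is.null(cm)) {
    chk_num("community.n_genomes", cm$n_genomes, 1)
    chk_num("community.genome_length", cm$genome_length, 1000)
    chk_num("community.n_genes_per_genome", cm$n_genes_per_genome, 1)
    chk_num("community.n_marker_genes", cm$n_marker_genes, 0)
    chk_num("community.gc_content", cm$gc_content, 0, 1,
            lo_open = TRUE, hi_open = TRUE)
    if (is.numeric(cm$n_marker_genes) && is.numeric(cm$n_genes_per_genome) &&
        length(cm$n_marker_genes) == 1L &&
        length(cm$n_genes_per_genome) == 1L &&
        cm$n_marker_genes > cm$n_genes_per_genome) {
      bad("community.n_marker_genes", cm$n_marker_genes,
          "<= community.n_genes_per_genome")
    }
  }
  sw <- config$spectrum_weights
  if (!is.null(sw)) {
    if (is.null(sw$default)) {
      bad("spectrum_weights.default", "<missing>",
          "default weight vector required")
    }
    for (key in names(sw)) {
      w <- unlist(sw[[key]])
      if (length(w) != 12L || any(!is.finite(w)) || any(w < 0) ||
          sum(w) <= 0) {
        bad(paste0("spectrum_weights.", key), w,
            "12 non-negative weights with positive sum")
      }
    }
  }
  pd <- config$paper_defaults
  if (!is.null(pd)) {
    chk_num("paper_defaults.ani_threshold", pd$ani_threshold, 0, 100)
    chk_num("paper_defaults.min_af", pd$min_af, 0, 1, hi_open = TRUE)
    chk_num("paper_defaults.min_support", pd$min_support, 0)
    chk_num("paper_defaults.sv_min_support", pd$sv_min_support, 0)
    chk_num("paper_defaults.min_snps_per_genome", pd$min_snps_per_genome, 0)
    chk_num("paper_defaults.min_depth", pd$min_depth, 0)
    chk_num("paper_defaults.alpha", pd$alpha, 0, 1, lo_open = TRUE)
  }
  vr <- config$variants
  if (!is.null(vr)) {
    chk_num("variants.snp_rate", vr$snp_rate, 0)
    for (f in c("frac_low_af", "frac_low_support",
                "frac_indel_single_strand", "frac_sv_low_support")) {
      if (!is.null(vr[[f]])) chk_num(paste0("variants.", f), vr[[f]], 0, 1)
    }
  }
  cl <- config$clusters
  if (!is.null(cl) && !is.null(cl$within_range) &&
      !is.null(cl$between_range)) {
    wr <- unlist(cl$within_range)
    br <- unlist(cl$between_range)
    if (length(wr) == 2L && length(br) == 2L && wr[1] <= br[2]) {
      bad("clusters.within_range", wr,
          "must lie strictly above clusters.between_range")
    }
  }
  if (length(v) == 0L) {
    return(data.frame(field = character(), value = character(),
                      constraint = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

as_groups_df <- function(groups) {
  if (is.data.frame(groups)) return(groups)
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$group, timepoint = g$timepoint,
               n_samples = g$n_samples, stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages in dependency order: genome/community simulation, marker-identity
#' simulation, dereplication, variant simulation and VCF round-trip,
#' filtering and genome inclusion, substitution spectra and shift tests,
#' per-gene SNP density with paired tests and KO enrichment, RPKM-like
#' abundance, codon-family Dn/Ds with positive-selection flags, and
#' marker-region false-positive-rate estimation against the planted truth.
#' All outputs are written under `out_dir`; a JSON manifest records the
#' config, seed, per-stage record counts and md5 checksums of every output,
#' so a rerun with the same seed can be verified bit-identical.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param out_dir Output directory (created; existing files overwritten).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (nrow(viol) > 0) {
    stop("invalid configuration:\n",
         paste(sprintf("  %s = %s (%s)", viol$field, viol$value,
                       viol$constraint), collapse = "\n"))
  }
  seed <- seed %||% config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8L)
  pd <- config$paper_defaults
  policy <- filter_policy(min_af = pd$min_af, min_support = pd$min_support,
                          sv_min_support = pd$sv_min_support,
                          min_snps_per_genome = pd$min_snps_per_genome)
  counts <- list()
  paths <- character(0)
  add_path <- function(p) paths <<- c(paths, p)

  # stage 1: community
  cm <- config$community
  genomes <- simulate_genomes(
    n_genomes = cm$n_genomes, genome_length = cm$genome_length,
    n_genes_per_genome = cm$n_genes_per_genome,
    n_marker_genes = cm$n_marker_genes, gc_content = cm$gc_content,
    seed = stage_seed[1])
  add_path(write_genomes_fasta(genomes, file.path(out_dir, "genomes.fna")))
  add_path(write_gene_models(genomes, file.path(out_dir, "genes.gff3")))
  counts$genomes <- length(genomes$sequences)
  counts$genes <- nrow(genomes$genes)

  # stage 2: marker identity + dereplication
  cl <- config$clusters
  sizes <- unlist(cl$sizes)
  if (sum(sizes) != cm$n_genomes) {
    stop("clusters.sizes must sum to community.n_genomes")
  }
  plan <- split(names(genomes$sequences),
                rep(seq_along(sizes), times = sizes))
  sim_id <- simulate_identity_matrix(
    plan, n_markers = cm$n_marker_genes,
    within_range = unlist(cl$within_range),
    between_range = unlist(cl$between_range), seed = stage_seed[2])
  add_path(write_tsv(sim_id$identities,
                     file.path(out_dir, "marker_identity.tsv")))
  ani <- compute_ani_proxy(sim_id)
  set.seed(stage_seed[3])
  coverage <- stats::setNames(stats::runif(cm$n_genomes, 1, 100),
                              names(genomes$sequences))
  add_path(write_tsv(data.frame(genome_id = names(coverage),
                                coverage = unname(coverage)),
                     file.path(out_dir, "coverage.tsv")))
  clusters <- select_representatives(
    cluster_genomes(ani, threshold = pd$ani_threshold), coverage)
  add_path(write_cluster_tsv(clusters, file.path(out_dir, "clusters.tsv")))
  counts$clusters <- length(clusters$clusters)
  counts$representatives <- length(clusters$representative)

  # stage 3: variant simulation on the representative genomes + VCF round-trip
  reps <- sort(unname(clusters$representative))
  ref_seqs <- genomes$sequences[reps]
  sheet <- build_sample_sheet(as_groups_df(config$groups))
  add_path(write_sample_metadata(sheet, file.path(out_dir, "samples.tsv")))
  vr <- config$variants
  sw <- lapply(config$spectrum_weights, function(w) {
    w <- unlist(w)
    if (is.null(names(w)) || !any(nzchar(names(w)))) {
      names(w) <- substitution_types()
    }
    w
  })
  sim_var <- simulate_variant_sets(
    ref_seqs, sheet, sw,
    snp_rate = vr$snp_rate, af_shape = unlist(vr$af_shape) %||% c(2, 8),
    depth_mean = vr$depth_mean %||% 60,
    frac_low_af = vr$frac_low_af %||% 0,
    frac_low_support = vr$frac_low_support %||% 0,
    indel_rate = vr$indel_rate %||% 0,
    frac_indel_single_strand = vr$frac_indel_single_strand %||% 0,
    sv_rate = vr$sv_rate %||% 0,
    frac_sv_low_support = vr$frac_sv_low_support %||% 0,
    seed = stage_seed[4])
  vcf_dir <- file.path(out_dir, "vcf")
  vcf_paths <- write_sample_vcfs(sim_var, vcf_dir)
  for (p in vcf_paths) add_path(p)
  add_path(write_sim_truth(sim_var, file.path(out_dir, "sim_truth.json")))
  counts$planted_calls <- nrow(sim_var$calls)

  # stage 4: read back + filter
  calls <- do.call(rbind, lapply(names(vcf_paths), function(s) {
    read_variant_calls(vcf_paths[[s]], sample_id = s)
  }))
  flt <- filter_variants(calls, policy)
  add_path(write_tsv(flt$rejected[, c("sample_id", "genome_id", "pos",
                                      "ref_allele", "alt_allele", "vtype",
                                      "reason")],
                     file.path(out_dir, "rejected_calls.tsv")))
  add_path(write_tsv(flt$kept, file.path(out_dir, "kept_calls.tsv")))
  counts$calls_read <- nrow(calls)
  counts$calls_kept <- nrow(flt$kept)
  counts$calls_rejected <- nrow(flt$rejected)
  included <- genomes_passing(flt$kept, policy)
  counts$genomes_passing <- length(included)

  # stage 5: spectra + shift tests
  glen <- sim_var$genome_lengths[included]
  kept_inc <- flt$kept[flt$kept$genome_id %in% included, , drop = FALSE]
  spectra <- tally_spectra(kept_inc, glen, sample_ids = sheet$sample_id)
  add_path(write_tsv(spectra, file.path(out_dir, "spectra.tsv")))
  shift <- compare_groups(spectra, sheet)
  add_path(write_tsv(shift, file.path(out_dir, "shift_tests.tsv")))
  counts$shift_tests <- nrow(shift)

  # stage 6: density + paired tests + enrichment (on representative genomes)
  genes_rep <- genomes$genes[genomes$genes$genome_id %in% included, ,
                             drop = FALSE]
  set.seed(stage_seed[5])
  dn <- config$density
  depth <- matrix(stats::rpois(nrow(genes_rep) * nrow(sheet),
                               dn$depth_mean %||% 60),
                  nrow(genes_rep), nrow(sheet),
                  dimnames = list(genes_rep$gene_id, sheet$sample_id))
  n_low <- round((dn$frac_low_depth %||% 0) * length(depth))
  if (n_low > 0) {
    depth[sample.int(length(depth), n_low)] <-
      sample.int(pd$min_depth, n_low, replace = TRUE) - 1L
  }
  dens <- snp_density(genes_rep, kept_inc, depth, min_depth = pd$min_depth,
                      genome_lengths = sim_var$genome_lengths)
  add_path(write_tsv(dens, file.path(out_dir, "density.tsv")))
  mats <- density_by_timepoint(dens, sheet)
  dtest <- paired_density_test(mats$a, mats$b)
  add_path(write_tsv(dtest, file.path(out_dir, "density_tests.tsv")))
  counts$genes_density_tested <- nrow(dtest)
  pathways <- simulate_ko_pathways(genomes$ko_pool, seed = stage_seed[6])
  add_path(write_tsv(pathways, file.path(out_dir, "pathways.tsv")))
  sig_genes <- dtest$gene_id[dtest$p_adjusted < pd$alpha]
  sig_kos <- unique(genes_rep$ko_id[genes_rep$gene_id %in% sig_genes])
  bg_kos <- unique(genes_rep$ko_id)
  enr <- ko_enrichment(sig_kos, bg_kos, pathways, alpha = pd$alpha)
  add_path(write_tsv(enr, file.path(out_dir, "enrichment.tsv")))

  # stage 7: abundance
  set.seed(stage_seed[7])
  reads <- matrix(stats::rpois(nrow(genes_rep) * nrow(sheet),
                               genes_rep$length / 50),
                  nrow(genes_rep), nrow(sheet),
                  dimnames = list(genes_rep$gene_id, sheet$sample_id))
  ab <- gene_abundance(reads, stats::setNames(genes_rep$length,
                                              genes_rep$gene_id))
  rng_df <- cbind(data.frame(gene_id = rownames(ab$rng),
                             stringsAsFactors = FALSE),
                  as.data.frame(ab$rng, check.names = FALSE))
  add_path(write_tsv(rng_df, file.path(out_dir, "abundance_rng.tsv")))

  # stage 8: codon families + Dn/Ds
  sel <- config$selection
  fam_kos <- sprintf("K%05d", 90000 + seq_len(sel$n_families))
  omega <- stats::setNames(rep(sel$omega$default %||% 0.2,
                               sel$n_families), fam_kos)
  npos <- min(sel$n_positive %||% 0, sel$n_families)
  if (npos > 0) omega[seq_len(npos)] <- sel$positive_omega %||% 5
  fams <- simulate_codon_families(
    omega, n_seqs = sel$n_seqs, n_codons = sel$n_codons,
    subs_per_codon = sel$subs_per_codon, seed = stage_seed[8])
  aln_dir <- file.path(out_dir, "alignments")
  for (p in write_codon_alignments(fams, aln_dir)) add_path(p)
  sel_res <- dnds_families(read_codon_alignments(aln_dir),
                           alpha = pd$alpha,
                           background = sel$background %||% "loo")
  sel_res$true_omega <- unname(omega[sel_res$ko_id])
  add_path(write_tsv(sel_res, file.path(out_dir, "selection.tsv")))
  counts$families <- nrow(sel_res)
  counts$families_positive <- sum(sel_res$positive)

  # stage 9: marker false-positive rate against planted truth
  mk <- genomes$marker_regions[genomes$marker_regions$genome_id %in%
                                 included, , drop = FALSE]
  fp <- suppressWarnings(
    estimate_false_positive_rate(kept_inc, mk, sim_var$calls))
  counts$fp_marker_calls <- attr(fp, "n_marker_calls")

  manifest <- list(
    tool = "microvarsig",
    version = as.character(utils::packageVersion("microvarsig")),
    seed = seed,
    config = config,
    counts = counts,
    false_positive_rate = if (is.na(fp)) NULL else as.numeric(fp),
    outputs = {
      rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
                 normalizePath(paths))
      stats::setNames(unname(tools::md5sum(paths)), rel)
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
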