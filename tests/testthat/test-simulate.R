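# Synthetic community, variant-set, and identity-matrix generators.

uniform_weights <- function() {
  list(default = stats::setNames(rep(1, 12), substitution_types()))
}

test_that("genome simulation is byte-deterministic under a fixed seed", {
  g1 <- simulate_genomes(n_genomes = 3, genome_length = 30000,
                         n_genes_per_genome = 40, n_marker_genes = 10,
                         seed = 1)
  g2 <- simulate_genomes(n_genomes = 3, genome_length = 30000,
                         n_genes_per_genome = 40, n_marker_genes = 10,
                         seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genomes_fasta(g1, file.path(d1, "g.fna"))
  write_genomes_fasta(g2, file.path(d2, "g.fna"))
  write_gene_models(g1, file.path(d1, "g.gff3"))
  write_gene_models(g2, file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fna")),
                   readLines(file.path(d2, "g.fna")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
})

test_that("gene models respect counts, bounds, frame and marker flags", {
  g <- simulate_genomes(n_genomes = 2, genome_length = 50000,
                        n_genes_per_genome = 60, n_marker_genes = 40,
                        seed = 2)
  for (gid in names(g$sequences)) {
    genes <- g$genes[g$genes$genome_id == gid, ]
    expect_equal(nrow(genes), 60)
    expect_equal(sum(genes$marker), 40)
    expect_true(all(genes$length %% 3 == 0))
    expect_true(all(genes$start >= 1 & genes$end <= 50000))
    # non-overlapping
    ord <- order(genes$start)
    expect_true(all(genes$start[ord][-1] > genes$end[ord][-60]))
  }
  # marker slot ids comparable across genomes
  expect_setequal(unique(g$genes$marker_id[g$genes$marker]),
                  sprintf("M%02d", 1:40))
  expect_error(simulate_genomes(genome_length = 1000,
                                n_genes_per_genome = 50),
               "too short")
})

test_that("base composition matches the requested GC content", {
  g <- simulate_genomes(n_genomes = 1, genome_length = 1e6,
                        n_genes_per_genome = 10, n_marker_genes = 5,
                        gc_content = 0.5, seed = 3)
  gc <- mean(strsplit(g$sequences[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)  # +-6 sigma binomial bound at n = 1e6
})

test_that("planted variants agree with the genome and the emitted VCF", {
  g <- simulate_genomes(n_genomes = 2, genome_length = 40000,
                        n_genes_per_genome = 30, n_marker_genes = 10,
                        seed = 4)
  sheet <- build_sample_sheet(data.frame(group = "X", timepoint = "day0",
                                         n_samples = 2))
  sim <- simulate_variant_sets(g, sheet, uniform_weights(), snp_rate = 3,
                               af_shape = c(5, 5), indel_rate = 0.2,
                               sv_rate = 0.05, seed = 5)
  # every ref allele equals the genome base(s) at its coordinate
  ref_obs <- substring(g$sequences[sim$calls$genome_id], sim$calls$pos,
                       sim$calls$pos + nchar(sim$calls$ref_allele) - 1L)
  expect_identical(unname(ref_obs), sim$calls$ref_allele)
  # VCF round-trip reproduces the planted calls
  dir <- withr::local_tempdir()
  paths <- write_sample_vcfs(sim, dir)
  back <- do.call(rbind, lapply(names(paths), function(s) {
    read_variant_calls(paths[[s]], s)
  }))
  expect_equal(nrow(back), nrow(sim$calls))
  key <- function(df) sort(paste(df$sample_id, df$genome_id, df$pos,
                                 df$ref_allele, df$alt_allele, df$vtype,
                                 df$support_total))
  expect_identical(key(back), key(sim$calls))
  # realized per-sample spectrum in truth equals a tally over the VCF SNPs
  glen <- stats::setNames(rep(40000, 2), names(g$sequences))
  for (s in sheet$sample_id) {
    sp <- tally_spectrum(back[back$sample_id == s, ], glen)
    expect_equal(unname(sp$counts),
                 as.numeric(sim$spectra[sim$spectra$sample_id == s,
                                        substitution_types()]))
  }
  # realized counts sum to the number of planted SNPs per sample
  expect_equal(rowSums(sim$spectra[, substitution_types()]),
               as.vector(table(sim$calls$sample_id[sim$calls$vtype == "SNP"])[
                 sim$spectra$sample_id]), ignore_attr = TRUE)
})

test_that("uniform spectrum weights give near-uniform realized shares", {
  g <- simulate_genomes(n_genomes = 1, genome_length = 200000,
                        n_genes_per_genome = 10, n_marker_genes = 5,
                        gc_content = 0.5, seed = 6)
  sheet <- build_sample_sheet(data.frame(group = "X", timepoint = "day0",
                                         n_samples = 1))
  sim <- simulate_variant_sets(g, sheet, uniform_weights(), snp_rate = 50,
                               seed = 7)
  shares <- as.numeric(sim$spectra[1, substitution_types()])
  shares <- shares / sum(shares)
  expect_gt(sum(shares > 0), 11)
  expect_true(all(abs(shares - 1 / 12) < 0.01))  # multinomial +-6 sigma
  # L1 spectrum recovery bound for >= 5000 planted SNPs
  expect_gte(sum(sim$spectra[1, substitution_types()]), 5000)
  expect_lte(sum(abs(shares - 1 / 12)), 0.03)
})

test_that("planted transversion boost lowers realized Ts/Tv", {
  g <- simulate_genomes(n_genomes = 1, genome_length = 100000,
                        n_genes_per_genome = 10, n_marker_genes = 5,
                        seed = 8)
  tv <- setdiff(substitution_types(), transition_types())
  w0 <- stats::setNames(rep(1, 12), substitution_types())
  w1 <- w0
  w1[tv] <- 1.5
  sheet <- build_sample_sheet(data.frame(group = "Oxi",
                                         timepoint = c("day0", "day30"),
                                         n_samples = c(1, 1)))
  sim <- simulate_variant_sets(g, sheet, list(default = w0,
                                              `Oxi:day30` = w1),
                               snp_rate = 20, seed = 9)
  tstv <- sapply(sheet$sample_id, function(s) {
    cnt <- as.numeric(sim$spectra[sim$spectra$sample_id == s,
                                  substitution_types()])
    sum(cnt[match(transition_types(), substitution_types())]) /
      sum(cnt[-match(transition_types(), substitution_types())])
  })
  expect_lt(tstv[["Oxi_day30_s01"]], tstv[["Oxi_day0_s01"]])
})

test_that("planted low-AF calls all fail the 1% filter", {
  g <- simulate_genomes(n_genomes = 1, genome_length = 50000,
                        n_genes_per_genome = 10, n_marker_genes = 5,
                        seed = 10)
  sheet <- build_sample_sheet(data.frame(group = "X", timepoint = "day0",
                                         n_samples = 1))
  sim <- simulate_variant_sets(g, sheet, uniform_weights(), snp_rate = 4,
                               frac_low_af = 0.2, seed = 11)
  low <- sim$calls[sim$calls$planted_violation == "low_af", ]
  expect_gt(nrow(low), 0)
  flt <- filter_variants(low)
  expect_equal(nrow(flt$kept), 0L)
  expect_true(all(flt$rejected$reason == "allele_frequency"))
})

test_that("all-zero weights for a present ref base raise a config error", {
  g <- simulate_genomes(n_genomes = 1, genome_length = 20000,
                        n_genes_per_genome = 10, n_marker_genes = 5,
                        seed = 12)
  sheet <- build_sample_sheet(data.frame(group = "X", timepoint = "day0",
                                         n_samples = 1))
  w <- stats::setNames(rep(1, 12), substitution_types())
  w[c("A>C", "A>G", "A>T")] <- 0
  expect_error(simulate_variant_sets(g, sheet, list(default = w), seed = 1),
               "all zero for ref base A")
  expect_error(simulate_variant_sets(g, sheet, list(X = w), seed = 1),
               "no spectrum weights")
})

test_that("identity simulation validates ranges and plants clusters", {
  expect_error(simulate_identity_matrix(list("A", "B"),
                                        within_range = c(90, 95),
                                        between_range = c(90, 95)),
               "overlap")
  si <- simulate_identity_matrix(list(c("A", "B"), "C"), n_markers = 5,
                                 seed = 1)
  expect_equal(nrow(si$identities), 3 * 5)  # 3 pairs x 5 markers
  expect_true(all(si$identities$identity_pct[
    si$identities$genome_a == "A" & si$identities$genome_b == "B"] >= 96))
  # single genome: no pairs, one singleton downstream
  s1 <- simulate_identity_matrix(list("solo"), seed = 2)
  expect_equal(nrow(s1$identities), 0L)
  cs <- cluster_genomes(compute_ani_proxy(s1))
  expect_equal(length(cs$clusters), 1L)
})
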