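# RPKM-like abundance, SNP density, Wilcoxon signed-rank, KO enrichment.

test_that("RNG abundance follows the count/length renormalisation", {
  counts <- matrix(c(10, 30), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  ab <- gene_abundance(counts, c(g1 = 1000, g2 = 3000))
  expect_equal(unname(ab$ng[, 1]), c(0.01, 0.01))
  expect_equal(unname(ab$rng[, 1]), c(0.5, 0.5))
  # single gene
  ab1 <- gene_abundance(matrix(7, 1, 1, dimnames = list("g1", "s1")),
                        c(g1 = 500))
  expect_equal(unname(ab1$rng[1, 1]), 1)
  # all-zero sample flagged, not NaN-silent
  expect_warning(ab0 <- gene_abundance(
    matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    c(g1 = 100, g2 = 100)), "all-zero")
  expect_true(all(is.na(ab0$rng)))
  expect_equal(ab0$flagged_samples, "s1")
  expect_error(gene_abundance(counts, c(g1 = 0, g2 = 100)), "positive")
})

test_that("RNG sums to one and is scale invariant", {
  set.seed(41)
  counts <- matrix(rpois(200, 20), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%02d", 1:10)))
  lens <- stats::setNames(sample(300:3000, 20), rownames(counts))
  ab <- gene_abundance(counts, lens)
  expect_true(all(abs(colSums(ab$rng) - 1) < 1e-9))
  ab10 <- gene_abundance(counts * 10, lens)
  expect_equal(ab$rng, ab10$rng)
})

test_that("SNP density applies the inclusive 10x coverage boundary", {
  genes <- data.frame(gene_id = "g1", genome_id = "G1", start = 1001,
                      end = 3000)
  snps <- data.frame(sample_id = rep(c("s1", "s2", "s3"), each = 4),
                     genome_id = "G1", pos = rep(c(1100, 1500, 2000, 2500), 3),
                     vtype = "SNP", stringsAsFactors = FALSE)
  depth <- matrix(c(30, 9, 10), 1, 3, dimnames = list("g1",
                                                      c("s1", "s2", "s3")))
  d <- snp_density(genes, snps, depth, min_depth = 10)
  expect_equal(d$density_per_kb, rep(2, 3))  # 4 SNPs over 2 kb
  expect_equal(d$included, c(TRUE, FALSE, TRUE))  # 9 excluded, 10 included
  expect_error(snp_density(genes, snps, depth,
                           genome_lengths = c(G1 = 2500)),
               "outside its contig")
})

test_that("exact signed-rank p matches hand computation and the oracle", {
  # all-positive differences, n = 3: 2 of 8 sign assignments as extreme
  expect_equal(signed_rank_test(c(1, 2, 3))$p_value, 0.25)
  # all zeros: p = 1, flagged
  r0 <- signed_rank_test(c(0, 0, 0))
  expect_equal(r0$p_value, 1)
  expect_true(r0$all_zero)
  # enumeration oracle for n <= 12, with ties and zeros
  set.seed(43)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    d <- sample(c(-3:3), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    r <- signed_rank_test(d)
    expect_equal(r$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
    expect_true(r$exact)
  }
  # matches wilcox.test exactly in the tie-free zero-free case
  set.seed(44)
  d <- sample(1:100, 15) * sample(c(-1, 1), 15, replace = TRUE)
  expect_equal(signed_rank_test(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("normal approximation kicks in above the exact limit", {
  set.seed(45)
  d <- rnorm(40, mean = 0.5)
  r <- signed_rank_test(d, exact_limit = 25)
  expect_false(r$exact)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-10)
})

test_that("paired density testing flags planted density shifts", {
  set.seed(46)
  n_genes <- 60
  n_subj <- 20
  genes <- sprintf("g%03d", seq_len(n_genes))
  subj <- sprintf("p%02d", seq_len(n_subj))
  base <- matrix(rpois(n_genes * n_subj, 5), n_genes, n_subj,
                 dimnames = list(genes, subj))
  shifted <- matrix(rpois(n_genes * n_subj, 5), n_genes, n_subj,
                    dimnames = list(genes, subj))
  planted <- 1:6
  shifted[planted, ] <- matrix(rpois(6 * n_subj, 15), 6, n_subj)
  res <- paired_density_test(base / 2, shifted / 2)
  hits <- res$gene_id[res$p_value < 0.05]
  expect_gte(sum(genes[planted] %in% hits), 5)
  # all-zero genes flagged with p = 1
  z <- paired_density_test(base[1, , drop = FALSE] * 0,
                           base[1, , drop = FALSE] * 0)
  expect_true(z$all_zero)
  expect_equal(z$p_value, 1)
})

test_that("KO enrichment matches the hypergeometric tail oracle", {
  bg <- sprintf("K%03d", 1:100)
  pw <- data.frame(ko_id = bg,
                   pathway_id = rep(c("P1", "P2"), c(10, 90)))
  sig <- c(bg[1:5], bg[31:45])  # 5 of pathway P1's 10, 20 significant total
  res <- ko_enrichment(sig, bg, pw)
  expect_equal(res$p_value[res$pathway_id == "P1"],
               oracle_hyper_upper(5, N = 100, K = 10, n = 20),
               tolerance = 1e-12)
  # significant set equal to background: every p = 1
  res_all <- ko_enrichment(bg, bg, pw)
  expect_true(all(res_all$p_value == 1))
  # small pathway entirely inside the significant set
  sig2 <- bg[1:10]
  res2 <- ko_enrichment(sig2, bg, pw)
  expect_equal(res2$p_value[res2$pathway_id == "P1"],
               oracle_hyper_upper(10, N = 100, K = 10, n = 10),
               tolerance = 1e-12)
  expect_lt(res2$p_value[res2$pathway_id == "P1"], 1e-12)
  expect_error(ko_enrichment(c("K999"), bg, pw), "subset")
  expect_message(
    ko_enrichment(bg[1], bg, rbind(pw, data.frame(ko_id = "KX",
                                                  pathway_id = "P9"))),
    "no background members")
})
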