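# Variant classification, filtering, genome inclusion, and the marker-gene
# false-positive rate.

mk_call <- function(vtype = "SNP", af = 0.1, total = 20, fwd = 10,
                    ref = "C", alt = "T", genome = "G1", pos = 100,
                    sample = "s1") {
  data.frame(sample_id = sample, genome_id = genome, contig_id = genome,
             pos = pos, ref_allele = ref, alt_allele = alt, vtype = vtype,
             allele_frequency = af, support_total = total,
             support_fwd = fwd, support_rev = total - fwd,
             stringsAsFactors = FALSE)
}

test_that("variants classify by allele-length difference with inclusive 50", {
  expect_equal(classify_variant("C", "T"), "SNP")
  expect_equal(classify_variant("A", strrep("A", 51)), "INDEL")  # 50 bp ins
  expect_equal(classify_variant("A", strrep("A", 52)), "SV")     # 51 bp ins
  expect_equal(classify_variant(strrep("A", 51), "A"), "INDEL")
  expect_equal(classify_variant("AC", "GT"), "MNP")
  expect_error(classify_variant("", "A"), "non-empty")
})

test_that("MNPs decompose into per-base SNPs at differing positions", {
  calls <- mk_call(ref = "ACG", alt = "ATG", vtype = "MNP", pos = 10)
  expect_message(out <- decompose_mnps(calls), "decomposed 1")
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 11L)
  expect_equal(out$ref_allele, "C")
  expect_equal(out$alt_allele, "T")
  expect_equal(out$vtype, "SNP")
})

test_that("filters follow the strict/inclusive boundary reading", {
  pol <- filter_policy()
  # AF rule strict at 1%
  r <- filter_variants(mk_call(af = 0.005, total = 20), pol)
  expect_equal(r$rejected$reason, "allele_frequency")
  r <- filter_variants(mk_call(af = 0.01, total = 20), pol)
  expect_equal(r$rejected$reason, "allele_frequency")  # boundary excluded
  # support rule strict at 5 reads
  r <- filter_variants(mk_call(af = 0.05, total = 5), pol)
  expect_equal(r$rejected$reason, "support")
  expect_equal(nrow(filter_variants(mk_call(af = 0.05, total = 6),
                                    pol)$kept), 1L)
  # InDel strand rule
  r <- filter_variants(mk_call(vtype = "INDEL", ref = "A", alt = "AT",
                               total = 8, fwd = 8), pol)
  expect_equal(r$rejected$reason, "strand")
  expect_equal(nrow(filter_variants(mk_call(vtype = "INDEL", ref = "A",
                                            alt = "AT", total = 8,
                                            fwd = 7), pol)$kept), 1L)
  # strand rule does not apply to SNPs by default, but can be extended
  expect_equal(nrow(filter_variants(mk_call(total = 8, fwd = 8),
                                    pol)$kept), 1L)
  pol2 <- filter_policy(snp_strand_rule = TRUE)
  expect_equal(filter_variants(mk_call(total = 8, fwd = 8),
                               pol2)$rejected$reason, "strand")
  # SV support rule inclusive at 3, and AF rule not applied to SVs
  sv <- mk_call(vtype = "SV", ref = strrep("A", 60), alt = "A",
                af = 0.001, total = 3, fwd = 2)
  expect_equal(nrow(filter_variants(sv, pol)$kept), 1L)
  sv$support_total <- 2L
  expect_equal(filter_variants(sv, pol)$rejected$reason, "sv_support")
  # first failing rule is reported: AF checked before support
  r <- filter_variants(mk_call(af = 0.005, total = 2), pol)
  expect_equal(r$rejected$reason, "allele_frequency")
})

test_that("filtering partitions the input and is idempotent and monotone", {
  set.seed(31)
  n <- 400
  total <- sample(1:30, n, replace = TRUE)
  fwd <- vapply(total, function(t) sample(0:t, 1), 0L)
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    mk_call(vtype = sample(c("SNP", "INDEL", "SV"), 1),
            af = runif(1, 0, 0.2), total = total[i], fwd = fwd[i],
            pos = i)
  }))
  r <- filter_variants(calls)
  expect_equal(nrow(r$kept) + nrow(r$rejected), n)
  key <- function(df) sort(paste(df$pos, df$vtype, df$support_total))
  expect_identical(sort(c(key(r$kept), key(r$rejected))), key(calls))
  # idempotence
  r2 <- filter_variants(r$kept)
  expect_equal(nrow(r2$rejected), 0L)
  expect_identical(key(r2$kept), key(r$kept))
  # monotonicity: stricter thresholds never enlarge the kept set
  for (pol in list(filter_policy(min_af = 0.05),
                   filter_policy(min_support = 10))) {
    expect_true(all(key(filter_variants(calls, pol)$kept) %in% key(r$kept)))
    expect_lte(nrow(filter_variants(calls, pol)$kept), nrow(r$kept))
  }
})

test_that("genome inclusion needs at least three kept SNPs", {
  calls <- rbind(mk_call(genome = "G1", pos = 1), mk_call(genome = "G1", pos = 2),
                 mk_call(genome = "G2", pos = 1), mk_call(genome = "G2", pos = 2),
                 mk_call(genome = "G2", pos = 3),
                 mk_call(genome = "G3", pos = 1, vtype = "INDEL",
                         ref = "A", alt = "AT"))
  expect_equal(genomes_passing(calls), "G2")  # 2 SNPs excluded, 3 included
  expect_equal(genomes_passing(calls[0, ]), character(0))
  # per-sample evaluation
  calls$sample_id <- c("s1", "s1", "s1", "s1", "s2", "s1")
  ps <- genomes_passing(calls, per_sample = TRUE)
  expect_equal(ps$s1, character(0))
  expect_equal(genomes_passing(calls,
                               filter_policy(min_snps_per_genome = 2))[1],
               "G1")
})

test_that("false-positive rate is truth-based and guards degenerate input", {
  mk <- data.frame(genome_id = "G1", start = c(50, 200), end = c(150, 300))
  truth <- rbind(mk_call(pos = 100), mk_call(pos = 250))
  kept <- rbind(mk_call(pos = 100), mk_call(pos = 250))
  expect_equal(as.numeric(
    estimate_false_positive_rate(kept, mk, truth)), 0)
  # 4 of 100 marker calls absent from truth -> 0.04
  kept100 <- do.call(rbind, lapply(1:100, function(i) mk_call(pos = 50 + i %% 100)))
  truth96 <- kept100[1:96, ]
  fp <- estimate_false_positive_rate(kept100, data.frame(
    genome_id = "G1", start = 1, end = 1000), truth96)
  expect_equal(as.numeric(fp), sum(!(kept100$pos[97:100] %in% truth96$pos)) /
                 100)
  # zero marker-region calls: undefined with warning, not 0
  expect_warning(
    fp0 <- estimate_false_positive_rate(mk_call(pos = 5000), mk, truth),
    "undefined")
  expect_true(is.na(fp0))
  expect_error(estimate_false_positive_rate(kept, data.frame(
    genome_id = "G1", start = c(50, 100), end = c(150, 200)), truth),
    "overlapping")
})

test_that("VCF reading splits multi-allelics and falls back to AD", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"srf\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"srr\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "G1\t10\t.\tA\tT,G\t.\t.\tAF=0.1,0.2;DP=30;SRF=14;SRR=16",
    "G1\t20\t.\tC\tT\t.\t.\tDP=40;AD=36,4;SRF=20;SRR=20"
  ), p)
  calls <- read_variant_calls(p, "s1")
  expect_equal(nrow(calls), 3L)  # multi-allelic split
  expect_equal(calls$allele_frequency[calls$pos == 10],
               c(0.1, 0.2))
  expect_equal(calls$allele_frequency[calls$pos == 20], 0.1)  # AD fallback
  expect_equal(unique(calls$support_total), c(30L, 40L))
  # record with neither AF nor AD is a hard error naming the record
  writeLines(c(readLines(p)[1:7], "G1\t30\t.\tC\tT\t.\t.\tDP=10;SRF=5;SRR=5"),
             p)
  expect_error(read_variant_calls(p, "s1"), "G1:30")
})

test_that("empty and malformed VCF records are handled gracefully", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "e.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), p)
  expect_warning(calls <- read_variant_calls(p, "s1"), "empty")
  expect_equal(nrow(calls), 0L)
  expect_error(read_variant_calls(file.path(dir, "absent.vcf"), "s1"),
               "not found")
})
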