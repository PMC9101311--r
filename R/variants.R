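# Variant parsing, size classification, filtering and genome inclusion.
#
# Classification follows the size convention: single-base substitutions are
# SNPs, length differences of 1-50 bp are InDels (inclusive at 50), larger
# events are structural variants. Filters: allele frequency strictly above 1%
# and support strictly above five reads for SNPs/InDels, at least one read on
# each strand for InDels, at least three supporting reads for SVs; a genome
# enters downstream analyses only with at least three kept SNPs.

#' Variant filter policy
#'
#' Thresholds follow a literal reading of the method: "larger than 1%" and
#' "more than five reads" are strict inequalities; the SV support rule
#' ("at least three reads") and the per-genome SNP rule ("at least three
#' SNPs") are inclusive.
#'
#' @param min_af Minimum allele frequency, strict (default 0.01).
#' @param min_support Minimum supporting reads for SNPs/InDels, strict
#'   (default 5, i.e. kept at >= 6).
#' @param indel_strand_rule Require at least one supporting read per strand
#'   for InDels (default `TRUE`).
#' @param snp_strand_rule Extend the strand rule to SNPs (default `FALSE`;
#'   sensitivity-analysis option).
#' @param sv_min_support Minimum supporting reads for SVs, inclusive
#'   (default 3).
#' @param min_snps_per_genome Kept-SNP count needed for a genome to enter
#'   downstream analyses, inclusive (default 3).
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(min_af = 0.01, min_support = 5,
                          indel_strand_rule = TRUE, snp_strand_rule = FALSE,
                          sv_min_support = 3, min_snps_per_genome = 3) {
  stopifnot(min_af >= 0, min_support >= 0, sv_min_support >= 0,
            min_snps_per_genome >= 0)
  structure(list(min_af = min_af, min_support = min_support,
                 indel_strand_rule = indel_strand_rule,
                 snp_strand_rule = snp_strand_rule,
                 sv_min_support = sv_min_support,
                 min_snps_per_genome = min_snps_per_genome),
            class = "filter_policy")
}

#' Classify variants by allele lengths
#'
#' Equal lengths of 1 are SNPs; equal lengths above 1 are MNPs (decomposed to
#' SNPs by [decompose_mnps()] / [read_variant_calls()]); a length difference
#' of 1-50 bp is an InDel; larger differences are SVs.
#'
#' @param ref_allele,alt_allele Non-empty DNA strings (vectorised).
#' @return Character vector: `"SNP"`, `"MNP"`, `"INDEL"` or `"SV"`.
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  if (any(!nzchar(ref_allele)) || any(!nzchar(alt_allele))) {
    stop("alleles must be non-empty strings")
  }
  lr <- nchar(ref_allele)
  la <- nchar(alt_allele)
  d <- abs(lr - la)
  ifelse(d == 0L, ifelse(lr == 1L, "SNP", "MNP"),
         ifelse(d <= 50L, "INDEL", "SV"))
}

#' Decompose multi-nucleotide substitutions into per-base SNPs
#'
#' Equal-length multi-base records are split into one SNP per differing
#' position; other records pass through unchanged.
#'
#' @param calls Variant call data.frame (see [read_variant_calls()]).
#' @return The data.frame with MNP rows replaced by SNP rows; the number of
#'   decomposed records is reported via `message()`.
#' @export
decompose_mnps <- function(calls) {
  is_mnp <- calls$vtype == "MNP"
  if (!any(is_mnp)) return(calls)
  keep <- calls[!is_mnp, , drop = FALSE]
  ext <- lapply(which(is_mnp), function(i) {
    r <- strsplit(calls$ref_allele[i], "")[[1]]
    a <- strsplit(calls$alt_allele[i], "")[[1]]
    diff <- which(r != a)
    if (length(diff) == 0L) return(NULL)
    out <- calls[rep(i, length(diff)), , drop = FALSE]
    out$pos <- calls$pos[i] + diff - 1L
    out$ref_allele <- r[diff]
    out$alt_allele <- a[diff]
    out$vtype <- "SNP"
    out
  })
  message("decomposed ", sum(is_mnp), " MNP record(s) into per-base SNPs")
  out <- rbind(keep, do.call(rbind, ext))
  out <- out[order(out$sample_id, out$contig_id, out$pos, out$alt_allele), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# parse one INFO column value like "AF=0.1;DP=30" into a named list
.parse_info <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file into one `VariantCall` row per ALT allele
#' (multi-allelic records are split; equal-length multi-base records are
#' decomposed into per-base SNPs). Allele frequency comes from the INFO field
#' named by `info_keys["af"]`; when absent, it falls back to `AD` (alt depth /
#' total depth). Strand support comes from `SRF`/`SRR`; when both are absent
#' the total support falls back to `DP` with unknown strand split. Malformed
#' records are skipped and counted in the `n_skipped` attribute.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_id Sample label attached to every call.
#' @param genome_map Optional named vector mapping contig id to genome id
#'   (default: genome id = contig id).
#' @param info_keys Named character vector with elements `af`, `dp`, `srf`,
#'   `srr` naming the INFO keys to read.
#' @return data.frame with columns `sample_id`, `genome_id`, `contig_id`,
#'   `pos`, `ref_allele`, `alt_allele`, `vtype`, `allele_frequency`,
#'   `support_total`, `support_fwd`, `support_rev`.
#' @export
read_variant_calls <- function(path, sample_id, genome_map = NULL,
                               info_keys = c(af = "AF", dp = "DP",
                                             srf = "SRF", srr = "SRR")) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  empty <- data.frame(
    sample_id = character(), genome_id = character(),
    contig_id = character(), pos = integer(), ref_allele = character(),
    alt_allele = character(), vtype = character(),
    allele_frequency = numeric(), support_total = integer(),
    support_fwd = integer(), support_rev = integer(),
    stringsAsFactors = FALSE)
  n_body <- length(grep("^[^#]", readLines(path, warn = FALSE)))
  if (n_body == 0L) {
    warning("empty VCF: ", path)
    return(empty)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- is.na(pos) | pos < 1L | is.na(fix$REF) | is.na(fix$ALT) |
    !nzchar(fix$REF) | !nzchar(fix$ALT)
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    warning("skipped ", n_skipped, " malformed record(s) in ", basename(path))
  }
  fix <- fix[!bad, , drop = FALSE]
  pos <- pos[!bad]
  if (nrow(fix) == 0L) return(structure(empty, n_skipped = n_skipped))
  af_raw <- .parse_info(fix$INFO, info_keys[["af"]])
  dp <- suppressWarnings(as.integer(.parse_info(fix$INFO, info_keys[["dp"]])))
  srf <- suppressWarnings(as.integer(.parse_info(fix$INFO,
                                                 info_keys[["srf"]])))
  srr <- suppressWarnings(as.integer(.parse_info(fix$INFO,
                                                 info_keys[["srr"]])))
  ad_raw <- .parse_info(fix$INFO, "AD")
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  alt_rank <- sequence(n_alt)
  af_list <- strsplit(af_raw, ",", fixed = TRUE)
  af <- vapply(seq_along(rec), function(k) {
    vals <- af_list[[rec[k]]]
    if (length(vals) == 0L || all(is.na(vals))) return(NA_real_)
    suppressWarnings(as.numeric(vals[min(alt_rank[k], length(vals))]))
  }, 0)
  if (anyNA(af)) {
    # AD fallback: ref,alt1,alt2,... depths
    ad_list <- strsplit(ad_raw, ",", fixed = TRUE)
    for (k in which(is.na(af))) {
      ad <- suppressWarnings(as.numeric(ad_list[[rec[k]]]))
      if (length(ad) >= alt_rank[k] + 1L && !anyNA(ad) && sum(ad) > 0) {
        af[k] <- ad[alt_rank[k] + 1L] / sum(ad)
      } else {
        stop("record ", fix$CHROM[rec[k]], ":", pos[rec[k]],
             " has no ", info_keys[["af"]], " field and no usable AD fallback")
      }
    }
  }
  fwd <- srf[rec]
  rev_ <- srr[rec]
  total <- ifelse(!is.na(fwd) & !is.na(rev_), fwd + rev_, dp[rec])
  if (anyNA(total)) {
    stop("record(s) without ", info_keys[["srf"]], "/", info_keys[["srr"]],
         " or ", info_keys[["dp"]], " support information in ",
         basename(path))
  }
  contig <- fix$CHROM[rec]
  genome <- if (is.null(genome_map)) contig else unname(genome_map[contig])
  alt_vec <- unlist(alts, use.names = FALSE)
  calls <- data.frame(
    sample_id = sample_id, genome_id = genome, contig_id = contig,
    pos = pos[rec], ref_allele = fix$REF[rec], alt_allele = alt_vec,
    vtype = classify_variant(fix$REF[rec], alt_vec),
    allele_frequency = af, support_total = as.integer(total),
    support_fwd = as.integer(fwd), support_rev = as.integer(rev_),
    stringsAsFactors = FALSE)
  calls <- decompose_mnps(calls)
  structure(calls, n_skipped = n_skipped)
}

#' Apply the variant filter policy
#'
#' SNPs and InDels are kept iff allele frequency exceeds `min_af` and total
#' support exceeds `min_support` (both strict); InDels additionally need at
#' least one supporting read on each strand when the strand rule is on
#' (unknown strand counts pass with a warning); SVs are kept iff support is
#' at least `sv_min_support`. Every rejected call carries its first failing
#' rule (checked in the order allele_frequency, support, strand).
#'
#' @param calls Variant call data.frame (classified; see
#'   [read_variant_calls()]).
#' @param policy A [filter_policy()].
#' @return List with `kept` (calls passing all rules) and `rejected` (calls
#'   with an added `reason` column).
#' @export
filter_variants <- function(calls, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  main <- calls$vtype %in% c("SNP", "INDEL")
  fail_af <- main & !(calls$allele_frequency > policy$min_af)
  reason[fail_af] <- "allele_frequency"
  fail_sup <- main & is.na(reason) &
    !(calls$support_total > policy$min_support)
  reason[fail_sup] <- "support"
  strand_known <- !is.na(calls$support_fwd) & !is.na(calls$support_rev)
  if (any(main & !strand_known)) {
    warning("strand support unknown for ", sum(main & !strand_known),
            " call(s); strand rule treated as passed")
  }
  strand_scope <- (calls$vtype == "INDEL" & policy$indel_strand_rule) |
    (calls$vtype == "SNP" & policy$snp_strand_rule)
  fail_strand <- strand_scope & is.na(reason) & strand_known &
    !(calls$support_fwd >= 1L & calls$support_rev >= 1L)
  reason[fail_strand] <- "strand"
  is_sv <- calls$vtype == "SV"
  fail_sv <- is_sv & !(calls$support_total >= policy$sv_min_support)
  reason[fail_sv] <- "sv_support"
  kept <- calls[is.na(reason), , drop = FALSE]
  rejected <- calls[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Genomes passing the kept-SNP inclusion rule
#'
#' A genome enters downstream analyses iff its kept SNP count reaches
#' `min_snps_per_genome`. The count is cohort-wide by default (across all
#' samples in `kept`); with `per_sample = TRUE` a named list per sample is
#' returned instead.
#'
#' @param kept Kept calls from [filter_variants()].
#' @param policy A [filter_policy()].
#' @param per_sample Evaluate the rule within each sample separately.
#' @return Sorted character vector of genome ids (or a named list of them).
#' @export
genomes_passing <- function(kept, policy = filter_policy(),
                            per_sample = FALSE) {
  snps <- kept[kept$vtype == "SNP", , drop = FALSE]
  rule <- function(df) {
    cnt <- table(df$genome_id)
    sort(as.character(names(cnt)[cnt >= policy$min_snps_per_genome]))
  }
  if (per_sample) {
    lapply(split(snps, snps$sample_id), rule)
  } else {
    rule(snps)
  }
}

#' Estimate the false-positive rate from marker-gene regions
#'
#' On synthetic runs with complete truth, the false-positive rate is the
#' fraction of kept calls falling inside single-copy marker gene regions that
#' are absent from the planted truth. With a zero denominator the rate is
#' undefined (`NA`, with a warning), never 0.
#'
#' @param kept Kept calls from [filter_variants()].
#' @param marker_regions data.frame with `genome_id`, `start`, `end`
#'   (1-based inclusive, non-overlapping within a genome).
#' @param truth_calls Planted truth calls (`sim_variants$calls` or any
#'   data.frame with `sample_id`, `genome_id`, `pos`, `ref_allele`,
#'   `alt_allele`).
#' @return Fraction in \[0, 1\], or `NA` when no kept call lies in a marker
#'   region. Attributes `n_marker_calls` and `n_false` carry the counts.
#' @export
estimate_false_positive_rate <- function(kept, marker_regions, truth_calls) {
  stopifnot(all(c("genome_id", "start", "end") %in% names(marker_regions)))
  if (any(marker_regions$end < marker_regions$start)) {
    stop("invalid marker interval (end < start)")
  }
  for (g in unique(marker_regions$genome_id)) {
    sub <- marker_regions[marker_regions$genome_id == g, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      stop("overlapping marker intervals in genome ", g)
    }
  }
  if (nrow(kept) == 0L) {
    warning("no kept calls in marker regions; false-positive rate undefined")
    return(structure(NA_real_, n_marker_calls = 0L, n_false = 0L))
  }
  gr_mk <- GenomicRanges::GRanges(
    marker_regions$genome_id,
    IRanges::IRanges(marker_regions$start, marker_regions$end))
  gr_calls <- GenomicRanges::GRanges(
    kept$genome_id, IRanges::IRanges(kept$pos, kept$pos))
  in_marker <- IRanges::overlapsAny(gr_calls, gr_mk)
  n_mk <- sum(in_marker)
  if (n_mk == 0L) {
    warning("no kept calls in marker regions; false-positive rate undefined")
    return(structure(NA_real_, n_marker_calls = 0L, n_false = 0L))
  }
  key <- function(df) paste(df$sample_id, df$genome_id, df$pos,
                            df$ref_allele, df$alt_allele, sep = "\r")
  n_false <- sum(!(key(kept)[in_marker] %in% key(truth_calls)))
  structure(n_false / n_mk, n_marker_calls = n_mk, n_false = n_false)
}
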