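# Per-sample variant simulation: SNPs drawn from condition-specific 12-type
# substitution spectra, InDels and SVs at configurable rates, allele
# frequencies and strand-split read support, plus planted filter violations.
# Every planted call is recorded in a ground-truth table.

#' The twelve ordered substitution types
#'
#' Ordered ref>alt single-nucleotide substitution classes, no strand
#' collapsing: 4 reference bases x 3 alternatives.
#'
#' @return Character vector of length 12 (`"A>C"`, `"A>G"`, ...).
#' @export
substitution_types <- function() {
  as.vector(t(outer(DNA_BASES, DNA_BASES, function(a, b) paste0(a, ">", b)))[
    t(outer(DNA_BASES, DNA_BASES, `!=`))])
}

#' Transition substitution types
#'
#' @return The four transition classes (`A>G`, `G>A`, `C>T`, `T>C`).
#' @export
transition_types <- function() c("A>G", "G>A", "C>T", "T>C")

#' Build a sample sheet from group/timepoint specifications
#'
#' Subjects are shared across timepoints within a group (paired longitudinal
#' design): group `Oxi` with `n_samples = 5` at `day0` and `day30` yields five
#' subjects, each with one sample per timepoint.
#'
#' @param groups data.frame with columns `group`, `timepoint`, `n_samples`.
#' @return data.frame with `sample_id`, `subject_id`, `group`, `timepoint`.
#' @export
build_sample_sheet <- function(groups) {
  stopifnot(all(c("group", "timepoint", "n_samples") %in% names(groups)))
  if (anyDuplicated(groups[, c("group", "timepoint")])) {
    stop("duplicate (group, timepoint) rows in group specification")
  }
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups$group[i]
    t <- groups$timepoint[i]
    n <- groups$n_samples[i]
    subj <- sprintf("%s_s%02d", g, seq_len(n))
    data.frame(sample_id = sprintf("%s_%s_s%02d", g, t, seq_len(n)),
               subject_id = subj, group = g, timepoint = t,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  stopifnot(!anyDuplicated(out$sample_id))
  out
}

# weights: named numeric over substitution_types() (or unnamed length 12 in
# that order) -> 4x4 matrix W[ref, alt]
spectrum_weight_matrix <- function(weights) {
  types <- substitution_types()
  if (is.null(names(weights))) {
    if (length(weights) != 12L) stop("spectrum weights must have length 12")
    names(weights) <- types
  }
  if (!setequal(names(weights), types)) {
    stop("spectrum weights must be named by the 12 substitution types")
  }
  if (any(weights < 0)) stop("spectrum weights must be non-negative")
  if (sum(weights) <= 0) stop("spectrum weights must not be all zero")
  W <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (ty in types) {
    p <- strsplit(ty, ">", fixed = TRUE)[[1]]
    W[p[1], p[2]] <- weights[[ty]]
  }
  W
}

lookup_weights <- function(spectrum_weights, group, timepoint) {
  key <- paste(group, timepoint, sep = ":")
  w <- spectrum_weights[[key]] %||% spectrum_weights[["default"]]
  if (is.null(w)) {
    stop("no spectrum weights for condition '", key, "' and no default")
  }
  w
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate per-sample variant call sets with ground truth
#'
#' SNP positions are uniform over the concatenated genomes; the reference
#' allele is read off the genome sequence and the alternate allele is drawn
#' from the sample's condition-specific 12-type spectrum weights, conditioned
#' on the reference base (the three types with that source base,
#' renormalised). Allele frequencies follow a Beta model, read support is
#' Poisson with a binomial strand split. Configurable fractions of calls are
#' planted as filter violations (allele frequency below the 1% rule, support
#' at five reads or fewer, single-strand InDels, SV support below three
#' reads) to exercise downstream filtering. InDels (1-50 bp) and SVs
#' (deletions > 50 bp) are planted at configurable per-kilobase rates.
#'
#' @param genomes A `sim_genomes` object or named character vector of genome
#'   sequences.
#' @param sample_sheet data.frame from [build_sample_sheet()].
#' @param spectrum_weights Named list: condition key `"<group>:<timepoint>"`
#'   (or `"default"`) to a 12-type weight vector.
#' @param snp_rate Expected SNPs per kilobase per sample.
#' @param af_shape Two Beta shape parameters for the allele-frequency model.
#' @param depth_mean Mean total read support per call.
#' @param frac_low_af Fraction of SNP/InDel calls planted with allele
#'   frequency `low_af_value` (below the default 1% filter).
#' @param low_af_value Allele frequency given to planted low-AF calls.
#' @param frac_low_support Fraction of SNP/InDel calls planted with total
#'   support of 1-5 reads.
#' @param indel_rate Expected InDels per kilobase per sample.
#' @param frac_indel_single_strand Fraction of InDels with all support on one
#'   strand.
#' @param sv_rate Expected SVs per kilobase per sample.
#' @param frac_sv_low_support Fraction of SVs with support of 1-2 reads.
#' @param seed Integer seed.
#' @return List of class `sim_variants`: `calls` (all planted calls, one row
#'   per call with `planted_violation` and `expect_kept` under the default
#'   [filter_policy()]), `spectra` (realised per-sample 12-type SNP counts),
#'   `sample_sheet`, and `genome_lengths`.
#' @export
simulate_variant_sets <- function(genomes, sample_sheet, spectrum_weights,
                                  snp_rate = 2, af_shape = c(2, 8),
                                  depth_mean = 60,
                                  frac_low_af = 0, low_af_value = 0.005,
                                  frac_low_support = 0,
                                  indel_rate = 0,
                                  frac_indel_single_strand = 0,
                                  sv_rate = 0, frac_sv_low_support = 0,
                                  seed = 1) {
  seqs <- if (inherits(genomes, "sim_genomes")) genomes$sequences else genomes
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  glen <- nchar(seqs)
  total_len <- sum(glen)
  bounds <- cumsum(glen)
  offsets <- c(0, bounds[-length(bounds)])
  # validate weights up front: every condition must give every present ref
  # base a usable alternative
  for (i in seq_len(nrow(sample_sheet))) {
    W <- spectrum_weight_matrix(
      lookup_weights(spectrum_weights, sample_sheet$group[i],
                     sample_sheet$timepoint[i]))
    bad <- rowSums(W) <= 0
    if (any(bad)) {
      stop("spectrum weights for condition '",
           paste(sample_sheet$group[i], sample_sheet$timepoint[i], sep = ":"),
           "' are all zero for ref base ",
           paste(DNA_BASES[bad], collapse = ","))
    }
  }
  set.seed(seed)
  types <- substitution_types()
  all_calls <- vector("list", nrow(sample_sheet))
  spectra <- matrix(0L, nrow(sample_sheet), 12L,
                    dimnames = list(sample_sheet$sample_id, types))
  for (si in seq_len(nrow(sample_sheet))) {
    sm <- sample_sheet[si, ]
    W <- spectrum_weight_matrix(
      lookup_weights(spectrum_weights, sm$group, sm$timepoint))
    n_snp <- stats::rpois(1, snp_rate * total_len / 1000)
    n_snp <- min(n_snp, total_len)
    gpos <- sort(sample.int(total_len, n_snp))
    gidx <- findInterval(gpos - 1L, bounds) + 1L
    pos <- gpos - offsets[gidx]
    ref <- substring(seqs[gidx], pos, pos)
    alt <- character(n_snp)
    for (b in DNA_BASES) {
      sel <- ref == b
      if (!any(sel)) next
      alts <- DNA_BASES[DNA_BASES != b]
      w <- W[b, alts]
      alt[sel] <- sample(alts, sum(sel), replace = TRUE, prob = w)
    }
    af <- pmax(stats::rbeta(n_snp, af_shape[1], af_shape[2]), 1e-4)
    support <- pmax(1L, stats::rpois(n_snp, depth_mean))
    violation <- rep("none", n_snp)
    ord <- sample.int(n_snp)
    k1 <- round(frac_low_af * n_snp)
    k2 <- round(frac_low_support * n_snp)
    if (k1 > 0) {
      af[ord[seq_len(k1)]] <- low_af_value
      violation[ord[seq_len(k1)]] <- "low_af"
    }
    if (k2 > 0) {
      idx2 <- ord[k1 + seq_len(k2)]
      support[idx2] <- sample(1:5, k2, replace = TRUE)
      violation[idx2] <- "low_support"
    }
    fwd <- stats::rbinom(n_snp, support, 0.5)
    snps <- data.frame(
      sample_id = sm$sample_id, genome_id = names(seqs)[gidx],
      contig_id = names(seqs)[gidx], pos = pos,
      ref_allele = ref, alt_allele = alt, vtype = "SNP",
      allele_frequency = af, support_total = support,
      support_fwd = fwd, support_rev = support - fwd,
      planted_violation = violation, stringsAsFactors = FALSE
    )
    tt <- table(factor(paste0(ref, ">", alt), levels = types))
    spectra[si, ] <- as.integer(tt)

    make_long <- function(n, min_len, max_len, vtype, frac_bad_support,
                          bad_support_values, frac_single_strand) {
      if (n == 0L) return(NULL)
      gidx <- sample.int(length(seqs), n, replace = TRUE)
      L <- sample(min_len:max_len, n, replace = TRUE)
      pos <- vapply(seq_len(n), function(i) {
        sample.int(glen[gidx[i]] - L[i] - 1L, 1L)
      }, 0L)
      is_ins <- vtype == "INDEL" & stats::runif(n) < 0.5
      ref <- ifelse(is_ins, substring(seqs[gidx], pos, pos),
                    substring(seqs[gidx], pos, pos + L))
      alt <- ifelse(is_ins,
                    vapply(seq_len(n), function(i) {
                      paste0(substring(seqs[gidx[i]], pos[i], pos[i]),
                             random_dna(L[i]))
                    }, ""),
                    substring(seqs[gidx], pos, pos))
      af <- pmax(stats::rbeta(n, af_shape[1], af_shape[2]), 1e-4)
      support <- pmax(2L, stats::rpois(n, if (vtype == "SV") 10 else depth_mean))
      violation <- rep("none", n)
      ord <- sample.int(n)
      kb <- round(frac_bad_support * n)
      if (kb > 0) {
        idxb <- ord[seq_len(kb)]
        support[idxb] <- sample(bad_support_values, kb, replace = TRUE)
        violation[idxb] <- if (vtype == "SV") "low_sv_support" else "low_support"
      }
      # keep both strands covered by default so the strand rule is violated
      # only where planted
      fwd <- 1L + stats::rbinom(n, pmax(support - 2L, 0L), 0.5)
      if (vtype == "INDEL" && frac_single_strand > 0) {
        ks <- round(frac_single_strand * n)
        if (ks > 0) {
          idxs <- ord[kb + seq_len(ks)]
          fwd[idxs] <- support[idxs]
          violation[idxs] <- "single_strand"
        }
      }
      data.frame(
        sample_id = sm$sample_id, genome_id = names(seqs)[gidx],
        contig_id = names(seqs)[gidx], pos = pos,
        ref_allele = ref, alt_allele = alt, vtype = vtype,
        allele_frequency = af, support_total = support,
        support_fwd = fwd, support_rev = support - fwd,
        planted_violation = violation, stringsAsFactors = FALSE
      )
    }
    indels <- make_long(stats::rpois(1, indel_rate * total_len / 1000),
                        1L, 50L, "INDEL", frac_low_support, 1:5,
                        frac_indel_single_strand)
    svs <- make_long(stats::rpois(1, sv_rate * total_len / 1000),
                     51L, 300L, "SV", frac_sv_low_support, 1:2, 0)
    calls <- rbind(snps, indels, svs)
    calls <- calls[order(calls$genome_id, calls$pos, calls$alt_allele), ]
    all_calls[[si]] <- calls
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  pol <- filter_policy()
  keep_main <- calls$allele_frequency > pol$min_af &
    calls$support_total > pol$min_support
  calls$expect_kept <- ifelse(
    calls$vtype == "SV",
    calls$support_total >= pol$sv_min_support,
    keep_main & (calls$vtype != "INDEL" |
                   (calls$support_fwd >= 1L & calls$support_rev >= 1L))
  )
  structure(list(calls = calls,
                 spectra = as.data.frame(cbind(
                   data.frame(sample_id = rownames(spectra),
                              stringsAsFactors = FALSE),
                   spectra), check.names = FALSE),
                 sample_sheet = sample_sheet,
                 genome_lengths = glen, seed = seed),
            class = "sim_variants")
}

#' Write simulated calls as one VCF 4.2 file per sample
#'
#' INFO keys: `AF` (allele frequency), `DP` (total support), `SRF`/`SRR`
#' (forward/reverse supporting reads).
#'
#' @param sim A `sim_variants` object, or a calls data.frame in its layout.
#' @param dir Output directory (created if missing).
#' @param genome_lengths Named lengths for the `##contig` header lines
#'   (taken from `sim` when omitted).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_sample_vcfs <- function(sim, dir, genome_lengths = NULL) {
  calls <- if (inherits(sim, "sim_variants")) sim$calls else sim
  if (is.null(genome_lengths) && inherits(sim, "sim_variants")) {
    genome_lengths <- sim$genome_lengths
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=microvarsig-simulator",
    if (!is.null(genome_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome_lengths),
              as.integer(genome_lengths))
    },
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total supporting reads\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Forward-strand supporting reads\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Reverse-strand supporting reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  samples <- unique(calls$sample_id)
  paths <- stats::setNames(file.path(dir, paste0(samples, ".vcf")), samples)
  for (s in samples) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    cs <- cs[order(cs$contig_id, cs$pos, cs$alt_allele), , drop = FALSE]
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s;DP=%d;SRF=%d;SRR=%d",
      cs$contig_id, as.integer(cs$pos), cs$ref_allele, cs$alt_allele,
      sprintf("%.6g", cs$allele_frequency), as.integer(cs$support_total),
      as.integer(cs$support_fwd), as.integer(cs$support_rev)
    )
    writeLines(c(header, body), paths[[s]])
  }
  invisible(paths)
}

#' Write the sample metadata TSV
#'
#' @param sample_sheet data.frame from [build_sample_sheet()].
#' @param path Output TSV path.
#' @export
write_sample_metadata <- function(sample_sheet, path) {
  write_tsv(sample_sheet[, c("sample_id", "subject_id", "group", "timepoint")],
            path)
}

#' Write simulation ground truth as JSON
#'
#' @param sim A `sim_variants` object.
#' @param path Output JSON path.
#' @export
write_sim_truth <- function(sim, path) {
  jsonlite::write_json(
    list(calls = sim$calls, spectra = sim$spectra,
         sample_sheet = sim$sample_sheet,
         genome_lengths = as.list(sim$genome_lengths), seed = sim$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
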