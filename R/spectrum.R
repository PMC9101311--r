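# Twelve-type substitution spectra: per-sample counts and per-kilobase rates
# over the included reference genomes, transition/transversion aggregates,
# and group/timepoint shift tests.

#' Tally the 12-type substitution spectrum for one sample
#'
#' Counts kept SNPs by ordered `ref>alt` class (no reverse-complement
#' collapsing: 12 classes). The per-kilobase denominator is the total length
#' of the included genomes. SNPs with ambiguous bases are excluded and
#' counted in `n_skipped`.
#'
#' @param snps Kept SNP calls for a single sample (rows with `vtype` other
#'   than `"SNP"` are ignored). Every SNP's genome must be in
#'   `genome_lengths`.
#' @param genome_lengths Named vector of included genome lengths (bp).
#' @param sample_id Optional label (default: taken from `snps`).
#' @return Object of class `substitution_spectrum`: `sample_id`, `counts`
#'   (named over [substitution_types()]), `denominator_kb`, `rates_per_kb`,
#'   `ts_count`, `tv_count`, `n_skipped`.
#' @export
tally_spectrum <- function(snps, genome_lengths, sample_id = NULL) {
  if (!is.null(snps$vtype)) snps <- snps[snps$vtype == "SNP", , drop = FALSE]
  if (is.null(sample_id)) {
    sample_id <- if (nrow(snps) > 0) unique(snps$sample_id) else NA_character_
    if (length(sample_id) != 1L) {
      stop("tally_spectrum expects a single sample; got ",
           length(sample_id))
    }
  }
  if (nrow(snps) > 0) {
    unknown <- setdiff(unique(snps$genome_id), names(genome_lengths))
    if (length(unknown) > 0) {
      stop("SNPs on genome(s) outside the included set: ",
           paste(unknown, collapse = ", "))
    }
  }
  ok <- is_dna(snps$ref_allele) & is_dna(snps$alt_allele) &
    nchar(snps$ref_allele) == 1L & nchar(snps$alt_allele) == 1L
  n_skipped <- sum(!ok)
  snps <- snps[ok, , drop = FALSE]
  types <- substitution_types()
  counts <- table(factor(paste0(snps$ref_allele, ">", snps$alt_allele),
                         levels = types))
  counts <- stats::setNames(as.numeric(counts), types)
  denom_kb <- sum(genome_lengths) / 1000
  ts <- sum(counts[transition_types()])
  structure(list(sample_id = sample_id, counts = counts,
                 denominator_kb = denom_kb,
                 rates_per_kb = counts / denom_kb,
                 ts_count = ts, tv_count = sum(counts) - ts,
                 n_skipped = n_skipped),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("substitution_spectrum for", x$sample_id, "-", sum(x$counts),
      "SNPs over", x$denominator_kb, "kb (Ts", x$ts_count, "/ Tv",
      x$tv_count, ")\n")
  invisible(x)
}

#' Merge two spectra
#'
#' Adds counts component-wise and denominators; intended for samples tallied
#' over matching genome sets.
#'
#' @param x,y `substitution_spectrum` objects.
#' @param sample_id Label for the merged spectrum.
#' @return A `substitution_spectrum`.
#' @export
merge_spectra <- function(x, y, sample_id = paste(x$sample_id, y$sample_id,
                                                  sep = "+")) {
  counts <- x$counts + y$counts
  denom <- x$denominator_kb + y$denominator_kb
  ts <- sum(counts[transition_types()])
  structure(list(sample_id = sample_id, counts = counts,
                 denominator_kb = denom, rates_per_kb = counts / denom,
                 ts_count = ts, tv_count = sum(counts) - ts,
                 n_skipped = x$n_skipped + y$n_skipped),
            class = "substitution_spectrum")
}

#' Transition/transversion ratio
#'
#' @param spectrum A `substitution_spectrum` (or a list with `ts_count`,
#'   `tv_count`).
#' @return `ts_count / tv_count`; `NA` (with a warning, not infinity) when
#'   there are no transversions.
#' @export
ts_tv_ratio <- function(spectrum) {
  if (spectrum$tv_count == 0) {
    warning("no transversions: Ts/Tv undefined")
    return(NA_real_)
  }
  spectrum$ts_count / spectrum$tv_count
}

#' Tally spectra for many samples into a wide table
#'
#' @param calls Kept calls across samples (only SNP rows are used).
#' @param genome_lengths Named vector of included genome lengths (bp).
#' @param sample_ids Samples to tally (default: those present in `calls`);
#'   listing extra ids yields all-zero rows for them.
#' @return data.frame with one row per sample: the 12 count columns (named by
#'   type), `rate_<type>` columns, `ts_count`, `tv_count`, `ts_rate`,
#'   `tv_rate`, `tstv` (`NA` when undefined) and `denominator_kb`.
#' @export
tally_spectra <- function(calls, genome_lengths, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(calls$sample_id))
  types <- substitution_types()
  rows <- lapply(sample_ids, function(s) {
    sp <- tally_spectrum(calls[calls$sample_id == s, , drop = FALSE],
                         genome_lengths, sample_id = s)
    out <- c(as.list(sp$counts),
             stats::setNames(as.list(sp$rates_per_kb),
                             paste0("rate_", types)),
             list(ts_count = sp$ts_count, tv_count = sp$tv_count,
                  ts_rate = sp$ts_count / sp$denominator_kb,
                  tv_rate = sp$tv_count / sp$denominator_kb,
                  tstv = if (sp$tv_count == 0) NA_real_ else
                    sp$ts_count / sp$tv_count,
                  denominator_kb = sp$denominator_kb))
    out
  })
  df <- cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
              do.call(rbind, lapply(rows, function(r) {
                as.data.frame(r, check.names = FALSE)
              })))
  rownames(df) <- NULL
  df
}

# a two-sample t-test that tolerates zero-variance degenerate input
.safe_t_test <- function(a, b, var_equal, paired) {
  if (paired) {
    d <- a - b
    if (all(d == 0)) return(list(statistic = 0, p.value = 1))
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = Inf * sign(mean(a) - mean(b)), p.value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal, paired = paired)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Test spectrum metrics for group/timepoint shifts
#'
#' Compares per-sample metric values between the two sides of each
#' comparison with a two-sample Student t-test (pooled variance by default,
#' Welch by flag), then adjusts all (comparison x metric) p-values in the
#' batch together with Benjamini-Hochberg. The default comparison set is
#' day-pair within each group (every pair of timepoints observed for that
#' group).
#'
#' @param spectra Wide table from [tally_spectra()].
#' @param metadata data.frame with `sample_id`, `group`, `timepoint` (and
#'   `subject_id` when `paired = TRUE`).
#' @param metrics Column names of `spectra` to test (default `ts_rate`,
#'   `tv_rate`, `tstv`; any `rate_<type>` column works).
#' @param comparisons Optional list of `list(label =, a = sample ids, b =
#'   sample ids)`; overrides the default group/timepoint pairs.
#' @param test `"student"` (default) or `"welch"`.
#' @param paired Pair samples by subject (sides must then match by
#'   `subject_id`).
#' @param adjust_method Multiple-testing adjustment (default `"BH"`).
#' @return data.frame with one row per comparison x metric: sample sizes,
#'   side means, `statistic`, `p_value`, `p_adjusted`. Sides with fewer than
#'   two usable samples are skipped with a warning.
#' @export
compare_groups <- function(spectra, metadata,
                           metrics = c("ts_rate", "tv_rate", "tstv"),
                           comparisons = NULL,
                           test = c("student", "welch"),
                           paired = FALSE, adjust_method = "BH") {
  test <- match.arg(test)
  stopifnot(all(metrics %in% names(spectra)))
  meta <- metadata[match(spectra$sample_id, metadata$sample_id), ,
                   drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  if (is.null(comparisons)) {
    comparisons <- list()
    for (g in unique(meta$group)) {
      tps <- sort(unique(meta$timepoint[meta$group == g]))
      if (length(tps) < 2L) next
      cmb <- utils::combn(tps, 2L)
      for (ci in seq_len(ncol(cmb))) {
        comparisons[[length(comparisons) + 1L]] <- list(
          label = paste0(g, ": ", cmb[1L, ci], " vs ", cmb[2L, ci]),
          a = spectra$sample_id[meta$group == g &
                                  meta$timepoint == cmb[1L, ci]],
          b = spectra$sample_id[meta$group == g &
                                  meta$timepoint == cmb[2L, ci]])
      }
    }
  }
  rows <- list()
  for (cmp in comparisons) {
    ia <- match(cmp$a, spectra$sample_id)
    ib <- match(cmp$b, spectra$sample_id)
    if (paired) {
      sa <- meta$subject_id[ia]
      sb <- meta$subject_id[ib]
      shared <- intersect(sa, sb)
      ia <- ia[match(shared, sa)]
      ib <- ib[match(shared, sb)]
    }
    for (metric in metrics) {
      va <- spectra[[metric]][ia]
      vb <- spectra[[metric]][ib]
      if (paired) {
        ok <- !is.na(va) & !is.na(vb)
        va <- va[ok]
        vb <- vb[ok]
      } else {
        va <- va[!is.na(va)]
        vb <- vb[!is.na(vb)]
      }
      if (length(va) < 2L || length(vb) < 2L) {
        warning("comparison '", cmp$label, "' metric '", metric,
                "' skipped: fewer than 2 samples on one side")
        next
      }
      tt <- .safe_t_test(va, vb, var_equal = (test == "student"),
                         paired = paired)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp$label, metric = metric,
        n_a = length(va), n_b = length(vb),
        mean_a = mean(va), mean_b = mean(vb),
        statistic = tt$statistic, p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(comparison = character(), metric = character(),
                      n_a = integer(), n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), statistic = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust_method)
  rownames(out) <- NULL
  out
}
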