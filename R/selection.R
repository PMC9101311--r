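# Per-family Dn/Ds estimation from codon alignments and positive-selection
# testing against the whole-sample background.

#' Construct a codon alignment
#'
#' Sequences are upper-cased and validated: equal lengths, width a multiple of
#' three, gap character `-`. Codons containing any character outside A/C/G/T/-
#' (ambiguity codes) are replaced by gap codons and counted in the
#' `n_ambiguous_codons` field.
#'
#' @param ko_id Family identifier (e.g., a KEGG Orthology id).
#' @param sequences Character vector of aligned coding sequences.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(ko_id, sequences) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("alignment has no sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("aligned sequences must all have the same length")
  if (w %% 3L != 0L) stop("alignment width must be a multiple of 3, got ", w)
  n_amb <- 0L
  has_other <- grepl("[^ACGT-]", sequences)
  if (any(has_other)) {
    for (i in which(has_other)) {
      ch <- strsplit(sequences[i], "")[[1]]
      bad <- !(ch %in% c(DNA_BASES, "-"))
      cod <- unique((which(bad) - 1L) %/% 3L)
      for (cj in cod) ch[(cj * 3L + 1L):(cj * 3L + 3L)] <- "-"
      n_amb <- n_amb + length(cod)
      sequences[i] <- paste(ch, collapse = "")
    }
  }
  structure(list(ko_id = ko_id, sequences = sequences,
                 n_codons = w %/% 3L, n_ambiguous_codons = n_amb),
            class = "codon_alignment")
}

# sequences -> integer codon-index matrix (n_seqs x n_codons); codons with a
# gap, ambiguity, or encoding a stop are NA (excluded pairwise downstream)
alignment_to_idx <- function(aln) {
  if (!is.null(aln$idx)) return(aln$idx)  # simulator-provided cache
  tab <- codon_tables()
  n_cod <- aln$n_codons
  m <- matrix(NA_integer_, length(aln$sequences), n_cod)
  for (i in seq_along(aln$sequences)) {
    ch <- strsplit(aln$sequences[i], "")[[1]]
    cm <- matrix(match(ch, DNA_BASES), nrow = 3L)
    idx <- (cm[1, ] - 1L) * 16L + (cm[2, ] - 1L) * 4L + cm[3, ]
    idx[is.na(cm[1, ]) | is.na(cm[2, ]) | is.na(cm[3, ])] <- NA_integer_
    idx[!is.na(idx) & tab$is_stop[pmax(idx, 1L)]] <- NA_integer_
    m[i, ] <- idx
  }
  m
}

#' Read per-family codon alignments from a directory of FASTA files
#'
#' One file per family, named `<ko_id>.fna` (configurable suffix).
#'
#' @param dir Directory containing the alignment FASTA files.
#' @param pattern Filename pattern; the family id is the filename minus suffix.
#' @return Named list of [codon_alignment()] objects.
#' @export
read_codon_alignments <- function(dir, pattern = "\\.fna$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no alignment files matching '", pattern,
                                "' in ", dir)
  alns <- lapply(files, function(f) {
    seqs <- Biostrings::readDNAStringSet(f)
    codon_alignment(sub(pattern, "", basename(f)), as.character(seqs))
  })
  names(alns) <- vapply(alns, `[[`, "", "ko_id")
  alns
}

#' Write codon alignments as per-family FASTA files
#'
#' @param families List of [codon_alignment()] objects (or a
#'   `simulated codon families` result holding `$alignments`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_codon_alignments <- function(families, dir) {
  if (!is.null(families$alignments)) families <- families$alignments
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(families, function(aln) {
    seqs <- Biostrings::DNAStringSet(aln$sequences)
    names(seqs) <- names(aln$sequences) %||%
      paste0(aln$ko_id, "_seq", seq_along(aln$sequences))
    p <- file.path(dir, paste0(aln$ko_id, ".fna"))
    Biostrings::writeXStringSet(seqs, p, width = 80L)
    p
  }, "")
  invisible(paths)
}

#' Aggregate change and site counts over a codon alignment
#'
#' Sums path-averaged (dn, ds) from [count_codon_changes()] over all unordered
#' sequence pairs and all codon columns where neither sequence has a gap or
#' ambiguity (gapped columns are skipped pairwise, standing in for
#' low-confidence-position masking). Site totals are averaged over sequences
#' within a column, then summed over columns. Codon pairs whose every
#' mutational path runs through a stop codon are dropped and counted.
#'
#' @param aln A [codon_alignment()] with at least two usable sequences.
#' @return A list with `ko_id`, `dn_changes`, `ds_changes`, `n_sites`,
#'   `s_sites`, `omega` (`(dn/n_sites)/(ds/s_sites)`, `NA` when `ds_changes`
#'   is 0), `n_pairs`, `blocked_pairs`, or `NULL` (with a warning) when fewer
#'   than two usable sequences remain.
#' @export
family_counts <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  m <- alignment_to_idx(aln)
  usable <- rowSums(!is.na(m)) > 0L
  m <- m[usable, , drop = FALSE]
  if (nrow(m) < 2L) {
    warning("family ", aln$ko_id, " has fewer than 2 usable sequences; skipped")
    return(NULL)
  }
  dt <- dnds_tables()
  # within a column, the sum of pairwise (dn, ds) over all unordered sequence
  # pairs factors over codon-type counts c: sum_{a<b} c_a c_b DN[a,b]
  # = c' DN c / 2 (DN symmetric, zero diagonal), so one tabulation plus two
  # matrix products replaces explicit pair enumeration
  L <- ncol(m)
  valid <- !is.na(m)
  key <- (col(m) - 1L) * 64L + m
  C <- matrix(tabulate(key[valid], nbins = 64L * L), 64L, L)
  dn <- sum(C * (dt$DN0 %*% C)) / 2
  ds <- sum(C * (dt$DS0 %*% C)) / 2
  n_blocked <- sum(C * (dt$blocked %*% C)) / 2
  n_col <- colMeans(matrix(dt$n_sites[m], nrow(m)), na.rm = TRUE)
  s_col <- colMeans(matrix(dt$s_sites[m], nrow(m)), na.rm = TRUE)
  n_sites <- sum(n_col, na.rm = TRUE)
  s_sites <- sum(s_col, na.rm = TRUE)
  omega <- if (ds > 0 && n_sites > 0 && s_sites > 0) {
    (dn / n_sites) / (ds / s_sites)
  } else {
    NA_real_
  }
  list(ko_id = aln$ko_id, dn_changes = dn, ds_changes = ds,
       n_sites = n_sites, s_sites = s_sites, omega = omega,
       n_pairs = nrow(m) * (nrow(m) - 1L) / 2L, blocked_pairs = n_blocked)
}

#' One-sided Fisher test for Dn enrichment against a background
#'
#' Tests the 2x2 table `[[dn, ds], [dn_bg, ds_bg]]` for enrichment of
#' nonsynonymous changes in the focal family (one-sided, greater), i.e. the
#' exact hypergeometric upper tail. Fractional (path-averaged) counts are
#' rounded half away from zero before the exact test.
#'
#' @param dn,ds Focal family change counts (may be fractional).
#' @param dn_bg,ds_bg Background change counts.
#' @return The one-sided p-value; a table with a zero margin returns 1 with
#'   attribute `degenerate = TRUE`.
#' @export
positive_selection_test <- function(dn, ds, dn_bg, ds_bg) {
  m <- matrix(round_half_away(c(dn, ds, dn_bg, ds_bg)), 2L, 2L, byrow = TRUE)
  if (any(m < 0)) stop("change counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Benjamini-Hochberg FDR adjustment with rejection set
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (step-up BH adjusted p-values) and `rejected`
#'   (logical, `q <= alpha`).
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Per-family Dn/Ds with positive-selection flags
#'
#' Runs [family_counts()] on every alignment, then tests each family for
#' enrichment of nonsynonymous changes against the pooled background with a
#' one-sided Fisher test and BH FDR control. Because summed pairwise counts
#' replicate each underlying substitution up to `n_seqs - 1` times, the exact
#' test is fed *per-pair average* counts (raw sums are reported unchanged);
#' see the methods vignette.
#'
#' @param alignments List of [codon_alignment()] objects.
#' @param alpha FDR level for the `positive` flag (default 0.05).
#' @param background `"loo"` (default) excludes the focal family from the
#'   background totals; `"all"` keeps it in.
#' @return `data.frame` with one row per usable family: change and site
#'   counts, `omega`, `fisher_p`, `q_value`, `positive` (Fisher + FDR flag),
#'   `dn_above_mean` / `ds_below_mean` (rate flags relative to the across-family
#'   mean) and `positive_strict` (their conjunction with `positive`), sorted by
#'   `q_value`.
#' @export
dnds_families <- function(alignments, alpha = 0.05,
                          background = c("loo", "all")) {
  background <- match.arg(background)
  fc <- Filter(Negate(is.null), lapply(alignments, family_counts))
  if (length(fc) == 0L) stop("no usable families")
  df <- data.frame(
    ko_id = vapply(fc, `[[`, "", "ko_id"),
    dn_changes = vapply(fc, `[[`, 0, "dn_changes"),
    ds_changes = vapply(fc, `[[`, 0, "ds_changes"),
    n_sites = vapply(fc, `[[`, 0, "n_sites"),
    s_sites = vapply(fc, `[[`, 0, "s_sites"),
    omega = vapply(fc, `[[`, 0, "omega"),
    n_pairs = vapply(fc, function(x) as.numeric(x$n_pairs), 0),
    stringsAsFactors = FALSE
  )
  # per-pair average counts de-correlate the pairwise pseudo-replication
  dn_avg <- df$dn_changes / df$n_pairs
  ds_avg <- df$ds_changes / df$n_pairs
  tot_dn <- sum(dn_avg)
  tot_ds <- sum(ds_avg)
  df$fisher_p <- vapply(seq_len(nrow(df)), function(i) {
    if (background == "loo") {
      positive_selection_test(dn_avg[i], ds_avg[i],
                              tot_dn - dn_avg[i], tot_ds - ds_avg[i])
    } else {
      positive_selection_test(dn_avg[i], ds_avg[i], tot_dn, tot_ds)
    }
  }, 0)
  adj <- fdr_adjust(df$fisher_p, alpha)
  df$q_value <- adj$q
  df$positive <- adj$rejected
  dn_rate <- df$dn_changes / df$n_sites
  ds_rate <- df$ds_changes / df$s_sites
  df$dn_above_mean <- dn_rate > mean(dn_rate)
  df$ds_below_mean <- ds_rate < mean(ds_rate)
  df$positive_strict <- df$positive & df$dn_above_mean & df$ds_below_mean
  df <- df[order(df$q_value, df$fisher_p, df$ko_id), ]
  rownames(df) <- NULL
  df
}
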