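# RPKM-like relative gene abundance, per-gene SNP density under the 10x
# valid-coverage rule, paired day0/day30 density testing (exact Wilcoxon
# signed-rank), and hypergeometric KO/pathway enrichment.

#' RPKM-like relative gene abundance
#'
#' For each gene `G_i`, `NG_i` is the read count divided by the gene length;
#' the relative abundance `RNG_i = NG_i / sum_j NG_j` renormalises within
#' each sample so the column sums to one.
#'
#' @param counts Numeric matrix (genes x samples) of aligned read counts;
#'   rownames are gene ids.
#' @param lengths Named numeric vector of gene lengths in bp (> 0).
#' @return Object of class `gene_abundance`: `ng` and `rng` matrices plus
#'   `flagged_samples` (samples with all-zero counts, whose RNG column is
#'   `NA` rather than silently 0/0).
#' @export
gene_abundance <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("length missing for some genes")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  ng <- counts / lengths
  tot <- colSums(ng)
  flagged <- colnames(counts)[tot == 0]
  if (length(flagged) > 0) {
    warning("sample(s) with all-zero counts flagged: ",
            paste(flagged, collapse = ", "))
  }
  tot[tot == 0] <- NA_real_
  rng <- sweep(ng, 2L, tot, "/")
  structure(list(ng = ng, rng = rng, flagged_samples = flagged),
            class = "gene_abundance")
}

#' Per-gene SNP density with the valid-coverage rule
#'
#' Density is the number of kept SNPs overlapping the gene span per kilobase
#' of gene length. Gene/sample combinations below `min_depth` are flagged
#' excluded (the boundary is inclusive: depth exactly `min_depth` is
#' included) and should not enter density testing.
#'
#' @param genes data.frame with `gene_id`, `genome_id`, `start`, `end` (and
#'   optionally `length`; computed from the span otherwise).
#' @param kept_snps Kept SNP calls (rows with `vtype != "SNP"` are ignored).
#' @param depth Numeric matrix (genes x samples) of mean read depth over the
#'   gene span.
#' @param min_depth Valid-coverage threshold (default 10).
#' @param genome_lengths Optional named contig lengths; when supplied, gene
#'   spans outside their contig raise a validation error.
#' @return Long data.frame: `gene_id`, `sample_id`, `n_snps`, `depth`,
#'   `density_per_kb`, `included`.
#' @export
snp_density <- function(genes, kept_snps, depth, min_depth = 10,
                        genome_lengths = NULL) {
  stopifnot(all(c("gene_id", "genome_id", "start", "end") %in% names(genes)))
  if (any(genes$end < genes$start) || any(genes$start < 1L)) {
    stop("invalid gene span (start < 1 or end < start)")
  }
  if (!is.null(genome_lengths)) {
    lim <- genome_lengths[genes$genome_id]
    if (anyNA(lim) || any(genes$end > lim)) {
      stop("gene span outside its contig")
    }
  }
  depth <- as.matrix(depth)
  if (is.null(rownames(depth)) || !all(genes$gene_id %in% rownames(depth))) {
    stop("depth matrix must have a row for every gene")
  }
  len_kb <- (genes$end - genes$start + 1L) / 1000
  snps <- kept_snps
  if (!is.null(snps$vtype)) snps <- snps[snps$vtype == "SNP", , drop = FALSE]
  gr_genes <- GenomicRanges::GRanges(
    genes$genome_id, IRanges::IRanges(genes$start, genes$end))
  samples <- colnames(depth)
  rows <- lapply(samples, function(s) {
    sub <- snps[snps$sample_id == s, , drop = FALSE]
    n <- if (nrow(sub) == 0L) {
      integer(nrow(genes))
    } else {
      gr_snp <- GenomicRanges::GRanges(sub$genome_id,
                                       IRanges::IRanges(sub$pos, sub$pos))
      GenomicRanges::countOverlaps(gr_genes, gr_snp)
    }
    d <- depth[genes$gene_id, s]
    data.frame(gene_id = genes$gene_id, sample_id = s, n_snps = n,
               depth = unname(d), density_per_kb = n / len_kb,
               included = unname(d) >= min_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment; `zeros = "pratt"` ranks them first and drops their
#' contribution). Ties take midranks. For `n` at most `exact_limit` the
#' two-sided p-value is exact - computed from the full null distribution of
#' the signed-rank statistic by convolution over doubled (hence integer)
#' midranks, doubling the smaller tail and capping at 1. Above the limit a
#' normal approximation with tie-exact variance `sum(r^2)/4` and continuity
#' correction is used.
#'
#' @param x,y Paired observations (`y` omitted: `x` are the differences).
#' @param zeros `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return List: `statistic` (W+, original midrank scale), `p_value`, `n`
#'   (differences used), `exact`, `all_zero` (`TRUE` gives p = 1, flagged).
#' @export
signed_rank_test <- function(x, y = NULL, zeros = c("wilcoxon", "pratt"),
                             exact_limit = 25) {
  zeros <- match.arg(zeros)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no usable pairs")
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE,
                all_zero = TRUE))
  }
  if (zeros == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    R2 <- as.integer(round(2 * r))
    tot <- sum(R2)
    f <- numeric(tot + 1L)
    f[1L] <- 1
    for (ri in R2) {
      g <- f
      g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] +
        f[1L:(tot + 1L - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, n = n, exact = TRUE,
                all_zero = FALSE))
  }
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  z <- (w - mu - sign(w - mu) * 0.5) / sigma
  list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))), n = n,
       exact = FALSE, all_zero = FALSE)
}

#' Pivot SNP densities into paired gene-by-subject matrices
#'
#' Entries excluded by the valid-coverage rule become `NA`; a subject enters
#' a gene's test only when both of its timepoint samples are included.
#'
#' @param density Long table from [snp_density()].
#' @param metadata data.frame with `sample_id`, `subject_id`, `timepoint`.
#' @param timepoints Length-2 character vector selecting the paired
#'   timepoints (default `c("day0", "day30")`).
#' @return List of two matrices (`a`, `b`), genes x subjects.
#' @export
density_by_timepoint <- function(density, metadata,
                                 timepoints = c("day0", "day30")) {
  stopifnot(length(timepoints) == 2L)
  meta <- metadata[metadata$timepoint %in% timepoints, , drop = FALSE]
  genes <- sort(unique(density$gene_id))
  subjects <- sort(unique(meta$subject_id))
  pick <- function(tp) {
    m <- matrix(NA_real_, length(genes), length(subjects),
                dimnames = list(genes, subjects))
    sub_meta <- meta[meta$timepoint == tp, , drop = FALSE]
    d <- density[density$sample_id %in% sub_meta$sample_id &
                   density$included, , drop = FALSE]
    subj <- sub_meta$subject_id[match(d$sample_id, sub_meta$sample_id)]
    m[cbind(d$gene_id, subj)] <- d$density_per_kb
    m
  }
  list(a = pick(timepoints[1]), b = pick(timepoints[2]))
}

#' Paired per-gene SNP-density tests
#'
#' Exact two-sided Wilcoxon signed-rank per gene on subject-paired densities
#' (normal approximation above `exact_limit` pairs), BH-adjusted across
#' genes. Genes whose paired differences are all zero get p = 1 and are
#' flagged.
#'
#' @param a,b Matrices (genes x subjects) of densities for the two
#'   timepoints, as from [density_by_timepoint()]; `NA` marks excluded
#'   entries.
#' @param zeros,exact_limit Passed to [signed_rank_test()].
#' @param min_pairs Minimum complete subject pairs for a gene to be tested
#'   (default 1).
#' @return data.frame: `gene_id`, `n_pairs`, `statistic`, `p_value`,
#'   `p_adjusted`, `all_zero`.
#' @export
paired_density_test <- function(a, b, zeros = "wilcoxon", exact_limit = 25,
                                min_pairs = 1) {
  stopifnot(identical(dim(a), dim(b)), identical(dimnames(a), dimnames(b)))
  rows <- list()
  for (g in rownames(a)) {
    ok <- !is.na(a[g, ]) & !is.na(b[g, ])
    if (sum(ok) < min_pairs) next
    res <- signed_rank_test(b[g, ok], a[g, ok], zeros = zeros,
                            exact_limit = exact_limit)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, n_pairs = sum(ok), statistic = res$statistic,
      p_value = res$p_value, all_zero = res$all_zero,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), n_pairs = integer(),
                      statistic = numeric(), p_value = numeric(),
                      all_zero = logical(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("gene_id", "n_pairs", "statistic", "p_value", "p_adjusted",
          "all_zero")]
}

#' Hypergeometric KO/pathway enrichment
#'
#' For each pathway, tests over-representation of its KO members in the
#' significant set relative to the background with the upper-tail
#' hypergeometric p-value `P(X >= x)`, BH-adjusted across pathways.
#' Pathways with no background members are skipped with a message.
#'
#' @param significant Character vector of significant KO ids (must be a
#'   subset of `background`).
#' @param background Character vector of background KO ids.
#' @param pathways data.frame with `ko_id`, `pathway_id`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, on adjusted p).
#' @return data.frame: `pathway_id`, `n_pathway` (background members),
#'   `n_hits` (significant members), `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
ko_enrichment <- function(significant, background, pathways, alpha = 0.05) {
  background <- unique(background)
  significant <- unique(significant)
  if (!all(significant %in% background)) {
    stop("significant KO set must be a subset of the background")
  }
  if (nrow(pathways) == 0L) stop("pathway map is empty")
  N <- length(background)
  n <- length(significant)
  rows <- list()
  for (pw in sort(unique(pathways$pathway_id))) {
    members <- intersect(pathways$ko_id[pathways$pathway_id == pw],
                         background)
    K <- length(members)
    if (K == 0L) {
      message("pathway ", pw, " has no background members; skipped")
      next
    }
    x <- length(intersect(significant, members))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pw, n_pathway = K, n_hits = x, p_value = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable pathways")
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
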