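# Reference-genome dereplication: per-pair median marker-gene identity as an
# ANI proxy, flat clustering at an operational 95% species threshold, and
# coverage-based representative selection.

#' Compute the per-pair ANI proxy from marker identities
#'
#' For each genome pair, the median percent identity over the shared marker
#' genes is used as a proxy for average nucleotide identity. Pairs sharing no
#' marker identity stay undefined (`NA`) and contribute no clustering edge.
#'
#' @param identities data.frame with columns `genome_a`, `genome_b`,
#'   `marker_id`, `identity_pct` (either orientation; duplicated orientations
#'   are pooled), or a `sim_identity` object.
#' @param genome_ids Optional ids to include even when absent from the table
#'   (isolated genomes become singletons downstream).
#' @return Object of class `ani_matrix`: `genome_ids` (sorted), `ani`
#'   (symmetric matrix, `NA` where undefined, diagonal 100), `n_markers`
#'   (matrix of marker counts per pair).
#' @export
compute_ani_proxy <- function(identities, genome_ids = NULL) {
  if (inherits(identities, "sim_identity")) {
    genome_ids <- unique(c(genome_ids, identities$genome_ids))
    identities <- identities$identities
  }
  stopifnot(all(c("genome_a", "genome_b", "identity_pct") %in%
                  names(identities)))
  if (nrow(identities) > 0 &&
      any(identities$identity_pct < 0 | identities$identity_pct > 100)) {
    stop("identity_pct outside [0, 100]")
  }
  ids <- sort(unique(c(genome_ids, identities$genome_a, identities$genome_b)))
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nm <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(identities) > 0) {
    a <- pmin(identities$genome_a, identities$genome_b)
    b <- pmax(identities$genome_a, identities$genome_b)
    key <- paste(a, b, sep = "\r")
    med <- tapply(identities$identity_pct, key, stats::median)
    cnt <- tapply(identities$identity_pct, key, length)
    parts <- strsplit(names(med), "\r", fixed = TRUE)
    ga <- vapply(parts, `[[`, "", 1L)
    gb <- vapply(parts, `[[`, "", 2L)
    ani[cbind(ga, gb)] <- med
    ani[cbind(gb, ga)] <- med
    nm[cbind(ga, gb)] <- as.integer(cnt)
    nm[cbind(gb, ga)] <- as.integer(cnt)
  }
  diag(ani) <- 100
  structure(list(genome_ids = ids, ani = ani, n_markers = nm),
            class = "ani_matrix")
}

# deterministic cluster labels: clusters ordered by their smallest member id
relabel_clusters <- function(membership) {
  groups <- split(names(membership), membership)
  groups <- groups[order(vapply(groups, min, ""))]
  out <- stats::setNames(
    rep(sprintf("C%03d", seq_along(groups)), lengths(groups)),
    unlist(groups, use.names = FALSE))
  out[sort(names(out))]
}

#' Cluster genomes at an ANI threshold
#'
#' Default linkage is single (connected components of the graph with an edge
#' wherever the ANI proxy is at or above the threshold) - the only flat
#' thresholding that is independent of genome input order. Undefined pairs are
#' treated as below threshold. Complete linkage is available for sensitivity
#' analysis.
#'
#' @param ani An `ani_matrix` from [compute_ani_proxy()].
#' @param threshold Percent identity threshold (default 95, the operational
#'   species boundary).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return Object of class `cluster_set`: `clusters` (named list of member
#'   vectors), `membership` (named vector genome id -> cluster label),
#'   `representative` (`NULL` until [select_representatives()]).
#' @export
cluster_genomes <- function(ani, threshold = 95,
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(ani, "ani_matrix"), threshold >= 0, threshold <= 100)
  ids <- ani$genome_ids
  if (length(ids) == 0L) {
    return(structure(list(clusters = list(), membership = character(0),
                          representative = NULL, threshold = threshold,
                          linkage = linkage),
                     class = "cluster_set"))
  }
  if (linkage == "single") {
    adj <- !is.na(ani$ani) & ani$ani >= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    membership <- stats::setNames(as.character(comp), ids)
  } else {
    d <- 100 - ani$ani
    d[is.na(d)] <- 200
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    membership <- stats::setNames(
      as.character(stats::cutree(hc, h = 100 - threshold)), ids)
  }
  membership <- relabel_clusters(membership)
  structure(list(clusters = split(names(membership), membership),
                 membership = membership, representative = NULL,
                 threshold = threshold, linkage = linkage),
            class = "cluster_set")
}

#' Select one representative genome per cluster by read coverage
#'
#' The member with the highest coverage wins; ties break to the
#' lexicographically smallest genome id. Genomes without a coverage value are
#' treated as coverage 0.
#'
#' @param clusters A `cluster_set` from [cluster_genomes()].
#' @param coverage Named numeric vector, genome id -> mean mapped read
#'   coverage (arbitrary non-negative units).
#' @return The `cluster_set` with `representative` (named vector cluster
#'   label -> genome id) and `coverage` filled in.
#' @export
select_representatives <- function(clusters, coverage) {
  stopifnot(inherits(clusters, "cluster_set"))
  ids <- names(clusters$membership)
  cov <- stats::setNames(rep(0, length(ids)), ids)
  known <- intersect(ids, names(coverage))
  cov[known] <- coverage[known]
  if (length(setdiff(ids, names(coverage))) > 0) {
    warning(length(setdiff(ids, names(coverage))),
            " genome(s) without coverage treated as coverage 0")
  }
  clusters$representative <- vapply(clusters$clusters, function(members) {
    members[order(-cov[members], members)][1L]
  }, "")
  clusters$coverage <- cov
  clusters
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$membership), "genomes in",
      length(x$clusters), "clusters (threshold", x$threshold, "%,",
      x$linkage, "linkage)\n")
  invisible(x)
}

#' Write cluster membership as TSV
#'
#' @param clusters A `cluster_set` (ideally after
#'   [select_representatives()]).
#' @param path Output TSV path.
#' @export
write_cluster_tsv <- function(clusters, path) {
  df <- data.frame(genome_id = names(clusters$membership),
                   cluster_id = unname(clusters$membership),
                   stringsAsFactors = FALSE)
  df$is_representative <- if (is.null(clusters$representative)) {
    NA
  } else {
    df$genome_id %in% clusters$representative
  }
  write_tsv(df, path)
}

#' k-mer sketch identity between marker genes of synthetic genomes
#'
#' A convenience estimator for synthetic data only: percent identity between
#' two marker sequences is approximated by the Sorensen-Dice overlap of their
#' k-mer sets, scaled to percent. This is a sketch, not an alignment (no
#' BLAST); real marker identity tables should come from an aligner.
#'
#' @param genomes A `sim_genomes` object.
#' @param k k-mer size (default 8).
#' @return data.frame in the layout accepted by [compute_ani_proxy()].
#' @export
estimate_marker_identity <- function(genomes, k = 8) {
  stopifnot(inherits(genomes, "sim_genomes"))
  mk <- genomes$marker_regions
  kmers <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  }
  rows <- list()
  for (m in unique(mk$marker_id)) {
    sub <- mk[mk$marker_id == m, , drop = FALSE]
    if (nrow(sub) < 2L) next
    seqs <- lapply(seq_len(nrow(sub)), function(i) {
      kmers(substring(genomes$sequences[[sub$genome_id[i]]],
                      sub$start[i], sub$end[i]))
    })
    cmb <- utils::combn(nrow(sub), 2L)
    for (ci in seq_len(ncol(cmb))) {
      i <- cmb[1L, ci]; j <- cmb[2L, ci]
      shared <- length(intersect(seqs[[i]], seqs[[j]]))
      denom <- length(seqs[[i]]) + length(seqs[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = min(sub$genome_id[i], sub$genome_id[j]),
        genome_b = max(sub$genome_id[i], sub$genome_id[j]),
        marker_id = m,
        identity_pct = if (denom == 0) 0 else 100 * 2 * shared / denom,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_a = character(), genome_b = character(),
                      marker_id = character(), identity_pct = numeric()))
  }
  do.call(rbind, rows)
}
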