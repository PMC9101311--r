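# Planted-cluster marker identity tables for exercising the dereplication
# module: within-cluster marker identities are drawn strictly above the
# species threshold, between-cluster identities strictly below it.

#' Simulate a per-marker pairwise identity table with planted clusters
#'
#' For every unordered genome pair and every marker, a percent identity is
#' drawn uniformly from `within_range` if both genomes belong to the same
#' planted cluster and from `between_range` otherwise. The two ranges must not
#' overlap (a shared boundary counts as overlap), so the planted partition is
#' recoverable by thresholding between them.
#'
#' @param clusters Planted partition: list of character vectors of genome ids
#'   (a single genome gives a singleton cluster and an empty identity table).
#' @param n_markers Number of marker genes scored per pair (default 40).
#' @param within_range,between_range Percent-identity ranges, each `c(lo, hi)`
#'   within \[0, 100\]; `within_range[1]` must exceed `between_range[2]`.
#' @param seed Integer seed.
#' @return List of class `sim_identity`: `identities` (data.frame `genome_a`,
#'   `genome_b`, `marker_id`, `identity_pct` with `genome_a < genome_b`),
#'   `planted_clusters` (named membership vector genome id -> cluster label).
#' @export
simulate_identity_matrix <- function(clusters, n_markers = 40,
                                     within_range = c(96, 99),
                                     between_range = c(75, 90),
                                     seed = 1) {
  stopifnot(length(within_range) == 2L, length(between_range) == 2L,
            n_markers >= 1)
  rng_ok <- function(r) all(r >= 0 & r <= 100) && r[1] <= r[2]
  if (!rng_ok(within_range) || !rng_ok(between_range)) {
    stop("identity ranges must be ordered and within [0, 100]")
  }
  if (within_range[1] <= between_range[2]) {
    stop("within-cluster and between-cluster identity ranges overlap: ",
         "within [", within_range[1], ", ", within_range[2], "] vs between [",
         between_range[1], ", ", between_range[2], "]")
  }
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids)) stop("genome ids must be unique across clusters")
  membership <- stats::setNames(
    rep(sprintf("C%03d", seq_along(clusters)),
        vapply(clusters, length, 0L)), ids)
  set.seed(seed)
  marker_ids <- sprintf("M%02d", seq_len(n_markers))
  rows <- list()
  ids_sorted <- sort(ids)
  if (length(ids_sorted) >= 2L) {
    cmb <- utils::combn(ids_sorted, 2L)
    same <- membership[cmb[1L, ]] == membership[cmb[2L, ]]
    lo <- ifelse(same, within_range[1], between_range[1])
    hi <- ifelse(same, within_range[2], between_range[2])
    n_pairs <- ncol(cmb)
    rows <- data.frame(
      genome_a = rep(cmb[1L, ], each = n_markers),
      genome_b = rep(cmb[2L, ], each = n_markers),
      marker_id = rep(marker_ids, times = n_pairs),
      identity_pct = stats::runif(n_pairs * n_markers,
                                  rep(lo, each = n_markers),
                                  rep(hi, each = n_markers)),
      stringsAsFactors = FALSE
    )
  } else {
    rows <- data.frame(genome_a = character(), genome_b = character(),
                       marker_id = character(), identity_pct = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(identities = rows, planted_clusters = membership,
                 genome_ids = ids_sorted, seed = seed),
            class = "sim_identity")
}
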