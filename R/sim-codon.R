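# Codon-family evolution at known dN/dS: sequences are mutated from a common
# stop-free ancestor; each proposed single-nucleotide change is accepted with
# probability min(1, omega) if nonsynonymous and min(1, 1/omega) if
# synonymous, and always rejected if it would create a stop codon. This
# acceptance scheme makes the realised site-normalised dN/dS equal omega on
# both sides of 1 (see the methods vignette).

# one accepted/rejected mutation round for the active (sequence, codon) slots
.mutate_step <- function(cur, omega, tab) {
  j <- sample.int(9L, length(cur), replace = TRUE)
  cand <- tab$nbr[cbind(cur, j)]
  syn <- tab$aa[cand] == tab$aa[cur]
  p_acc <- ifelse(syn, min(1, 1 / omega), min(1, omega))
  acc <- !tab$is_stop[cand] & stats::runif(length(cur)) < p_acc
  ifelse(acc, cand, cur)
}

evolve_family <- function(anc_idx, n_seqs, subs_per_codon, omega, tab) {
  n_cod <- length(anc_idx)
  m <- matrix(rep(anc_idx, each = n_seqs), nrow = n_seqs)
  hits <- matrix(stats::rpois(n_seqs * n_cod, subs_per_codon), n_seqs)
  while (any(hits > 0L)) {
    act <- which(hits > 0L)
    m[act] <- .mutate_step(m[act], omega, tab)
    hits[act] <- hits[act] - 1L
  }
  m
}

#' Simulate codon alignments at known dN/dS
#'
#' For each family, `n_seqs` sequences are evolved independently from a
#' common random stop-free ancestor of `n_codons` codons. Proposed mutations
#' are uniform over the nine single-nucleotide neighbours of the current
#' codon; proposals creating stop codons are rejected, synonymous proposals
#' are accepted with probability `min(1, 1/omega)` and nonsynonymous ones with
#' probability `min(1, omega)`. Alignments are gap-free unless
#' `gap_codons_per_seq > 0`, in which case whole codons are masked with `---`
#' (gaps are always codon-aligned).
#'
#' @param omega_map Named numeric vector: family (KO) id to true dN/dS
#'   (omega >= 0; `omega = 0` forbids nonsynonymous changes entirely).
#' @param n_seqs Sequences per family.
#' @param n_codons Codons per sequence.
#' @param subs_per_codon Expected mutation proposals per codon per sequence.
#' @param gap_codons_per_seq Number of codons per sequence randomly replaced
#'   by gap codons (default 0, off).
#' @param seed Integer seed.
#' @return List of class `sim_codon_families`: `alignments` (named list of
#'   [codon_alignment()]), `true_omega` (the input map).
#' @export
simulate_codon_families <- function(omega_map, n_seqs = 20, n_codons = 500,
                                    subs_per_codon = 0.1,
                                    gap_codons_per_seq = 0, seed = 1) {
  if (length(omega_map) == 0L) stop("omega_map must be non-empty")
  if (is.null(names(omega_map)) || any(!nzchar(names(omega_map)))) {
    stop("omega_map must be named by family id")
  }
  if (any(omega_map < 0)) stop("omega must be non-negative")
  stopifnot(n_seqs >= 2, n_codons >= 1, subs_per_codon >= 0)
  set.seed(seed)
  tab <- codon_tables()
  alignments <- vector("list", length(omega_map))
  names(alignments) <- names(omega_map)
  for (fi in seq_along(omega_map)) {
    anc <- sample(tab$sense_idx, n_codons, replace = TRUE)
    m <- evolve_family(anc, n_seqs, subs_per_codon, omega_map[[fi]], tab)
    seqs <- do.call(paste0, lapply(seq_len(n_codons),
                                   function(j) tab$codons[m[, j]]))
    if (gap_codons_per_seq > 0) {
      for (i in seq_len(n_seqs)) {
        gcod <- sample.int(n_codons, min(gap_codons_per_seq, n_codons))
        ch <- strsplit(seqs[i], "")[[1]]
        for (cj in gcod) ch[((cj - 1L) * 3L + 1L):((cj - 1L) * 3L + 3L)] <- "-"
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    names(seqs) <- sprintf("%s_seq%02d", names(omega_map)[fi],
                           seq_len(n_seqs))
    aln <- codon_alignment(names(omega_map)[fi], seqs)
    if (gap_codons_per_seq == 0) aln$idx <- m  # skip re-parsing downstream
    alignments[[fi]] <- aln
  }
  structure(list(alignments = alignments, true_omega = omega_map,
                 seed = seed),
            class = "sim_codon_families")
}
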