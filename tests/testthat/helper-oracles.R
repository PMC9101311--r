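# Independent brute-force oracles. These deliberately avoid the package's
# lookup tables: translation goes through seqinr, path enumeration is
# recursive, tail probabilities come from choose(), and the signed-rank null
# is enumerated over all sign vectors.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 11)
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

# path-averaged (dn, ds) by recursive enumeration of mutation orderings
oracle_count_changes <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L) return(list(c(0, 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[pos] <- strsplit(b, "")[[1]][pos]
      nxt <- paste(nxt, collapse = "")
      if (oracle_is_stop(nxt)) next
      step <- if (oracle_translate(nxt) == oracle_translate(cur)) {
        c(0, 1)
      } else {
        c(1, 0)
      }
      for (tail in walk(nxt, setdiff(remaining, pos))) {
        out[[length(out) + 1L]] <- step + tail
      }
    }
    out
  }
  paths <- walk(a, diffs)
  if (length(paths) == 0L) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

oracle_count_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon)
  syn <- 0L
  tot <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(bases, substr(codon, pos, pos))) {
      nb <- strsplit(codon, "")[[1]]
      nb[pos] <- alt
      nb <- paste(nb, collapse = "")
      if (oracle_is_stop(nb)) next
      tot <- tot + 1L
      if (oracle_translate(nb) == aa0) syn <- syn + 1L
    }
  }
  s <- 3 * syn / tot
  c(n_sites = 3 - s, s_sites = s)
}

all_sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons[!vapply(codons, oracle_is_stop, TRUE)]
}

# connected components by breadth-first search on a logical adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  label <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- label
      queue <- c(queue, nb)
    }
  }
  comp
}

# same-partition check that ignores labels
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# upper-tail hypergeometric P(X >= x) from binomial coefficients
oracle_hyper_upper <- function(x, N, K, n) {
  ks <- x:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# one-sided (greater) Fisher p for [[a, b], [c, d]]
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_upper(a, N = a + b + c + d, K = a + c, n = a + b)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign vectors
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, 0)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
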