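# Codon machinery shared by the selection module and the codon-family simulator.
#
# Codons are indexed 1..64 with the third position varying fastest:
#   idx = (b1-1)*16 + (b2-1)*4 + b3,  b in {A=1, C=2, G=3, T=4}.
# Translation uses the bacterial/archaeal code (translation table 11).

.codon_cache <- new.env(parent = emptyenv())

codon_index <- function(codons) {
  b1 <- match(substr(codons, 1L, 1L), DNA_BASES)
  b2 <- match(substr(codons, 2L, 2L), DNA_BASES)
  b3 <- match(substr(codons, 3L, 3L), DNA_BASES)
  (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
}

codon_tables <- function() {
  tab <- get0("tab", envir = .codon_cache)
  if (!is.null(tab)) return(tab)
  g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  code <- Biostrings::getGeneticCode("11")
  aa <- unname(code[codons])
  stopifnot(!anyNA(aa))
  is_stop <- aa == "*"
  # 9 single-nucleotide neighbours of each codon, column order: position 1
  # alternatives first, then position 2, then position 3
  nbr <- matrix(0L, 64L, 9L)
  for (i in seq_len(64L)) {
    ch <- c(g$p1[i], g$p2[i], g$p3[i])
    k <- 0L
    for (pos in 1:3) {
      for (alt in DNA_BASES[DNA_BASES != ch[pos]]) {
        k <- k + 1L
        nx <- ch
        nx[pos] <- alt
        nbr[i, k] <- codon_index(paste0(nx[1], nx[2], nx[3]))
      }
    }
  }
  tab <- list(codons = codons, aa = aa, is_stop = is_stop,
              stop_idx = which(is_stop), sense_idx = which(!is_stop),
              nbr = nbr)
  assign("tab", tab, envir = .codon_cache)
  tab
}

# orderings of the differing positions for path enumeration (d <= 3)
.position_orders <- list(
  matrix(1L, 1L, 1L),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

check_codon <- function(codon, arg = "codon") {
  if (length(codon) != 1L || is.na(codon) || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    stop(sprintf("%s must be a single 3-letter string over A/C/G/T, got '%s'",
                 arg, paste(codon, collapse = ",")), call. = FALSE)
  }
  tab <- codon_tables()
  if (tab$is_stop[codon_index(codon)]) {
    stop(sprintf("%s '%s' is a stop codon (translation table 11)", arg, codon),
         call. = FALSE)
  }
  invisible(codon)
}

#' Count synonymous and nonsynonymous changes between two codons
#'
#' Enumerates every ordering of the differing positions (at most 3, hence at
#' most 6 orderings), classifies each single-nucleotide step as synonymous or
#' nonsynonymous under translation table 11, discards orderings whose
#' intermediate codons are stop codons, and averages the per-path counts over
#' the surviving orderings (NG86-style path averaging).
#'
#' @param codon_a,codon_b Gap-free, non-stop codons as 3-letter strings.
#' @return Named numeric vector `c(dn = , ds = )`. `dn + ds` equals the number
#'   of differing positions whenever at least one path survives. If every path
#'   passes through a stop codon both components are `NA` (the caller should
#'   exclude such pairs).
#' @examples
#' count_codon_changes("GTT", "GTA")  # synonymous: c(dn = 0, ds = 1)
#' count_codon_changes("TTT", "GTA")  # path-averaged: c(dn = 1.5, ds = 0.5)
#' @export
count_codon_changes <- function(codon_a, codon_b) {
  check_codon(codon_a, "codon_a")
  check_codon(codon_b, "codon_b")
  tab <- codon_tables()
  a <- strsplit(codon_a, "", fixed = FALSE)[[1]]
  b <- strsplit(codon_b, "", fixed = FALSE)[[1]]
  diffs <- which(a != b)
  d <- length(diffs)
  if (d == 0L) return(c(dn = 0, ds = 0))
  orders <- .position_orders[[d]]
  dn_paths <- numeric(0)
  ds_paths <- numeric(0)
  for (r in seq_len(nrow(orders))) {
    cur <- a
    dn <- 0
    ds <- 0
    ok <- TRUE
    for (pos in diffs[orders[r, ]]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      i_cur <- codon_index(paste(cur, collapse = ""))
      i_nxt <- codon_index(paste(nxt, collapse = ""))
      if (tab$is_stop[i_nxt]) {
        ok <- FALSE
        break
      }
      if (tab$aa[i_nxt] == tab$aa[i_cur]) ds <- ds + 1 else dn <- dn + 1
      cur <- nxt
    }
    if (ok) {
      dn_paths <- c(dn_paths, dn)
      ds_paths <- c(ds_paths, ds)
    }
  }
  if (length(dn_paths) == 0L) return(c(dn = NA_real_, ds = NA_real_))
  c(dn = mean(dn_paths), ds = mean(ds_paths))
}

#' Count nonsynonymous and synonymous sites of a codon
#'
#' Each of the nine single-nucleotide neighbours is classified as synonymous or
#' nonsynonymous under translation table 11; neighbours that are stop codons are
#' excluded from the denominator. The synonymous site count is three times the
#' synonymous fraction among the remaining neighbours.
#'
#' @param codon Gap-free, non-stop codon as a 3-letter string.
#' @return Named numeric vector `c(n_sites = , s_sites = )` summing to 3.
#' @examples
#' count_sites("TTT")  # c(n_sites = 8/3, s_sites = 1/3)
#' count_sites("TGG")  # tryptophan: s_sites = 0
#' @export
count_sites <- function(codon) {
  check_codon(codon)
  tab <- codon_tables()
  i <- codon_index(codon)
  nb <- tab$nbr[i, ]
  keep <- !tab$is_stop[nb]
  syn_frac <- mean(tab$aa[nb[keep]] == tab$aa[i])
  s <- 3 * syn_frac
  c(n_sites = 3 - s, s_sites = s)
}

# 64x64 lookup matrices of path-averaged (dn, ds) for every ordered pair of
# sense codons (NA where either codon is a stop, or where every mutational
# path is blocked by stops), plus per-codon site vectors. Built once per
# session from count_codon_changes()/count_sites() and cached.
dnds_tables <- function() {
  dt <- get0("dnds", envir = .codon_cache)
  if (!is.null(dt)) return(dt)
  tab <- codon_tables()
  DN <- DS <- matrix(NA_real_, 64L, 64L)
  for (a in tab$sense_idx) {
    ca <- tab$codons[a]
    for (b in tab$sense_idx) {
      r <- count_codon_changes(ca, tab$codons[b])
      DN[a, b] <- r[["dn"]]
      DS[a, b] <- r[["ds"]]
    }
  }
  NS <- SS <- rep(NA_real_, 64L)
  for (a in tab$sense_idx) {
    s <- count_sites(tab$codons[a])
    NS[a] <- s[["n_sites"]]
    SS[a] <- s[["s_sites"]]
  }
  # zero-filled copies and a blocked-pair indicator support the quadratic-form
  # aggregation in family_counts()
  blocked <- is.na(DN)
  blocked[tab$stop_idx, ] <- FALSE
  blocked[, tab$stop_idx] <- FALSE
  DN0 <- DN
  DS0 <- DS
  DN0[is.na(DN0)] <- 0
  DS0[is.na(DS0)] <- 0
  dt <- list(DN = DN, DS = DS, DN0 = DN0, DS0 = DS0,
             blocked = blocked + 0, n_sites = NS, s_sites = SS)
  assign("dnds", dt, envir = .codon_cache)
  dt
}
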