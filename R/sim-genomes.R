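# Synthetic multi-genome communities: random genomes with non-overlapping CDS
# gene models, single-copy marker flags and KO family labels.

#' Simulate a set of prokaryote-like genomes with gene models
#'
#' Generates `n_genomes` random genome sequences at a target GC content and
#' places non-overlapping CDS gene models on both strands. Each gene length is
#' a multiple of three; exactly `n_marker_genes` genes per genome are flagged
#' as universal single-copy markers, with marker slot ids (`M01`, `M02`, ...)
#' assigned in genomic order so that the k-th marker is comparable across
#' genomes. Gene KO labels are drawn from a configurable pool. Deterministic
#' under a fixed seed.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Genome length in bp (all genomes equal length).
#' @param n_genes_per_genome Number of CDS genes per genome.
#' @param n_marker_genes Number of single-copy marker genes per genome
#'   (default 40).
#' @param gc_content Target GC fraction in (0, 1).
#' @param gene_length_range Min/max gene length in bp; lengths are rounded to
#'   multiples of 3.
#' @param ko_pool Character vector of KO ids genes are labelled from; default
#'   is a pool of `max(10, n_genes_per_genome %/% 2)` ids.
#' @param seed Integer seed.
#' @return Object of class `sim_genomes`: `sequences` (named character
#'   vector), `genes` (data.frame: genome_id, gene_id, start, end, strand,
#'   length, ko_id, marker, marker_id), `marker_regions` (data.frame:
#'   genome_id, marker_id, start, end).
#' @export
simulate_genomes <- function(n_genomes = 5, genome_length = 50000,
                             n_genes_per_genome = 60, n_marker_genes = 40,
                             gc_content = 0.5,
                             gene_length_range = c(300, 900),
                             ko_pool = NULL, seed = 1) {
  stopifnot(n_genomes >= 1, gc_content > 0, gc_content < 1,
            n_marker_genes >= 0, n_marker_genes <= n_genes_per_genome)
  if (genome_length < n_genes_per_genome * gene_length_range[1]) {
    stop("genome_length ", genome_length, " too short for ",
         n_genes_per_genome, " genes of minimum length ",
         gene_length_range[1])
  }
  set.seed(seed)
  if (is.null(ko_pool)) {
    ko_pool <- sprintf("K%05d", 10000 + seq_len(max(10, n_genes_per_genome %/% 2)))
  }
  base_prob <- c((1 - gc_content) / 2, gc_content / 2,
                 gc_content / 2, (1 - gc_content) / 2)
  lmin <- 3L * (gene_length_range[1] %/% 3L)
  lmax <- 3L * (gene_length_range[2] %/% 3L)
  genome_ids <- sprintf("G%03d", seq_len(n_genomes))
  sequences <- character(n_genomes)
  names(sequences) <- genome_ids
  genes <- vector("list", n_genomes)
  for (gi in seq_len(n_genomes)) {
    sequences[gi] <- paste(sample(DNA_BASES, genome_length, replace = TRUE,
                                  prob = base_prob), collapse = "")
    lens <- 3L * sample(seq(lmin %/% 3L, lmax %/% 3L),
                        n_genes_per_genome, replace = TRUE)
    if (sum(lens) > genome_length) {
      stop("genome_length ", genome_length, " too short for the sampled gene ",
           "lengths (need ", sum(lens), " bp)")
    }
    slack <- genome_length - sum(lens)
    gaps <- as.vector(stats::rmultinom(1, slack,
                                       rep(1, n_genes_per_genome + 1L)))
    starts <- cumsum(gaps[seq_len(n_genes_per_genome)] +
                       c(0L, lens[-n_genes_per_genome])) + 1L
    marker_slots <- sort(sample.int(n_genes_per_genome, n_marker_genes))
    is_marker <- seq_len(n_genes_per_genome) %in% marker_slots
    marker_id <- rep(NA_character_, n_genes_per_genome)
    marker_id[is_marker] <- sprintf("M%02d", seq_len(n_marker_genes))
    genes[[gi]] <- data.frame(
      genome_id = genome_ids[gi],
      gene_id = sprintf("%s_g%03d", genome_ids[gi],
                        seq_len(n_genes_per_genome)),
      start = starts,
      end = starts + lens - 1L,
      strand = sample(c("+", "-"), n_genes_per_genome, replace = TRUE),
      length = lens,
      ko_id = sample(ko_pool, n_genes_per_genome, replace = TRUE),
      marker = is_marker,
      marker_id = marker_id,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes)
  stopifnot(all(genes$end <= genome_length), all(genes$length %% 3L == 0L))
  mk <- genes[genes$marker, c("genome_id", "marker_id", "start", "end")]
  rownames(mk) <- NULL
  structure(list(sequences = sequences, genes = genes, marker_regions = mk,
                 genome_length = genome_length, ko_pool = ko_pool,
                 seed = seed),
            class = "sim_genomes")
}

#' @export
print.sim_genomes <- function(x, ...) {
  cat("sim_genomes:", length(x$sequences), "genomes x", x$genome_length,
      "bp;", nrow(x$genes), "genes (",
      sum(x$genes$marker), "marker-flagged )\n")
  invisible(x)
}

genome_lengths <- function(genomes) {
  if (inherits(genomes, "sim_genomes")) {
    stats::setNames(rep(genomes$genome_length, length(genomes$sequences)),
                    names(genomes$sequences))
  } else {
    nchar(genomes)
  }
}

#' Write simulated genomes as FASTA
#'
#' @param genomes A `sim_genomes` object or named character vector.
#' @param path Output FASTA path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- if (inherits(genomes, "sim_genomes")) genomes$sequences else genomes
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' CDS features with `ID`, `ko_id`, `marker` (0/1) and `marker_id` attributes.
#'
#' @param genes A `sim_genomes` object or its `genes` data.frame.
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(genes, path) {
  if (inherits(genes, "sim_genomes")) genes <- genes$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$genome_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$ko_id <- genes$ko_id
  gr$marker <- ifelse(genes$marker, "1", "0")
  gr$marker_id <- ifelse(is.na(genes$marker_id), "NA", genes$marker_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models written by [write_gene_models()]
#'
#' @param path GFF3 path.
#' @return data.frame in the same layout as `sim_genomes$genes`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = gr$ID,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start + 1L
  df$ko_id <- gr$ko_id
  df$marker <- gr$marker == "1"
  df$marker_id <- ifelse(gr$marker_id == "NA", NA_character_, gr$marker_id)
  df[order(df$genome_id, df$start), , drop = FALSE]
}

#' Assign KO ids to pathways for enrichment testing
#'
#' Splits a KO pool into `n_pathways` pathways of roughly equal size (each KO
#' belongs to exactly one pathway). A convenience generator for synthetic
#' enrichment inputs.
#'
#' @param ko_pool Character vector of KO ids.
#' @param n_pathways Number of pathways.
#' @param seed Integer seed.
#' @return data.frame with `ko_id`, `pathway_id`.
#' @export
simulate_ko_pathways <- function(ko_pool, n_pathways = 5, seed = 1) {
  stopifnot(n_pathways >= 1)
  set.seed(seed)
  pw <- sprintf("P%03d", sample(rep_len(seq_len(n_pathways),
                                        length(ko_pool))))
  data.frame(ko_id = ko_pool, pathway_id = pw, stringsAsFactors = FALSE)
}
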