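`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (used only to integerise fractional change counts
# for the exact test; raw fractional counts are preserved everywhere else)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}
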