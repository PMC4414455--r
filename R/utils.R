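#' @useDynLib mirstress, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats rnbinom rpois rbinom runif setNames dnbinom pnbinom p.adjust
#' @importFrom utils write.table
NULL

# reverse complement for plain character vectors (DNA alphabet)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Render a DNA sequence in RNA notation
#'
#' The pipeline works internally in the DNA alphabet; reports use RNA
#' notation (U for T) as is conventional for miRNA sequences.
#'
#' @param x character vector of DNA sequences.
#' @return The same sequences with T replaced by U.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' GC content of a sequence, in percent
#'
#' @param seq nucleotide sequence (character scalar).
#' @return GC percentage in (0, 100).
#' @export
gc_percent <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

# deterministic TSV writer (fixed formatting so seeded runs are
# byte-identical)
write_tsv_det <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
}

# named character vector -> FASTA file
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# reads: data.frame(seq, qual); FASTQ Sanger Phred+33
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    ids <- sprintf("@read_%d", seq_len(nrow(reads)))
    out <- paste(ids, reads$seq, "+", reads$qual, sep = "\n")
    writeLines(out, con)
  }
  invisible(path)
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(seq = lines[idx + 1], qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

# Phred+33 quality string -> integer scores
phred_scores <- function(qual) utf8ToInt(qual) - 33L
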