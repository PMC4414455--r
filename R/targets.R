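# miRNA target prediction by complementarity expectation scoring.
#
# Plant miRNAs pair near-perfectly with their mRNA targets, so targets are
# found by scanning transcript windows for complementarity to the miRNA:
# each aligned miRNA position contributes 0 (Watson-Crick), 0.5 (G:U
# wobble, displayed "o", not a mismatch) or 1.0 (mismatch, displayed "x"),
# penalties doubled over the seed span (miRNA positions 2-13 from the 5'
# end); one single-nucleotide bulge is allowed at cost 2.0. The expectation
# is the penalty sum; sites at or below the cutoff (default 3.0) are
# reported with their hybrid duplex MFE.

#' Target-scoring weights
#'
#' @param mismatch,wobble,gap per-position penalties (defaults 1.0, 0.5,
#'   2.0).
#' @param seed_start,seed_end 1-based miRNA seed span over which penalties
#'   are multiplied by `seed_mult` (defaults 2-13, x2).
#' @param seed_mult seed multiplier.
#' @return List of scoring constants for [score_site()] / [scan_targets()].
#' @export
target_weights <- function(mismatch = 1.0, wobble = 0.5, gap = 2.0,
                           seed_start = 2L, seed_end = 13L,
                           seed_mult = 2.0) {
  list(mismatch = mismatch, wobble = wobble, gap = gap,
       seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
       seed_mult = seed_mult)
}

# pairing class of miRNA base vs target base (both sense): 2 WC, 1 GU, 0 mm
.pair_class <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "C" & t == "G") |
    (m == "G" & t == "C") | (m == "T" & t == "A")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, 2L, ifelse(gu, 1L, 0L))
}

#' Score one miRNA/target window alignment
#'
#' Aligns the miRNA (5' to 3') against a transcript window (sense strand)
#' read antiparallel. The window may be one nucleotide shorter or longer
#' than the miRNA, in which case the best placement of a single bulge is
#' chosen.
#'
#' @param mirna miRNA sequence, 5' to 3' (DNA or RNA alphabet).
#' @param window target window sequence (transcript sense strand), length
#'   within 1 nt of the miRNA length.
#' @param weights scoring constants from [target_weights()].
#' @return A list with `expectation` and `alignment`, a three-row character
#'   vector: miRNA 5'->3', pairing symbols (`|` Watson-Crick, `o` G:U, `x`
#'   mismatch, space at bulges), target 3'->5'.
#' @export
score_site <- function(mirna, window, weights = target_weights()) {
  m <- chartr("Uu", "Tt", toupper(mirna))
  w <- chartr("Uu", "Tt", toupper(window))
  L <- nchar(m); Lp <- nchar(w)
  if (abs(Lp - L) > 1) {
    stop("score_site: window length must be within 1 nt of the miRNA")
  }
  res <- score_window_cpp(as.integer(seq_to_codes(m)),
                          as.integer(seq_to_codes(w)), weights)
  mch <- strsplit(m, "")[[1]]
  wch <- rev(strsplit(w, "")[[1]])  # target displayed 3'->5'
  if (res$gaptype == 1L) {           # extra (bulged) target base
    g <- res$gappos
    mrow <- append(mch, "-", after = g)
    trow <- wch
  } else if (res$gaptype == 2L) {    # bulged miRNA base
    g <- res$gappos
    mrow <- mch
    trow <- append(wch, "-", after = g - 1L)
  } else {
    mrow <- mch; trow <- wch
  }
  sym <- character(length(mrow))
  for (k in seq_along(mrow)) {
    if (mrow[k] == "-" || trow[k] == "-") { sym[k] <- " "; next }
    cls <- .pair_class(mrow[k], trow[k])
    sym[k] <- c("x", "o", "|")[cls + 1L]
  }
  list(expectation = res$score,
       alignment = c(paste0("miRNA  5' ", as_rna(paste(mrow, collapse = "")),
                            " 3'"),
                     paste0("          ", paste(sym, collapse = "")),
                     paste0("target 3' ", as_rna(paste(trow, collapse = "")),
                            " 5'")))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every transcript window whose expectation is at or below `cutoff` is
#' reported; overlapping windows of the same miRNA on the same transcript
#' are reduced to the best-scoring one. Each site is annotated with the
#' duplex hybridization MFE from [duplex_mfe()].
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcriptome named character vector of transcripts (or FASTA
#'   path).
#' @param cutoff maximum reported expectation (default 3.0).
#' @param weights scoring constants from [target_weights()].
#' @return data.frame with one row per site: `mirna`, `unigene`, `start`,
#'   `end` (0-based half-open on the transcript), `expectation`,
#'   `duplex_mfe` and the three alignment rows.
#' @export
scan_targets <- function(mirnas, transcriptome, cutoff = 3.0,
                         weights = target_weights()) {
  if (cutoff <= 0) stop("scan_targets: cutoff must be positive")
  if (is.character(transcriptome) && length(transcriptome) == 1 &&
      file.exists(transcriptome)) transcriptome <- read_fasta(transcriptome)
  out <- list()
  for (mi in seq_along(mirnas)) {
    mseq <- chartr("Uu", "Tt", toupper(mirnas[[mi]]))
    mcodes <- as.integer(seq_to_codes(mseq))
    for (ti in seq_along(transcriptome)) {
      tseq <- toupper(transcriptome[[ti]])
      hits <- scan_transcript_cpp(mcodes, as.integer(seq_to_codes(tseq)),
                                  weights, cutoff)
      if (!nrow(hits)) next
      # reduce overlapping windows to the best-scoring one
      hits <- hits[order(hits$score, hits$start), , drop = FALSE]
      kept <- logical(0)
      keep_rows <- list()
      occupied <- integer(0)
      for (r in seq_len(nrow(hits))) {
        span <- seq.int(hits$start[r], hits$start[r] + hits$wlen[r] - 1L)
        if (any(span %in% occupied)) next
        occupied <- c(occupied, span)
        keep_rows[[length(keep_rows) + 1L]] <- hits[r, , drop = FALSE]
      }
      hits <- do.call(rbind, keep_rows)
      for (r in seq_len(nrow(hits))) {
        wseq <- substr(tseq, hits$start[r] + 1L,
                       hits$start[r] + hits$wlen[r])
        sc <- score_site(mseq, wseq, weights)
        out[[length(out) + 1L]] <- data.frame(
          mirna = names(mirnas)[mi], unigene = names(transcriptome)[ti],
          start = hits$start[r], end = hits$start[r] + hits$wlen[r],
          expectation = sc$expectation,
          duplex_mfe = duplex_mfe(mseq, wseq),
          aln_mirna = sc$alignment[1], aln_symbols = sc$alignment[2],
          aln_target = sc$alignment[3], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(mirna = character(0), unigene = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0), duplex_mfe = numeric(0),
                      aln_mirna = character(0), aln_symbols = character(0),
                      aln_target = character(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$mirna, res$unigene, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
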