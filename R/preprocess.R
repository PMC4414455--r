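# Read cleaning, tag collapsing and the library composition summaries.

#' Trim the 3' sequencing adapter from reads
#'
#' Finds the left-most occurrence of the adapter's first 8 nt in each read
#' and returns the insert upstream of it. When no full 8-mer is present, the
#' longest (>= 6 nt) prefix of the adapter matching the read's 3' end is
#' used. Reads with no recognizable adapter are dropped (the insert
#' boundary is unknowable in a single-end small-RNA protocol), as are reads
#' whose insert is empty (adapter-adapter ligation).
#'
#' @param read character vector of read sequences.
#' @param adapter3 3' adapter sequence (>= 6 nt).
#' @return Character vector of inserts; `NA` where no insert was recovered.
#' @export
trim_adapter <- function(read, adapter3) {
  if (nchar(adapter3) < 6) stop("adapter3 must be at least 6 nt")
  key <- substr(adapter3, 1, 8)
  pos <- regexpr(key, read, fixed = TRUE)
  out <- rep(NA_character_, length(read))
  hit <- pos > 1
  out[hit] <- substr(read[hit], 1, pos[hit] - 1)
  # pos == 1: adapter-adapter ligation, no insert -> NA
  miss <- pos < 0
  if (any(miss)) {
    n <- nchar(read)
    for (k in seq(min(nchar(key) - 1L, 7L), 6L)) {
      cand <- miss & n > k &
        substr(read, n - k + 1L, n) == substr(adapter3, 1, k)
      out[cand] <- substr(read[cand], 1, n[cand] - k)
      miss <- miss & !cand
    }
  }
  out
}

#' Clean a raw small-RNA library
#'
#' Applies the standard small-RNA read filters in a fixed order: (1) low
#' quality (more than `qual_frac` of bases under Phred `qual_min`, or any
#' N), (2) 5' adapter contaminant (read starts with the tail of the 5'
#' adapter, <= 1 mismatch over 8 nt), (3) 3' adapter trimming, dropping
#' reads without a recoverable insert, (4) poly(A) inserts (>= 80% A or
#' ending in a run of >= 8 A), (5) length, keeping inserts of
#' `min_len`-`max_len` nt. Each removed read is counted once, at the first
#' failing rule.
#'
#' @param reads data.frame with columns `seq` and (optionally) `qual`
#'   (Sanger Phred+33), or a character vector of sequences.
#' @param adapter3,adapter5 adapter sequences.
#' @param min_len,max_len insert length window kept (defaults 15 and 30).
#' @param qual_min,qual_frac quality filter parameters.
#' @param polyA_frac,polyA_run poly(A) filter parameters.
#' @return A list with `inserts` (clean insert sequences) and `stats`, a
#'   list with `raw_reads`, `removed_by_reason` (named vector: low_quality,
#'   contaminant_5p, no_insert, polyA, too_short, too_long) and
#'   `clean_reads`; the counts always reconcile.
#' @export
clean_library <- function(reads, adapter3, adapter5 = NULL,
                          min_len = 15L, max_len = 30L,
                          qual_min = 20L, qual_frac = 0.1,
                          polyA_frac = 0.8, polyA_run = 8L) {
  if (is.character(reads)) reads <- data.frame(seq = reads, qual = NA)
  seqs <- toupper(reads$seq)
  qual <- reads$qual
  n_raw <- length(seqs)
  removed <- c(low_quality = 0L, contaminant_5p = 0L, no_insert = 0L,
               polyA = 0L, too_short = 0L, too_long = 0L)
  alive <- rep(TRUE, n_raw)

  # 1. quality: >qual_frac of bases below qual_min, or any N
  bad_q <- grepl("N", seqs, fixed = TRUE)
  if (!all(is.na(qual))) {
    # characters encoding Phred < qual_min are ASCII 33..(32+qual_min)
    low_class <- sprintf("[^%s-~]", intToUtf8(33L + qual_min))
    n_low <- nchar(gsub(low_class, "", qual))  # bases at/above threshold
    frac_low <- 1 - n_low / nchar(qual)
    bad_q <- bad_q | (!is.na(qual) & frac_low > qual_frac)
  }
  removed["low_quality"] <- sum(alive & bad_q)
  alive <- alive & !bad_q

  # 2. 5' contaminant: first 8 nt match the 5' adapter tail with <=1 mismatch
  if (!is.null(adapter5) && nchar(adapter5) >= 8) {
    tail5 <- substr(adapter5, nchar(adapter5) - 7L, nchar(adapter5))
    mm <- rep(0L, n_raw)
    for (p in 1:8) {
      mm <- mm + (substr(seqs, p, p) != substr(tail5, p, p))
    }
    contam <- nchar(seqs) >= 8 & mm <= 1L
    removed["contaminant_5p"] <- sum(alive & contam)
    alive <- alive & !contam
  }

  # 3. adapter trim; no adapter or empty insert -> no_insert
  inserts <- trim_adapter(seqs, adapter3)
  no_ins <- is.na(inserts)
  removed["no_insert"] <- sum(alive & no_ins)
  alive <- alive & !no_ins

  # 4. poly(A)
  a_frac <- ifelse(alive, nchar(gsub("[^A]", "", inserts)) /
                     pmax(1L, nchar(inserts)), 0)
  polyA <- alive & (a_frac >= polyA_frac |
                      grepl(sprintf("A{%d}$", polyA_run), inserts))
  removed["polyA"] <- sum(polyA)
  alive <- alive & !polyA

  # 5. length window
  len <- nchar(inserts)
  short <- alive & len < min_len
  removed["too_short"] <- sum(short)
  alive <- alive & !short
  long <- alive & len > max_len
  removed["too_long"] <- sum(long)
  alive <- alive & !long

  clean <- inserts[alive]
  stats <- list(raw_reads = n_raw, removed_by_reason = removed,
                clean_reads = length(clean))
  stopifnot(stats$raw_reads == stats$clean_reads + sum(removed))
  list(inserts = clean, stats = stats)
}

#' Collapse clean inserts into unique sequence tags
#'
#' Counts the occurrences of each unique insert sequence per library. Tags
#' are returned in a deterministic order: descending total count, ties
#' broken alphabetically.
#'
#' @param inserts_ck,inserts_cd character vectors of clean inserts from the
#'   control (CK) and treated (Cd) libraries.
#' @return data.frame with columns `sequence`, `count_ck`, `count_cd`.
#' @export
collapse_tags <- function(inserts_ck, inserts_cd = character(0)) {
  all_seq <- sort(unique(c(inserts_ck, inserts_cd)))
  if (!length(all_seq)) {
    return(data.frame(sequence = character(0), count_ck = integer(0),
                      count_cd = integer(0), stringsAsFactors = FALSE))
  }
  ck <- table(factor(inserts_ck, levels = all_seq))
  cd <- table(factor(inserts_cd, levels = all_seq))
  out <- data.frame(sequence = all_seq, count_ck = as.integer(ck),
                    count_cd = as.integer(cd), stringsAsFactors = FALSE)
  ord <- order(-(out$count_ck + out$count_cd), out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(sum(out$count_ck) == length(inserts_ck),
            sum(out$count_cd) == length(inserts_cd))
  out
}

#' Length distribution of small RNA tags
#'
#' Per-library percentage of reads (or of unique tags) at each length over
#' the conventional 14-30 nt plot range.
#'
#' @param tags tag table from [collapse_tags()].
#' @param by `"total"` weights each tag by its read count (redundant
#'   sequences); `"unique"` counts each distinct tag once.
#' @return data.frame with columns `length`, `ck_percent`, `cd_percent`;
#'   each percentage column sums to 100 (when the library is non-empty).
#' @export
length_distribution <- function(tags, by = c("total", "unique")) {
  by <- match.arg(by)
  lens <- 14:30
  len <- nchar(tags$sequence)
  w_ck <- if (by == "total") tags$count_ck else as.integer(tags$count_ck > 0)
  w_cd <- if (by == "total") tags$count_cd else as.integer(tags$count_cd > 0)
  ck <- vapply(lens, function(l) sum(w_ck[len == l]), numeric(1))
  cd <- vapply(lens, function(l) sum(w_cd[len == l]), numeric(1))
  data.frame(length = lens,
             ck_percent = if (sum(ck) > 0) 100 * ck / sum(ck) else ck,
             cd_percent = if (sum(cd) > 0) 100 * cd / sum(cd) else cd)
}

#' First-nucleotide bias of small RNA tags
#'
#' Fraction of unique tags of each length (18-25 nt) starting with each
#' base; plant mature miRNAs are strongly biased toward a 5' U.
#'
#' @param tags tag table from [collapse_tags()].
#' @return data.frame with columns `length`, `A`, `C`, `G`, `U`; rows sum
#'   to 1. Lengths with no tags are omitted.
#' @export
first_base_bias <- function(tags) {
  len <- nchar(tags$sequence)
  first <- substr(tags$sequence, 1, 1)
  rows <- lapply(18:25, function(l) {
    sel <- len == l
    if (!any(sel)) return(NULL)
    f <- table(factor(first[sel], levels = c("A", "C", "G", "T")))
    p <- as.numeric(f) / sum(f)
    data.frame(length = l, A = p[1], C = p[2], G = p[3], U = p[4])
  })
  do.call(rbind, rows)
}
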