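# Conserved and novel miRNA identification.
#
# Conserved miRNAs: tags matched to known mature miRNAs within two
# substitutions (no indels, length within +/- 2 nt), clustered per
# reference, the dominant-count member taken as the real sequence and
# expression summed over the cluster. Novel miRNAs: unannotated tags that
# map perfectly to transcripts are folded in windows around the hit; a
# candidate precursor must satisfy plant hairpin criteria (mature wholly in
# one arm, pairing, MFE and MFEI thresholds, 68-300 nt).

# best sliding Hamming alignment of the shorter sequence inside the longer;
# returns mismatches and the offset of `a` relative to `b` (a_start - b_start)
.slide_hamming <- function(a, b) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  swap <- length(ca) > length(cb)
  if (swap) { tmp <- ca; ca <- cb; cb <- tmp }
  ns <- length(ca); nl <- length(cb)
  best <- ns + 1L; best_off <- 0L
  for (off in 0:(nl - ns)) {
    mm <- sum(ca != cb[(off + 1L):(off + ns)])
    if (mm < best) { best <- mm; best_off <- off }
  }
  # offset of a's start relative to b's start
  list(mismatches = best, offset = if (swap) best_off else -best_off)
}

#' Match tags against known mature miRNAs within two mismatches
#'
#' A tag matches a reference mature miRNA when their lengths differ by at
#' most `len_tol` nt and the best sliding (ungapped) alignment of the
#' shorter inside the longer has at most `max_mismatch` substitutions. The
#' best hit per tag is kept (fewest mismatches, ties to the alphabetically
#' first reference name).
#'
#' @param tags tag table (columns `sequence`, `count_ck`, `count_cd`).
#' @param mature_reference named character vector of known mature miRNAs
#'   (miRBase-style), DNA or RNA alphabet.
#' @param max_mismatch substitution bound (default 2).
#' @param len_tol length difference tolerance in nt (default 2).
#' @return data.frame with columns `sequence`, `ref`, `mismatches`,
#'   `count_ck`, `count_cd`.
#' @export
match_conserved <- function(tags, mature_reference, max_mismatch = 2L,
                            len_tol = 2L) {
  refs <- chartr("Uu", "Tt", toupper(mature_reference))
  ref_len <- nchar(refs)
  seqs <- tags$sequence
  lens <- nchar(seqs)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    cand <- which(abs(ref_len - lens[i]) <= len_tol)
    if (!length(cand)) next
    best_mm <- max_mismatch + 1L; best_ref <- NA_character_
    for (r in cand[order(names(refs)[cand])]) {
      mm <- .slide_hamming(seqs[i], refs[r])$mismatches
      if (mm < best_mm) { best_mm <- mm; best_ref <- names(refs)[r] }
    }
    if (best_mm <= max_mismatch) {
      rows[[i]] <- data.frame(sequence = seqs[i], ref = best_ref,
                              mismatches = best_mm,
                              count_ck = tags$count_ck[i],
                              count_cd = tags$count_cd[i],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), ref = character(0),
                      mismatches = integer(0), count_ck = integer(0),
                      count_cd = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# does a member tag pass the class-specific expression-summation rule,
# relative to the cluster's mature/reference sequence?
.passes_class_rule <- function(tag, ref, rule, end_zone = 3L,
                               max_mm = if (rule == "conserved") 2L else 3L) {
  al <- .slide_hamming(tag, ref)
  ca <- utf8ToInt(chartr("U", "T", toupper(tag)))
  cb <- utf8ToInt(chartr("U", "T", toupper(ref)))
  swap <- length(ca) > length(cb)
  # positions of substitutions in coordinates of the shorter sequence
  s <- if (swap) cb else ca
  l <- if (swap) ca else cb
  off <- abs(al$offset)
  aligned_l <- l[(off + 1L):(off + length(s))]
  mm_pos <- which(s != aligned_l)
  if (rule == "conserved") return(length(mm_pos) <= max_mm)
  # novel rule: substitutions only in the outermost end_zone nt of each end
  # of the mature reference, none in the middle; length difference counts
  # toward the end mismatches
  if (swap) {
    # tag longer than mature: extensions at the ends
    ext5 <- off; ext3 <- length(ca) - length(cb) - off
    mm_ref_pos <- mm_pos  # aligned block covers whole reference
    n_core <- length(cb)
  } else {
    ext5 <- 0L; ext3 <- 0L
    mm_ref_pos <- mm_pos + off
    n_core <- length(cb)
  }
  trim5 <- if (!swap) off else 0L
  trim3 <- if (!swap) length(cb) - length(ca) - off else 0L
  in_middle <- mm_ref_pos > end_zone & mm_ref_pos <= n_core - end_zone
  if (any(in_middle)) return(FALSE)
  end5 <- sum(mm_ref_pos <= end_zone) + ext5 + trim5
  end3 <- sum(mm_ref_pos > n_core - end_zone) + ext3 + trim3
  end5 <= max_mm && end3 <= max_mm && (end5 + end3) <= max_mm
}

#' Cluster matched tags and sum expression per miRNA
#'
#' Within each cluster (one per matched reference miRNA, or per novel
#' precursor) the member with the dominant read count is the representative
#' (ties: alphabetically smallest sequence). Expression per library is the
#' sum over members passing the class rule: conserved members may carry up
#' to two substitutions anywhere; novel members may deviate by at most 3 nt
#' in total, confined to the outermost 3 nt of each end, with no
#' substitution in the middle.
#'
#' @param members data.frame with columns `group`, `sequence`, `count_ck`,
#'   `count_cd` and optionally `ref_seq`, the cluster reference the class
#'   rule is checked against (the matched known mature for conserved
#'   clusters, the canonical mature for novel loci); without it the
#'   dominant member is used.
#' @param terminal_rule `"conserved"` or `"novel"`.
#' @return data.frame, one row per group: `name`, `class`,
#'   `representative_seq`, `n_members`, `expr_ck`, `expr_cd`, plus a
#'   `members` list-column of member sequences included in the sums.
#' @export
cluster_and_quantify <- function(members,
                                 terminal_rule = c("conserved", "novel")) {
  terminal_rule <- match.arg(terminal_rule)
  groups <- sort(unique(members$group))
  rows <- lapply(groups, function(g) {
    mem <- members[members$group == g, , drop = FALSE]
    tot <- mem$count_ck + mem$count_cd
    rep_i <- order(-tot, mem$sequence)[1]
    # the class rule is checked against the cluster reference (the matched
    # known mature, or the canonical mature of a novel locus) when given;
    # otherwise against the dominant member
    ref <- if (!is.null(mem$ref_seq)) mem$ref_seq[1] else mem$sequence[rep_i]
    ok <- vapply(mem$sequence, .passes_class_rule, logical(1),
                 ref = ref, rule = terminal_rule)
    data.frame(name = g, class = terminal_rule,
               representative_seq = mem$sequence[rep_i],
               n_members = nrow(mem),
               expr_ck = sum(mem$count_ck[ok]),
               expr_cd = sum(mem$count_cd[ok]),
               members = I(list(mem$sequence[ok])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), class = character(0),
                      representative_seq = character(0),
                      n_members = integer(0), expr_ck = integer(0),
                      expr_cd = integer(0), members = I(list()),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# all occurrences of tag sequences inside a precursor, either orientation,
# via a substring index of the precursor (first occurrence per sequence);
# returns a data.frame (tag row index, sequence as found in the precursor,
# 0-based start)
.match_tags_to_pre <- function(tag_seqs, pre) {
  n <- nchar(pre)
  lens <- unique(nchar(tag_seqs))
  lens <- lens[lens <= n]
  index_of <- function(x) {
    subs <- character(0); poss <- integer(0)
    for (l in lens) {
      st <- 1:(n - l + 1L)
      ss <- substring(x, st, st + l - 1L)
      keep <- !duplicated(ss)
      subs <- c(subs, ss[keep]); poss <- c(poss, st[keep] - 1L)
    }
    list(seqs = subs, pos = poss)
  }
  fwd <- index_of(pre)
  rc <- index_of(revcomp(pre))
  rows <- list()
  m1 <- match(tag_seqs, fwd$seqs)
  h1 <- which(!is.na(m1))
  if (length(h1)) {
    rows[[length(rows) + 1L]] <- data.frame(
      tag = h1, sequence = tag_seqs[h1], start = fwd$pos[m1[h1]],
      stringsAsFactors = FALSE)
  }
  m2 <- match(tag_seqs, rc$seqs)
  h2 <- which(!is.na(m2))
  if (length(h2)) {
    rows[[length(rows) + 1L]] <- data.frame(
      tag = h2, sequence = revcomp(tag_seqs[h2]),
      start = n - rc$pos[m2[h2]] - nchar(tag_seqs[h2]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(tag = integer(0), sequence = character(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$tag, out$start), , drop = FALSE]
}

# hairpin criteria for one folded window; mature span [ms, me) 0-based
.check_precursor <- function(fold, ms, me, mfe_max, mfei_max, min_paired,
                             max_unpaired, max_consec_unpaired, seq) {
  pt <- parse_dotbracket(fold$dotbracket)
  n <- length(pt)
  mat <- (ms + 1L):me  # 1-based positions
  mlen <- me - ms
  if (mlen < 18L || mlen > 26L) return(NULL)
  partners <- pt[mat]
  paired <- partners > 0L
  if (sum(paired) < min_paired) return(NULL)
  unp <- !paired
  if (sum(unp) > max_unpaired) return(NULL)
  r <- rle(unp)
  if (any(r$lengths[r$values] > max_consec_unpaired)) return(NULL)
  pp <- partners[paired]
  if (all(pp > me)) arm <- "5p"
  else if (all(pp <= ms)) arm <- "3p"
  else return(NULL)  # straddles the loop / pairs within itself
  if (fold$mfe > mfe_max) return(NULL)
  fi <- mfei(fold$mfe, n, gc_percent(seq))
  if (fi > mfei_max) return(NULL)
  list(arm = arm, mfei = fi)
}

#' Predict novel miRNAs from transcript hairpins
#'
#' For each tag that maps perfectly to a transcript (and is not already
#' annotated), two windows around the hit are extracted
#' (`[pos - flank, tag_end + 20)` and `[pos - 20, tag_end + flank)`, both
#' orientations) and folded. A window is accepted as a pre-miRNA candidate
#' when: the mature (the tag) is 18-26 nt and lies wholly in one arm, at
#' least `min_paired` of its bases are paired, at most `max_unpaired`
#' unpaired with at most `max_consec_unpaired` consecutive, the loop does
#' not overlap the mature, MFE <= `mfe_max`, MFEI <= `mfei_max`, and the
#' precursor is `pre_min`-`pre_max` nt. Candidates sharing a precursor
#' locus are merged; the dominant tag becomes the canonical mature.
#'
#' @param tags annotated tag table; only rows with category `unannotated`
#'   are considered.
#' @param transcriptome named character vector of transcript (unigene)
#'   sequences, or a FASTA path.
#' @param flank search window flank in nt (default 150).
#' @param min_count minimum total read count for a tag to seed a hairpin
#'   search (default 3).
#' @param mfe_max,mfei_max,min_paired,max_unpaired,max_consec_unpaired
#'   hairpin acceptance thresholds (defaults -18 kcal/mol, -0.5, 16, 4, 2).
#' @param pre_min,pre_max accepted precursor length range (68-300 nt).
#' @param known_mature optional known mature miRNAs; accepted hairpins
#'   whose mature matches one within 2 substitutions (length +/- 2 nt) are
#'   reported as conserved pre-miRNA loci (`known_loci`) rather than novel
#'   calls.
#' @return A list with `candidates` (one row per accepted precursor:
#'   `name`, `unigene`, `start`, `end`, `strand`, `length`, `mfe`, `mfei`,
#'   `arm`, `precursor_seq`, `dotbracket`, `mature_seq`, `mature_start`,
#'   `mature_end` in precursor coordinates), `records`, the corresponding
#'   mature records from [cluster_and_quantify()] under the novel terminal
#'   rule, and `known_loci`, hairpins attributed to known miRNAs.
#' @export
predict_novel <- function(tags, transcriptome, flank = 150L, min_count = 3L,
                          mfe_max = -18, mfei_max = -0.5, min_paired = 16L,
                          max_unpaired = 4L, max_consec_unpaired = 2L,
                          pre_min = 68L, pre_max = 300L,
                          known_mature = NULL) {
  if (is.character(transcriptome) && length(transcriptome) == 1 &&
      file.exists(transcriptome)) transcriptome <- read_fasta(transcriptome)
  if (!is.null(tags$category)) {
    tags <- tags[tags$category == "unannotated", , drop = FALSE]
  }
  tags <- tags[tags$count_ck + tags$count_cd >= min_count, , drop = FALSE]
  empty <- list(candidates = data.frame(), records = data.frame(),
                known_loci = data.frame())
  if (!nrow(tags)) return(empty)
  hits <- map_perfect(tags$sequence, transcriptome)
  if (!nrow(hits)) return(empty)

  cands <- list()
  for (h in seq_len(nrow(hits))) {
    tag <- hits$tag[h]
    uni <- hits$ref[h]
    txseq <- transcriptome[[uni]]
    txlen <- nchar(txseq)
    pos <- hits$offset[h]          # 0-based tag start on transcript
    tend <- pos + nchar(tag)       # 0-based half-open end
    wins <- unique(list(
      c(max(0L, pos - flank), min(txlen, tend + 20L)),
      c(max(0L, pos - 20L), min(txlen, tend + flank))))
    for (w in wins) {
      wlen <- w[2] - w[1]
      if (wlen < pre_min || wlen > pre_max) next
      wseq <- substr(txseq, w[1] + 1L, w[2])
      for (strand in c("+", "-")) {
        if (strand == "+") {
          fseq <- wseq
          ms <- pos - w[1]
        } else {
          fseq <- revcomp(wseq)
          ms <- wlen - (tend - w[1])
        }
        me <- ms + nchar(tag)
        fold <- fold_rna(fseq)
        chk <- .check_precursor(fold, ms, me, mfe_max, mfei_max, min_paired,
                                max_unpaired, max_consec_unpaired, fseq)
        if (is.null(chk)) next
        mature_seq <- if (strand == "+") tag else revcomp(tag)
        cands[[length(cands) + 1L]] <- data.frame(
          unigene = uni, start = w[1], end = w[2], strand = strand,
          length = wlen, mfe = fold$mfe, mfei = chk$mfei, arm = chk$arm,
          precursor_seq = fseq, dotbracket = fold$dotbracket,
          mature_seq = tag, mature_start = ms, mature_end = me,
          tag_count = tags$count_ck[match(tag, tags$sequence)] +
            tags$count_cd[match(tag, tags$sequence)],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)

  # merge candidates sharing a precursor locus (same unigene, overlapping
  # spans): keep the window of the dominant tag, best MFEI on ties
  cand <- cand[order(cand$unigene, cand$start, cand$end), , drop = FALSE]
  cand$locus <- NA_integer_
  locus <- 0L
  for (i in seq_len(nrow(cand))) {
    if (i == 1L || cand$unigene[i] != cand$unigene[i - 1L] ||
        cand$start[i] >= max(cand$end[cand$locus == locus &
                                        !is.na(cand$locus)])) {
      locus <- locus + 1L
    }
    cand$locus[i] <- locus
  }
  keep <- do.call(rbind, lapply(split(cand, cand$locus), function(g) {
    g[order(-g$tag_count, g$mfei, g$start, g$strand), , drop = FALSE][1, ]
  }))
  # deterministic naming: by descending dominant count, then locus position
  keep <- keep[order(-keep$tag_count, keep$unigene, keep$start), ,
               drop = FALSE]
  # hairpins attributable to a known miRNA are conserved pre-miRNA loci,
  # reported separately: either the mature matches a known mature within 2
  # substitutions (length +/- 2), or a known mature occurs verbatim in the
  # precursor overlapping at least half of the candidate's mature span
  # (catching isomiR-seeded hairpins at known loci)
  known_idx <- logical(nrow(keep))
  if (!is.null(known_mature) && length(known_mature)) {
    refs <- chartr("Uu", "Tt", toupper(known_mature))
    known_idx <- vapply(seq_len(nrow(keep)), function(i) {
      s <- keep$mature_seq[i]
      by_seq <- any(vapply(seq_along(refs), function(r) {
        abs(nchar(refs[r]) - nchar(s)) <= 2L &&
          min(.slide_hamming(s, refs[r])$mismatches,
              .slide_hamming(revcomp(s), refs[r])$mismatches) <= 2L
      }, logical(1)))
      if (by_seq) return(TRUE)
      loc <- .match_tags_to_pre(refs, keep$precursor_seq[i])
      if (!nrow(loc)) return(FALSE)
      ov <- pmin(loc$start + nchar(loc$sequence), keep$mature_end[i]) -
        pmax(loc$start, keep$mature_start[i])
      any(ov >= 0.5 * nchar(loc$sequence))
    }, logical(1))
  }
  known_loci <- keep[known_idx, , drop = FALSE]
  if (nrow(known_loci)) {
    known_loci$name <- sprintf("conserved_pre_%d", seq_len(nrow(known_loci)))
  } else {
    known_loci$name <- character(0)
  }
  keep <- keep[!known_idx, , drop = FALSE]
  keep$name <- if (nrow(keep)) sprintf("novel_mir_%d", seq_len(nrow(keep)))
               else character(0)
  rownames(keep) <- NULL

  # cluster members: tags lying in the precursor (either orientation) whose
  # occurrence overlaps the mature region, grouped per locus
  mem_rows <- list()
  for (i in seq_len(nrow(keep))) {
    pre <- keep$precursor_seq[i]
    ref_seq <- if (keep$strand[i] == "+") keep$mature_seq[i]
               else revcomp(keep$mature_seq[i])
    loc <- .match_tags_to_pre(tags$sequence, pre)
    loc <- loc[loc$start + nchar(loc$sequence) > keep$mature_start[i] - 3L &
                 loc$start < keep$mature_end[i] + 3L, , drop = FALSE]
    loc <- loc[!duplicated(loc$tag), , drop = FALSE]
    if (nrow(loc)) {
      mem_rows[[length(mem_rows) + 1L]] <- data.frame(
        group = keep$name[i], sequence = loc$sequence,
        count_ck = tags$count_ck[loc$tag], count_cd = tags$count_cd[loc$tag],
        ref_seq = ref_seq, stringsAsFactors = FALSE)
    }
  }
  members <- do.call(rbind, mem_rows)
  records <- if (is.null(members)) {
    cluster_and_quantify(data.frame(group = character(0),
                                    sequence = character(0),
                                    count_ck = integer(0),
                                    count_cd = integer(0)), "novel")
  } else {
    cluster_and_quantify(members, "novel")
  }
  records <- records[match(keep$name, records$name), , drop = FALSE]
  rownames(records) <- NULL
  list(candidates = keep[, setdiff(names(keep), c("locus", "tag_count"))],
       records = records,
       known_loci = known_loci[, setdiff(names(known_loci),
                                         c("locus", "tag_count"))])
}

#' Detect a miRNA/miRNA* (5p/3p) pair on a precursor
#'
#' Looks for a second expressed tag on the arm opposite the mature that
#' forms the canonical Dicer duplex with 2-nt 3' overhangs (+/- `tol` nt).
#' Such pairs are flagged higher-confidence.
#'
#' @param candidate one row of `predict_novel()$candidates`.
#' @param tags tag table.
#' @param tol overhang tolerance in nt (default 1).
#' @param min_count minimum total count for the star tag.
#' @return A list with the star sequence, its span and counts, or `NULL`
#'   when no qualifying star tag exists.
#' @export
detect_star <- function(candidate, tags, tol = 1L, min_count = 1L) {
  pre <- candidate$precursor_seq
  pt <- parse_dotbracket(candidate$dotbracket)
  ms <- candidate$mature_start; me <- candidate$mature_end
  mat <- (ms + 1L):me
  paired <- mat[pt[mat] > 0L]
  if (!length(paired)) return(NULL)
  # extrapolate the partner of an (possibly unpaired) mature position from
  # the nearest paired mature base, assuming a locally regular helix
  exp_partner <- function(q) {
    qp <- paired[which.min(abs(paired - q))]
    pt[qp] - (q - qp)
  }
  # Dicer duplex geometry with 2-nt 3' overhangs on both strands: the star
  # spans (1-based) [partner(me - 2), partner(ms + 1) + 2] on either arm
  exp_star5 <- exp_partner(me - 2L) - 1L              # 0-based star start
  exp_star3 <- exp_partner(ms + 1L) + 2L - 1L         # 0-based star last
  ok <- tags$count_ck + tags$count_cd >= min_count
  loc <- .match_tags_to_pre(tags$sequence[ok], pre)
  loc$count_ck <- tags$count_ck[ok][loc$tag]
  loc$count_cd <- tags$count_cd[ok][loc$tag]
  for (l in seq_len(nrow(loc))) {
    ts <- loc$start[l]; te <- ts + nchar(loc$sequence[l])
    # must sit on the opposite arm
    if (candidate$arm == "5p" && ts < me) next
    if (candidate$arm == "3p" && te > ms) next
    o5 <- abs(ts - exp_star5)
    o3 <- abs((te - 1L) - exp_star3)
    if (o5 <= tol && o3 <= tol) {
      return(list(star_seq = loc$sequence[l], star_start = ts,
                  star_end = te, count_ck = loc$count_ck[l],
                  count_cd = loc$count_cd[l],
                  arm = if (candidate$arm == "5p") "3p" else "5p"))
    }
  }
  NULL
}

#' Enumerate isomiRs of a mature miRNA
#'
#' Every tag that aligns exactly within the precursor and overlaps at least
#' half of the mature span is reported as an isomiR, with signed 5'/3'
#' offsets relative to the canonical mature (positive = trimmed at that
#' end, negative = extended).
#'
#' @param candidate one row of `predict_novel()$candidates` (or any list
#'   with `precursor_seq`, `mature_start`, `mature_end`, `mature_seq`).
#' @param tags tag table.
#' @return data.frame with columns `sequence`, `offset_5p`, `offset_3p`,
#'   `count_ck`, `count_cd`, `is_canonical`, `is_dominant`.
#' @export
enumerate_isomirs <- function(candidate, tags) {
  pre <- candidate$precursor_seq
  ms <- candidate$mature_start; me <- candidate$mature_end
  mlen <- me - ms
  loc <- .match_tags_to_pre(tags$sequence, pre)
  te <- loc$start + nchar(loc$sequence)
  ov <- pmin(te, me) - pmax(loc$start, ms)
  loc <- loc[ov >= 0.5 * mlen, , drop = FALSE]
  loc <- loc[!duplicated(loc$tag), , drop = FALSE]
  out <- if (nrow(loc)) {
    data.frame(sequence = loc$sequence, offset_5p = loc$start - ms,
               offset_3p = me - (loc$start + nchar(loc$sequence)),
               count_ck = tags$count_ck[loc$tag],
               count_cd = tags$count_cd[loc$tag], stringsAsFactors = FALSE)
  } else NULL
  if (is.null(out)) {
    return(data.frame(sequence = character(0), offset_5p = integer(0),
                      offset_3p = integer(0), count_ck = integer(0),
                      count_cd = integer(0), is_canonical = logical(0),
                      is_dominant = logical(0), stringsAsFactors = FALSE))
  }
  out$is_canonical <- out$offset_5p == 0L & out$offset_3p == 0L
  tot <- out$count_ck + out$count_cd
  out <- out[order(-tot, out$sequence), , drop = FALSE]
  out$is_dominant <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}
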