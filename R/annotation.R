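# Tag annotation against reference sets, with the single-assignment
# priority rule: ncRNA (GenBank consulted before Rfam) > known miRNA >
# other reference > unannotated.

#' Perfect-match mapping of tags to a reference set
#'
#' A tag hits a reference record iff it is an exact substring of the record
#' on the sense strand (small-RNA reads are directional after adapter
#' ligation).
#'
#' @param tags character vector of tag sequences (or a tag table with a
#'   `sequence` column).
#' @param reference named character vector of reference sequences, or a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return data.frame with columns `tag`, `ref` (record name) and `offset`
#'   (0-based position of the match in the record); one row per
#'   (tag, record, offset) triple.
#' @export
map_perfect <- function(tags, reference) {
  if (is.data.frame(tags)) tags <- tags$sequence
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) reference <- read_fasta(reference)
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  out <- list()
  if (!length(tags) || !length(reference)) {
    return(data.frame(tag = character(0), ref = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  subjects <- Biostrings::DNAStringSet(reference)
  widths <- nchar(tags)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags[idx]))
    for (r in seq_along(subjects)) {
      m <- Biostrings::matchPDict(pd, subjects[[r]])
      starts <- Biostrings::startIndex(m)
      hit <- which(lengths(starts) > 0)
      for (h in hit) {
        out[[length(out) + 1L]] <- data.frame(
          tag = tags[idx[h]], ref = names(reference)[r],
          offset = starts[[h]] - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag = character(0), ref = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tag, res$ref, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# parse "type=..." / "source=..." attributes from ncRNA reference headers
.ref_attr <- function(headers, key) {
  m <- regmatches(headers, regexpr(sprintf("%s=[^ ]+", key), headers))
  out <- rep(NA_character_, length(headers))
  out[grepl(sprintf("%s=", key), headers)] <- sub(sprintf("^%s=", key), "", m)
  out
}

#' Classify tags by annotation priority
#'
#' Applies the single-assignment priority rule: a tag hitting any ncRNA
#' record takes that record's declared type (rRNA, tRNA, snRNA, snoRNA),
#' with GenBank-sourced records consulted before Rfam; otherwise a hit to
#' the known mature-miRNA reference gives `known_miRNA`; otherwise a hit to
#' the generic other-reference set gives `other_reference`; otherwise
#' `unannotated`. The rule is a total order, so the outcome does not depend
#' on the order in which hit sets are supplied.
#'
#' @param tags character vector of tag sequences.
#' @param ncrna_hits data.frame (tag, ref) of ncRNA hits; record names must
#'   carry `type=` and `source=` attributes (see [map_perfect()] input).
#' @param ncrna_ref the ncRNA reference (names used for type/source lookup).
#' @param mirna_hits,other_hits data.frames of hits against the known
#'   mature-miRNA reference and the optional other-reference set.
#' @return data.frame with columns `sequence`, `category`, `source`.
#' @export
classify_tags <- function(tags, ncrna_hits, ncrna_ref, mirna_hits,
                          other_hits = NULL) {
  if (inherits(ncrna_ref, "DNAStringSet")) {
    ncrna_ref <- setNames(as.character(ncrna_ref), names(ncrna_ref))
  }
  types <- .ref_attr(names(ncrna_ref), "type")
  sources <- .ref_attr(names(ncrna_ref), "source")
  names(types) <- names(sources) <- names(ncrna_ref)

  category <- rep("unannotated", length(tags))
  source <- rep("none", length(tags))

  if (nrow(ncrna_hits)) {
    hit_type <- types[ncrna_hits$ref]
    hit_src <- sources[ncrna_hits$ref]
    # GenBank before Rfam; then deterministic by type name
    ord <- order(ncrna_hits$tag, match(hit_src, c("GenBank", "Rfam")),
                 hit_type)
    first <- !duplicated(ncrna_hits$tag[ord])
    sel <- ord[first]
    idx <- match(ncrna_hits$tag[sel], tags)
    category[idx] <- hit_type[sel]
    source[idx] <- hit_src[sel]
  }
  open <- category == "unannotated"
  if (nrow(mirna_hits)) {
    hit <- open & tags %in% mirna_hits$tag
    category[hit] <- "known_miRNA"
    source[hit] <- "miRBase"
  }
  open <- category == "unannotated"
  if (!is.null(other_hits) && nrow(other_hits)) {
    hit <- open & tags %in% other_hits$tag
    category[hit] <- "other_reference"
    source[hit] <- "reference"
  }
  data.frame(sequence = tags, category = category, source = source,
             stringsAsFactors = FALSE)
}

#' Annotate a tag table against all reference sets
#'
#' Convenience wrapper: runs [map_perfect()] against the ncRNA, known-miRNA
#' and optional other-reference sets, then [classify_tags()].
#'
#' @param tags tag table from [collapse_tags()].
#' @param ncrna_ref named character vector (or DNAStringSet / FASTA path)
#'   of ncRNA records with `type=` and `source=` header attributes.
#' @param mirna_ref known mature miRNA reference.
#' @param other_ref optional generic reference (stands in for the
#'   genome-dependent repeat/exon/intron classes, which need a genome).
#' @return The tag table with `category` and `source` columns appended.
#' @export
annotate_tags <- function(tags, ncrna_ref, mirna_ref, other_ref = NULL) {
  seqs <- tags$sequence
  nc <- map_perfect(seqs, ncrna_ref)
  mi <- map_perfect(seqs, mirna_ref)
  ot <- if (is.null(other_ref)) NULL else map_perfect(seqs, other_ref)
  cls <- classify_tags(seqs, nc, ncrna_ref, mi, ot)
  stopifnot(identical(cls$sequence, seqs))
  tags$category <- cls$category
  tags$source <- cls$source
  tags
}

.CATEGORIES <- c("rRNA", "snRNA", "snoRNA", "tRNA", "known_miRNA",
                 "other_reference", "unannotated")

#' Composition summary of an annotated tag table
#'
#' Per-category unique-tag and total-read counts and percentages for each
#' library; categories always sum to the library totals.
#'
#' @param tags annotated tag table from [annotate_tags()].
#' @return data.frame, one row per category.
#' @export
summarize_composition <- function(tags) {
  cat_f <- factor(tags$category, levels = .CATEGORIES)
  uniq_ck <- tapply(tags$count_ck > 0, cat_f, sum, default = 0)
  uniq_cd <- tapply(tags$count_cd > 0, cat_f, sum, default = 0)
  tot_ck <- tapply(tags$count_ck, cat_f, sum, default = 0)
  tot_cd <- tapply(tags$count_cd, cat_f, sum, default = 0)
  pct <- function(x) if (sum(x) > 0) 100 * x / sum(x) else x * 0
  out <- data.frame(category = .CATEGORIES,
                    unique_ck = as.integer(uniq_ck),
                    unique_cd = as.integer(uniq_cd),
                    total_ck = as.integer(tot_ck),
                    total_cd = as.integer(tot_cd),
                    unique_ck_pct = pct(as.numeric(uniq_ck)),
                    unique_cd_pct = pct(as.numeric(uniq_cd)),
                    total_ck_pct = pct(as.numeric(tot_ck)),
                    total_cd_pct = pct(as.numeric(tot_cd)),
                    stringsAsFactors = FALSE)
  stopifnot(sum(out$unique_ck) == sum(tags$count_ck > 0),
            sum(out$total_ck) == sum(tags$count_ck),
            sum(out$total_cd) == sum(tags$count_cd))
  out
}
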