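# Ground-truthed synthetic data: planted pre-miRNA hairpins, ncRNA
# references, a transcriptome embedding precursors and target sites, and
# two adapter-ligated read libraries (control CK, treated Cd).
#
# The generator states the world the pipeline assumes: two unreplicated
# libraries of 18-30 nt inserts ligated to a 3' adapter, read counts per
# miRNA drawn from a negative binomial (Poisson in the dispersion -> 0
# limit), a fraction of miRNA reads as isomiR variants, ncRNA degradation
# fragments, random background, and a fraction of deliberately bad reads
# (no insert, poly(A), short inserts, low quality, 5' contaminants).

#' Default 3' and 5' adapters (Illumina TruSeq small RNA)
#' @export
DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"

#' @rdname DEFAULT_ADAPTER3
#' @export
DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

.rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate one pre-miRNA hairpin
#'
#' Builds a stem-loop precursor as stem + loop + reverse complement of the
#' stem, with `n_bulges` single-nucleotide insertions in the 3' arm, and
#' places a mature miRNA of `mature_len` nt wholly within one arm.
#'
#' @param stem_len stem length in nt (>= 18).
#' @param loop_len terminal loop length in nt (>= 3).
#' @param n_bulges number of single-nucleotide bulges inserted in the 3'
#'   arm.
#' @param mature_len mature miRNA length (default sampled from 20-22).
#' @param arm `"5p"` or `"3p"`; which arm carries the mature.
#' @param gc stem GC fraction (default 0.55, typical of plant precursors).
#' @return A list with `sequence`, `mature_start`, `mature_end` (0-based,
#'   half-open), `mature_seq`, `arm`. Total length is checked against the
#'   68-255 nt precursor range.
#' @export
gen_premirna <- function(stem_len, loop_len, n_bulges = 0L,
                         mature_len = sample(20:22, 1),
                         arm = sample(c("5p", "3p"), 1), gc = 0.55) {
  if (stem_len < 18) stop("gen_premirna: stem_len must be >= 18")
  if (loop_len < 3) stop("gen_premirna: loop_len must be >= 3")
  total <- 2L * stem_len + loop_len + n_bulges
  if (total < 68L || total > 255L) {
    stop("gen_premirna: total length ", total, " outside [68, 255]")
  }
  stem <- .rand_dna(stem_len, gc)
  loop <- .rand_dna(loop_len, 0.3)
  arm3 <- revcomp(stem)
  if (n_bulges > 0) {
    pos <- sort(sample(seq_len(stem_len - 1L), n_bulges))
    chars <- strsplit(arm3, "", fixed = TRUE)[[1]]
    for (b in rev(seq_len(n_bulges))) {
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1),
                      after = pos[b])
    }
    arm3 <- paste(chars, collapse = "")
  }
  seq <- paste0(stem, loop, arm3)
  n <- nchar(seq)
  # place the mature wholly within one arm, >= 2 nt from the terminus so
  # the star duplex with its 2-nt 3' overhang also fits
  if (arm == "5p") {
    ms <- sample(2:(stem_len - mature_len - 2L), 1)
  } else {
    start3 <- stem_len + loop_len  # 0-based start of the 3' arm
    ms <- start3 + sample(2:(nchar(arm3) - mature_len - 2L), 1)
  }
  me <- ms + mature_len
  list(sequence = seq, mature_start = ms, mature_end = me,
       mature_seq = substr(seq, ms + 1L, me), arm = arm)
}

#' Simulate a ground-truth set of miRNAs and abundances
#'
#' @param n_conserved,n_novel numbers of planted conserved and novel
#'   miRNAs.
#' @param n_up,n_down numbers of miRNAs with a planted 4-fold change
#'   up/down under treatment.
#' @param n_ck_only,n_cd_only numbers of library-specific miRNAs.
#' @param lfc planted log2 fold change magnitude (default 2, i.e. 4-fold).
#' @param mean_range range of CK mean counts (log-uniform; default
#'   20-2000).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param ncrna_fraction fraction of clean reads from ncRNA fragments.
#' @param isomir_fraction fraction of each miRNA's reads that are isomiR
#'   variants.
#' @param bad_fraction fraction (of depth) of deliberately bad reads.
#' @param seed RNG seed; all downstream generation is reproducible from it.
#' @return A `truth_set` list: `premirnas` (data.frame), `abundance`
#'   (data.frame with means and true log2 fold changes), the fractions,
#'   `dispersion` and `seed`.
#' @export
simulate_truth <- function(n_conserved = 20L, n_novel = 10L, n_up = 2L,
                           n_down = 4L, n_ck_only = 1L, n_cd_only = 2L,
                           lfc = 2, mean_range = c(20, 2000),
                           dispersion = 0.1, ncrna_fraction = 0.3,
                           isomir_fraction = 0.2, bad_fraction = 0.1,
                           seed = 1L) {
  set.seed(seed)
  n <- n_conserved + n_novel
  if (n_up + n_down + n_ck_only + n_cd_only > n) {
    stop("more DE/specific miRNAs requested than miRNAs")
  }
  name <- c(sprintf("mir_c%02d", seq_len(n_conserved)),
            sprintf("mir_n%02d", seq_len(n_novel)))
  class <- rep(c("conserved", "novel"), c(n_conserved, n_novel))
  pres <- lapply(seq_len(n), function(i) {
    gen_premirna(stem_len = sample(30:45, 1), loop_len = sample(8:14, 1),
                 n_bulges = sample(0:2, 1))
  })
  premirnas <- data.frame(
    name = name, class = class,
    sequence = vapply(pres, `[[`, character(1), "sequence"),
    mature_start = vapply(pres, `[[`, integer(1), "mature_start"),
    mature_end = vapply(pres, `[[`, integer(1), "mature_end"),
    mature_seq = vapply(pres, `[[`, character(1), "mature_seq"),
    arm = vapply(pres, `[[`, character(1), "arm"),
    stringsAsFactors = FALSE)

  mean_ck <- round(exp(runif(n, log(mean_range[1]), log(mean_range[2]))))
  log2fc <- rep(0, n)
  idx <- sample(n, n_up + n_down + n_ck_only + n_cd_only)
  up <- idx[seq_len(n_up)]
  down <- idx[n_up + seq_len(n_down)]
  cko <- idx[n_up + n_down + seq_len(n_ck_only)]
  cdo <- idx[n_up + n_down + n_ck_only + seq_len(n_cd_only)]
  log2fc[up] <- lfc
  log2fc[down] <- -lfc
  mean_cd <- mean_ck * 2^log2fc
  mean_cd[cko] <- 0
  mean_ck[cdo] <- 0
  mean_cd[cdo] <- round(exp(runif(n_cd_only, log(mean_range[1]),
                                  log(mean_range[2]))))
  log2fc[cko] <- -Inf
  log2fc[cdo] <- Inf
  abundance <- data.frame(name = name, mean_ck = mean_ck, mean_cd = mean_cd,
                          log2fc = log2fc, stringsAsFactors = FALSE)
  structure(list(premirnas = premirnas, abundance = abundance,
                 dispersion = dispersion, ncrna_fraction = ncrna_fraction,
                 isomir_fraction = isomir_fraction,
                 bad_fraction = bad_fraction, seed = seed),
            class = "truth_set")
}

#' Generate ncRNA reference sequences
#'
#' Random rRNA/tRNA/snRNA/snoRNA records with `type=` and `source=`
#' (GenBank or Rfam) header attributes, as the annotation stage expects.
#'
#' @return Named character vector of reference sequences.
#' @export
gen_ncrna_reference <- function() {
  spec <- data.frame(
    type = c("rRNA", "rRNA", "tRNA", "tRNA", "tRNA", "snRNA", "snRNA",
             "snoRNA", "snoRNA"),
    len = c(1200L, 800L, 75L, 76L, 74L, 150L, 160L, 120L, 110L),
    source = c("GenBank", "Rfam", "GenBank", "Rfam", "GenBank", "Rfam",
               "GenBank", "Rfam", "GenBank"),
    stringsAsFactors = FALSE)
  seqs <- vapply(spec$len, .rand_dna, character(1))
  names(seqs) <- sprintf("nc%02d type=%s source=%s", seq_len(nrow(spec)),
                         spec$type, spec$source)
  seqs
}

#' Generate a synthetic transcriptome with embedded precursors and targets
#'
#' Emits background unigenes of 300-2000 nt, one unigene per planted
#' precursor (embedded verbatim with random flanks), and one unigene per
#' target spec carrying the requested complementary sites.
#'
#' @param n_background number of pure background unigenes.
#' @param premirnas precursor data.frame (`simulate_truth()$premirnas`), or
#'   NULL.
#' @param target_specs data.frame with columns `mirna` (name),
#'   `mature_seq`, `n_sites`, `n_mismatch`, `n_gu`; or NULL.
#' @param len_range background unigene length range.
#' @return A list with `transcriptome` (named character vector; duplicate
#'   ids are an error) and `target_truth` (data.frame: `unigene`, `start`,
#'   `end`, `mirna`, `expected_expectation`).
#' @export
gen_transcriptome <- function(n_background = 50L, premirnas = NULL,
                              target_specs = NULL,
                              len_range = c(300L, 2000L)) {
  seqs <- character(0)
  for (i in seq_len(n_background)) {
    seqs[sprintf("Unigene%04d", i)] <-
      .rand_dna(sample(len_range[1]:len_range[2], 1))
  }
  if (!is.null(premirnas) && nrow(premirnas)) {
    for (i in seq_len(nrow(premirnas))) {
      fl1 <- .rand_dna(sample(50:300, 1))
      fl2 <- .rand_dna(sample(50:300, 1))
      id <- sprintf("Unigene_pre_%s", premirnas$name[i])
      if (id %in% names(seqs)) stop("duplicate unigene ids")
      seqs[id] <- paste0(fl1, premirnas$sequence[i], fl2)
    }
  }
  truth_rows <- list()
  if (!is.null(target_specs) && nrow(target_specs)) {
    for (i in seq_len(nrow(target_specs))) {
      ts <- target_specs[i, ]
      mat <- chartr("Uu", "Tt", toupper(ts$mature_seq))
      L <- nchar(mat)
      id <- sprintf("Unigene_tgt_%s_%d", ts$mirna, i)
      pieces <- .rand_dna(sample(100:300, 1))
      starts <- integer(0)
      for (s in seq_len(ts$n_sites)) {
        site <- strsplit(revcomp(mat), "", fixed = TRUE)[[1]]
        # site[k] (5'->3') faces miRNA position L - k + 1
        # mutate only outside the seed (miRNA positions 14..L) so each
        # mismatch costs exactly 1.0 and each wobble 0.5
        free_mpos <- setdiff(seq_len(L), 1:13)
        mm_pos <- if (ts$n_mismatch > 0) {
          sample(free_mpos, ts$n_mismatch)
        } else integer(0)
        mat_chars <- strsplit(mat, "", fixed = TRUE)[[1]]
        gu_ok <- free_mpos[mat_chars[free_mpos] %in% c("G", "T")]
        gu_ok <- setdiff(gu_ok, mm_pos)
        gu_pos <- if (ts$n_gu > 0) sample(gu_ok, ts$n_gu) else integer(0)
        for (mp in mm_pos) {
          mb <- substr(mat, mp, mp)
          comp <- c(A = "T", C = "G", G = "C", T = "A")[mb]
          wob <- c(G = "T", T = "G")[mb]
          bad <- setdiff(c("A", "C", "G", "T"), c(comp, wob[!is.na(wob)]))
          site[L - mp + 1L] <- sample(bad, 1)
        }
        for (gp in gu_pos) {
          mb <- substr(mat, gp, gp)
          site[L - gp + 1L] <- if (mb == "G") "T" else "G"
        }
        starts <- c(starts, nchar(pieces))
        pieces <- paste0(pieces, paste(site, collapse = ""),
                         .rand_dna(sample(80:200, 1)))
      }
      seqs[id] <- pieces
      for (s0 in starts) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          unigene = id, start = s0, end = s0 + L, mirna = ts$mirna,
          expected_expectation = ts$n_mismatch * 1.0 + ts$n_gu * 0.5,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (anyDuplicated(names(seqs))) stop("duplicate unigene ids")
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(unigene = character(0), start = integer(0),
               end = integer(0), mirna = character(0),
               expected_expectation = numeric(0), stringsAsFactors = FALSE)
  list(transcriptome = seqs, target_truth = truth)
}

# one isomiR variant of a mature within its precursor: a 1-3 nt terminal
# trim or (when the precursor has room) extension
.isomir_variant <- function(pre, ms, me) {
  n <- nchar(pre)
  end5 <- sample(c(TRUE, FALSE), 1)
  size <- sample(1:3, 1)
  extend <- sample(c(TRUE, FALSE), 1)
  if (end5) {
    ns <- if (extend) max(0L, ms - size) else ms + size
    ne <- me
  } else {
    ns <- ms
    ne <- if (extend) min(n, me + size) else me - size
  }
  if (ne - ns < 15L) { ns <- ms; ne <- me - 1L }  # keep inserts >= 15 nt
  substr(pre, ns + 1L, ne)
}

#' Generate the two synthetic read libraries
#'
#' Draws per-miRNA read counts from a negative binomial with the
#' condition-specific means (Poisson when `truth$dispersion` is 0), makes
#' `truth$isomir_fraction` of each miRNA's reads isomiR variants, adds
#' ncRNA fragments (`truth$ncrna_fraction` of `depth`), fills to `depth`
#' with random background reads, appends the 3' adapter to every insert
#' (reads truncated at `read_len`), and injects `truth$bad_fraction` of
#' deliberately bad reads.
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param depth target clean reads per library.
#' @param adapter3,adapter5 adapter sequences.
#' @param ncrna_ref ncRNA reference to draw fragments from.
#' @param read_len sequencer read length (default 49 nt).
#' @return A list with `ck` and `cd` (data.frames `seq`, `qual`), and
#'   `counts`: the realized per-miRNA counts per library (the quantity the
#'   pipeline should recover).
#' @export
gen_libraries <- function(truth, depth = 1e5, adapter3 = DEFAULT_ADAPTER3,
                          adapter5 = DEFAULT_ADAPTER5,
                          ncrna_ref = gen_ncrna_reference(),
                          read_len = 49L) {
  if (depth <= 0) stop("depth must be positive")
  pre <- truth$premirnas
  ab <- truth$abundance
  draw <- function(mu) {
    if (mu <= 0) return(0L)
    if (truth$dispersion <= 1e-12) rpois(1, mu)
    else rnbinom(1, mu = mu, size = 1 / truth$dispersion)
  }
  counts <- data.frame(name = ab$name,
                       count_ck = vapply(ab$mean_ck, draw, numeric(1)),
                       count_cd = vapply(ab$mean_cd, draw, numeric(1)),
                       stringsAsFactors = FALSE)

  one_library <- function(col) {
    n_mir <- counts[[col]]
    inserts <- character(0)
    for (i in seq_len(nrow(pre))) {
      k <- n_mir[i]
      if (k == 0) next
      n_iso <- rbinom(1, k, truth$isomir_fraction)
      mat <- pre$mature_seq[i]
      iso <- if (n_iso > 0)

        vapply(seq_len(n_iso), function(z)
          .isomir_variant(pre$sequence[i], pre$mature_start[i],
                          pre$mature_end[i]), character(1))
      else character(0)
      inserts <- c(inserts, rep(mat, k - n_iso), iso)
    }
    n_nc <- round(truth$ncrna_fraction * depth)
    if (n_nc > 0) {
      refs <- sample(seq_along(ncrna_ref), n_nc, replace = TRUE)
      frag <- vapply(refs, function(r) {
        l <- sample(15:30, 1)
        s0 <- sample(nchar(ncrna_ref[r]) - l + 1L, 1)
        substr(ncrna_ref[r], s0, s0 + l - 1L)
      }, character(1))
      inserts <- c(inserts, frag)
    }
    n_bg <- depth - length(inserts)
    if (n_bg < 0) {
      stop("depth too small for the planted abundances + ncRNA fraction")
    }
    if (n_bg > 0) {
      inserts <- c(inserts,
                   vapply(sample(15:30, n_bg, replace = TRUE), .rand_dna,
                          character(1)))
    }
    reads <- substr(paste0(inserts, adapter3), 1L, read_len)
    quals <- strrep("I", nchar(reads))
    # deliberately bad reads
    n_bad <- round(truth$bad_fraction * depth)
    if (n_bad > 0) {
      kinds <- sample(c("no_insert", "polyA", "short", "low_quality",
                        "contaminant"), n_bad, replace = TRUE)
      bad_seq <- character(n_bad)
      bad_qual <- character(n_bad)
      for (b in seq_len(n_bad)) {
        ins <- switch(kinds[b],
          no_insert = "",
          polyA = strrep("A", sample(16:28, 1)),
          short = .rand_dna(sample(8:14, 1)),
          low_quality = .rand_dna(sample(18:24, 1)),
          contaminant = paste0(substr(adapter5, nchar(adapter5) - 7L,
                                      nchar(adapter5)),
                               .rand_dna(sample(10:20, 1))))
        rd <- substr(paste0(ins, adapter3), 1L, read_len)
        q <- strrep("I", nchar(rd))
        if (kinds[b] == "low_quality") {
          nb <- nchar(rd)
          nlow <- ceiling(0.3 * nb)
          qc <- strsplit(q, "")[[1]]
          qc[sample(nb, nlow)] <- "#"
          q <- paste(qc, collapse = "")
        }
        bad_seq[b] <- rd
        bad_qual[b] <- q
      }
      reads <- c(reads, bad_seq)
      quals <- c(quals, bad_qual)
    }
    ord <- sample(length(reads))
    data.frame(seq = reads[ord], qual = quals[ord], stringsAsFactors = FALSE)
  }
  ck <- one_library("count_ck")
  cd <- one_library("count_cd")
  list(ck = ck, cd = cd, counts = counts)
}

#' Simulate a complete dataset on disk
#'
#' Builds a truth set, references, transcriptome and the two FASTQ
#' libraries, and writes everything (plus TSV truth side-cars) under
#' `outdir`. Identical seeds give byte-identical outputs.
#'
#' @param outdir output directory (created if needed).
#' @param seed RNG seed for all randomness.
#' @param depth clean reads per library (default 1e5).
#' @param target_specs optional target spec data.frame (see
#'   [gen_transcriptome()]); the default plants one perfect site, one
#'   1-mismatch site and one 1-wobble site.
#' @param n_background background unigenes.
#' @param ... passed to [simulate_truth()].
#' @return Invisibly, a list with the truth objects and all file paths.
#' @export
simulate_dataset <- function(outdir, seed = 1L, depth = 1e5,
                             target_specs = NULL, n_background = 50L, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(seed = seed, ...)
  pre <- truth$premirnas
  if (is.null(target_specs)) {
    pick <- c(which(pre$class == "conserved")[1:2],
              which(pre$class == "novel")[1])
    target_specs <- data.frame(
      mirna = pre$name[pick],
      mature_seq = pre$mature_seq[pick],
      n_sites = 1L, n_mismatch = c(0L, 1L, 0L), n_gu = c(0L, 0L, 1L),
      stringsAsFactors = FALSE)
  }
  tx <- gen_transcriptome(n_background, pre, target_specs)
  ncrna <- gen_ncrna_reference()
  # known mature reference: planted conserved matures plus unplanted decoys
  cons <- pre[pre$class == "conserved", ]
  mature_ref <- setNames(cons$mature_seq,
                         sprintf("ref-%s", sub("^mir_", "miR", cons$name)))
  decoys <- vapply(1:5, function(i) .rand_dna(21), character(1))
  mature_ref <- c(mature_ref, setNames(decoys, sprintf("ref-decoy%d", 1:5)))
  libs <- gen_libraries(truth, depth = depth, ncrna_ref = ncrna)

  paths <- list(
    ck_fastq = file.path(outdir, "ck.fastq"),
    cd_fastq = file.path(outdir, "cd.fastq"),
    transcriptome = file.path(outdir, "transcriptome.fa"),
    mature_ref = file.path(outdir, "mature_ref.fa"),
    ncrna_ref = file.path(outdir, "ncrna_ref.fa"),
    truth_premirnas = file.path(outdir, "truth_premirnas.tsv"),
    truth_abundance = file.path(outdir, "truth_abundance.tsv"),
    truth_counts = file.path(outdir, "truth_counts.tsv"),
    truth_targets = file.path(outdir, "truth_targets.tsv"))
  write_fastq(libs$ck, paths$ck_fastq)
  write_fastq(libs$cd, paths$cd_fastq)
  write_fasta(tx$transcriptome, paths$transcriptome)
  write_fasta(mature_ref, paths$mature_ref)
  write_fasta(ncrna, paths$ncrna_ref)
  write_tsv_det(pre, paths$truth_premirnas)
  write_tsv_det(truth$abundance, paths$truth_abundance)
  write_tsv_det(libs$counts, paths$truth_counts)
  write_tsv_det(tx$target_truth, paths$truth_targets)
  invisible(list(truth = truth, transcriptome = tx$transcriptome,
                 target_truth = tx$target_truth, ncrna_ref = ncrna,
                 mature_ref = mature_ref, libraries = libs, paths = paths))
}
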