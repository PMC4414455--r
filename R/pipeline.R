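# End-to-end orchestration: preprocess -> annotation -> miRNA discovery ->
# targets -> differential expression, with TSV reports for every stage.

#' Pipeline configuration
#'
#' All thresholds of the pipeline with their documented defaults. Any
#' field can be overridden by name.
#'
#' @param ck_fastq,cd_fastq paths to the control and treated FASTQ
#'   libraries.
#' @param transcriptome,mature_ref,ncrna_ref,other_ref reference FASTA
#'   paths (`other_ref` optional).
#' @param outdir output directory.
#' @param ... overrides for any default threshold; unknown names are an
#'   error.
#' @return A named list of settings for [run_pipeline()].
#' @export
pipeline_config <- function(ck_fastq, cd_fastq, transcriptome, mature_ref,
                            ncrna_ref, other_ref = NULL, outdir, ...) {
  cfg <- list(
    ck_fastq = ck_fastq, cd_fastq = cd_fastq,
    transcriptome = transcriptome, mature_ref = mature_ref,
    ncrna_ref = ncrna_ref, other_ref = other_ref, outdir = outdir,
    adapter3 = DEFAULT_ADAPTER3, adapter5 = DEFAULT_ADAPTER5,
    min_len = 15L, max_len = 30L, qual_min = 20L, qual_frac = 0.1,
    polyA_frac = 0.8, polyA_run = 8L,
    conserved_max_mm = 2L, conserved_len_tol = 2L,
    flank = 150L, novel_min_count = 3L, mfe_max = -18, mfei_max = -0.5,
    min_paired = 16L, max_unpaired = 4L, max_consec_unpaired = 2L,
    pre_min = 68L, pre_max = 300L,
    target_cutoff = 3.0, target_weights = target_weights(),
    p_cut = 0.05, fc_cut = 1.5, tpm_floor = 0.01)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes cleaning/collapsing, annotation, conserved and novel miRNA
#' identification, isomiR enumeration, target prediction and differential
#' expression, writing one TSV per stage plus a run summary under
#' `config$outdir`. All coordinates in outputs are 0-based half-open. On
#' failure, files written by the failing run are removed.
#'
#' @param config list from [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  for (f in c("ck_fastq", "cd_fastq", "transcriptome", "mature_ref",
              "ncrna_ref")) {
    if (is.null(config[[f]])) stop("config is missing the ", f, " input")
    if (!file.exists(config[[f]])) {
      stop("input file for ", f, " does not exist: ", config[[f]])
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    written <<- c(written, path)
    write_tsv_det(df, path)
    path
  }

  reads_ck <- read_fastq(config$ck_fastq)
  reads_cd <- read_fastq(config$cd_fastq)
  tx <- read_fasta(config$transcriptome)
  mature_ref <- read_fasta(config$mature_ref)
  ncrna_ref <- read_fasta(config$ncrna_ref)
  other_ref <- if (!is.null(config$other_ref)) read_fasta(config$other_ref)

  # ---- preprocess
  cl_ck <- clean_library(reads_ck, config$adapter3, config$adapter5,
                         config$min_len, config$max_len, config$qual_min,
                         config$qual_frac, config$polyA_frac,
                         config$polyA_run)
  cl_cd <- clean_library(reads_cd, config$adapter3, config$adapter5,
                         config$min_len, config$max_len, config$qual_min,
                         config$qual_frac, config$polyA_frac,
                         config$polyA_run)
  tags <- collapse_tags(cl_ck$inserts, cl_cd$inserts)
  stats_df <- data.frame(
    metric = c("raw_reads", names(cl_ck$stats$removed_by_reason),
               "clean_reads"),
    ck = c(cl_ck$stats$raw_reads, cl_ck$stats$removed_by_reason,
           cl_ck$stats$clean_reads),
    cd = c(cl_cd$stats$raw_reads, cl_cd$stats$removed_by_reason,
           cl_cd$stats$clean_reads))
  emit(stats_df, "clean_stats.tsv")
  emit(tags, "tags.tsv")
  tag_fa <- setNames(tags$sequence,
                     sprintf("tag%d_x%d", seq_len(nrow(tags)),
                             tags$count_ck + tags$count_cd))
  fa_path <- file.path(config$outdir, "tags.fa")
  written <- c(written, fa_path)
  write_fasta(tag_fa, fa_path)
  emit(length_distribution(tags, "total"), "length_distribution_total.tsv")
  emit(length_distribution(tags, "unique"), "length_distribution_unique.tsv")
  fbb <- first_base_bias(tags)
  if (!is.null(fbb)) emit(fbb, "first_base_bias.tsv")

  # ---- annotation
  ann <- annotate_tags(tags, ncrna_ref, mature_ref, other_ref)
  comp <- summarize_composition(ann)
  emit(ann, "annotated_tags.tsv")
  emit(comp, "composition.tsv")

  # ---- conserved miRNAs (tags not claimed by ncRNA/other classes)
  mirna_pool <- ann[ann$category %in% c("known_miRNA", "unannotated"), ,
                    drop = FALSE]
  cons_hits <- match_conserved(mirna_pool, mature_ref,
                               config$conserved_max_mm,
                               config$conserved_len_tol)
  cons_members <- data.frame(group = cons_hits$ref,
                             sequence = cons_hits$sequence,
                             count_ck = cons_hits$count_ck,
                             count_cd = cons_hits$count_cd,
                             ref_seq = chartr("Uu", "Tt",
                                              toupper(mature_ref[cons_hits$ref])),
                             stringsAsFactors = FALSE)
  conserved <- cluster_and_quantify(cons_members, "conserved")
  emit(conserved[, setdiff(names(conserved), "members")],
       "conserved_mirnas.tsv")

  # ---- novel miRNAs from transcript hairpins
  novel_pool <- ann[ann$category == "unannotated" &
                      !ann$sequence %in% cons_hits$sequence, , drop = FALSE]
  novel <- predict_novel(novel_pool, tx, flank = config$flank,
                         min_count = config$novel_min_count,
                         mfe_max = config$mfe_max,
                         mfei_max = config$mfei_max,
                         min_paired = config$min_paired,
                         max_unpaired = config$max_unpaired,
                         max_consec_unpaired = config$max_consec_unpaired,
                         pre_min = config$pre_min, pre_max = config$pre_max,
                         known_mature = mature_ref)
  if (!is.null(novel$known_loci) && nrow(novel$known_loci)) {
    emit(novel$known_loci[, setdiff(names(novel$known_loci),
                                    c("precursor_seq", "dotbracket"))],
         "conserved_precursors.tsv")
  }
  if (nrow(novel$candidates)) {
    emit(novel$candidates[, setdiff(names(novel$candidates),
                                    c("precursor_seq", "dotbracket"))],
         "novel_precursors.tsv")
    pre_fa <- setNames(novel$candidates$precursor_seq,
                       novel$candidates$name)
    pre_path <- file.path(config$outdir, "novel_precursors.fa")
    written <- c(written, pre_path)
    write_fasta(pre_fa, pre_path)
    db_path <- file.path(config$outdir, "novel_structures.txt")
    written <- c(written, db_path)
    writeLines(sprintf(">%s\n%s\n%s (%.2f kcal/mol)",
                       novel$candidates$name,
                       as_rna(novel$candidates$precursor_seq),
                       novel$candidates$dotbracket, novel$candidates$mfe),
               db_path)
    emit(novel$records[, setdiff(names(novel$records), "members")],
         "novel_mirnas.tsv")
    # star strands and isomiRs
    stars <- lapply(seq_len(nrow(novel$candidates)), function(i) {
      st <- detect_star(novel$candidates[i, ], tags)
      if (is.null(st)) return(NULL)
      data.frame(name = novel$candidates$name[i], star_seq = st$star_seq,
                 star_arm = st$arm, count_ck = st$count_ck,
                 count_cd = st$count_cd, stringsAsFactors = FALSE)
    })
    stars <- do.call(rbind, stars[!vapply(stars, is.null, logical(1))])
    if (!is.null(stars)) emit(stars, "mirna_pairs.tsv")
    isos <- do.call(rbind, lapply(seq_len(nrow(novel$candidates)),
      function(i) {
        iso <- enumerate_isomirs(novel$candidates[i, ], tags)
        if (!nrow(iso)) return(NULL)
        cbind(name = novel$candidates$name[i], iso,
              stringsAsFactors = FALSE)
      }))
    if (!is.null(isos)) emit(isos, "isomirs.tsv")
  }

  # ---- targets
  mirna_set <- c(setNames(conserved$representative_seq, conserved$name),
                 if (nrow(novel$records))
                   setNames(novel$records$representative_seq,
                            novel$records$name))
  targets <- if (length(mirna_set)) {
    scan_targets(mirna_set, tx, config$target_cutoff,
                 config$target_weights)
  } else {
    scan_targets(character(0), tx, config$target_cutoff)
  }
  emit(targets, "targets.tsv")

  # ---- differential expression
  all_records <- rbind(
    conserved[, c("name", "class", "expr_ck", "expr_cd")],
    if (nrow(novel$records))
      novel$records[, c("name", "class", "expr_ck", "expr_cd")])
  de <- if (!is.null(all_records) && nrow(all_records) &&
            sum(all_records$expr_ck) > 0 && sum(all_records$expr_cd) > 0) {
    call_de(diffexp_table(all_records, config$tpm_floor),
            config$p_cut, config$fc_cut)
  } else {
    data.frame()
  }
  if (nrow(de)) emit(de, "diffexp.tsv")

  results <- list(clean_ck = cl_ck$stats, clean_cd = cl_cd$stats,
                  tags = tags, annotated = ann, composition = comp,
                  conserved = conserved, novel = novel, targets = targets,
                  diffexp = de)
  summary <- summarize_run(results)
  emit(summary, "summary.tsv")
  ok <- TRUE
  invisible(c(results, list(summary = summary)))
}

#' Summarize a pipeline run
#'
#' One row per headline metric: raw/clean read counts, shared and
#' library-specific tags (unique and total), per-class miRNA counts and
#' significant-miRNA counts.
#'
#' @param results list produced inside [run_pipeline()].
#' @return data.frame with `metric`, `ck`, `cd` columns (`cd` is NA for
#'   joint metrics).
#' @export
summarize_run <- function(results) {
  tags <- results$tags
  shared <- tags$count_ck > 0 & tags$count_cd > 0
  ck_only <- tags$count_ck > 0 & tags$count_cd == 0
  cd_only <- tags$count_cd > 0 & tags$count_ck == 0
  de <- results$diffexp
  n_sig <- if (!is.null(de) && nrow(de)) sum(de$significant) else 0L
  rows <- list(
    c("raw_reads", results$clean_ck$raw_reads, results$clean_cd$raw_reads),
    c("clean_reads", results$clean_ck$clean_reads,
      results$clean_cd$clean_reads),
    c("unique_tags", sum(tags$count_ck > 0), sum(tags$count_cd > 0)),
    c("unique_tags_shared", sum(shared), NA),
    c("unique_tags_ck_specific", sum(ck_only), NA),
    c("unique_tags_cd_specific", sum(cd_only), NA),
    c("total_reads_shared", sum(tags$count_ck[shared]) +
        sum(tags$count_cd[shared]), NA),
    c("total_reads_ck_specific", sum(tags$count_ck[ck_only]), NA),
    c("total_reads_cd_specific", sum(tags$count_cd[cd_only]), NA),
    c("conserved_mirnas", nrow(results$conserved), NA),
    c("novel_mirnas",
      if (is.null(results$novel$records)) 0L
      else nrow(results$novel$records), NA),
    c("target_sites", nrow(results$targets), NA),
    c("significant_mirnas", n_sig, NA))
  data.frame(metric = vapply(rows, `[[`, character(1), 1),
             ck = as.numeric(vapply(rows, `[[`, character(1), 2)),
             cd = suppressWarnings(
               as.numeric(vapply(rows, function(r) as.character(r[3]),
                                 character(1)))),
             stringsAsFactors = FALSE)
}
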