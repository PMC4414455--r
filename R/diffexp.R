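# Two-library differential expression of miRNAs.
#
# Counts are normalized to transcripts per million (TPM) against the total
# number of miRNA-matching reads in each library; significance of a
# count difference between the two unreplicated libraries comes from the
# Audic-Claverie Bayesian test, and calls additionally require a 1.5-fold
# change. miRNAs with all reads in one library are flagged as
# library-specific.

#' Transcripts-per-million normalization
#'
#' @param count read count(s).
#' @param library_total total miRNA-matching reads in the library (> 0).
#' @return `count / library_total * 1e6`.
#' @export
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("tpm: library_total must be positive")
  count / library_total * 1e6
}

#' Log2 fold change with a zero floor
#'
#' `log2(max(tpm_cd, floor) / max(tpm_ck, floor))`; the floor keeps
#' library-specific miRNAs finite and plottable.
#'
#' @param tpm_cd,tpm_ck normalized expression in the treated and control
#'   libraries.
#' @param floor minimum TPM used in the ratio (default 0.01).
#' @return log2 fold change (treatment over control).
#' @export
log2_fold_change <- function(tpm_cd, tpm_ck, floor = 0.01) {
  if (floor <= 0) stop("log2_fold_change: floor must be positive")
  log2(pmax(tpm_cd, floor) / pmax(tpm_ck, floor))
}

#' Audic-Claverie test for a two-library count difference
#'
#' Posterior predictive test for digital expression data without
#' replicates: given `x` counts among `N1` reads in one library, the
#' probability of observing `y` counts among `N2` reads in the other is
#' \deqn{p(y|x) = \left(\frac{N2}{N1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}},}
#' a negative binomial in `y` with size `x + 1` and success probability
#' `N1/(N1+N2)`, which is how it is evaluated (exact, overflow-safe for
#' counts up to at least 1e6). The two-sided p-value doubles the smaller
#' tail, capped at 1; because the inclusive-tail construction treats the
#' observed point asymmetrically under a library swap, the doubled-tail
#' value is computed in both orientations and the smaller taken, making
#' the test exactly symmetric in its two libraries.
#'
#' @param x,y counts in the two libraries.
#' @param N1,N2 library totals (> 0).
#' @return Two-sided p-value(s) in `[0, 1]`. Vectorized over counts.
#' @export
audic_claverie_p <- function(x, N1, y, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  one_sided <- function(x, N1, y, N2) {
    prob <- N1 / (N1 + N2)
    lower <- pnbinom(y, size = x + 1, prob = prob)
    upper <- 1 - pnbinom(y - 1, size = x + 1, prob = prob)
    pmin(1, 2 * pmin(lower, upper))
  }
  pmin(one_sided(x, N1, y, N2), one_sided(y, N2, x, N1))
}

#' Build the differential expression table for a set of miRNAs
#'
#' @param records data.frame with columns `name` and per-library summed
#'   counts `expr_ck`, `expr_cd` (e.g. from [cluster_and_quantify()]).
#' @param floor TPM floor for fold changes (default 0.01).
#' @param total_ck,total_cd normalization denominators; default is the
#'   total miRNA-matching reads, i.e. the column sums of `records`.
#' @return data.frame with counts, TPMs, `log2fc` and Audic-Claverie
#'   `pvalue` per miRNA (no calls yet; see [call_de()]).
#' @export
diffexp_table <- function(records, floor = 0.01,
                          total_ck = sum(records$expr_ck),
                          total_cd = sum(records$expr_cd)) {
  out <- data.frame(mirna = records$name,
                    count_ck = records$expr_ck,
                    count_cd = records$expr_cd,
                    tpm_ck = tpm(records$expr_ck, total_ck),
                    tpm_cd = tpm(records$expr_cd, total_cd),
                    stringsAsFactors = FALSE)
  out$log2fc <- log2_fold_change(out$tpm_cd, out$tpm_ck, floor)
  out$pvalue <- audic_claverie_p(out$count_ck, total_ck,
                                 out$count_cd, total_cd)
  out
}

#' Call differentially expressed and library-specific miRNAs
#'
#' A miRNA is significant when its Audic-Claverie p-value is below `p_cut`
#' and its fold change is at least `fc_cut` in either direction
#' (`|log2fc| >= log2(fc_cut)`). Stars mark P < 0.05 (`*`) and P < 0.01
#' (`**`). miRNAs with zero counts in exactly one library are flagged
#' `CK_only` / `Cd_only`. A Benjamini-Hochberg adjusted p-value column is
#' emitted for reference but not used for the calls.
#'
#' @param results data.frame from [diffexp_table()].
#' @param p_cut raw p-value threshold (default 0.05).
#' @param fc_cut fold-change threshold on the linear scale (default 1.5).
#' @return `results` with `padj`, `sig_label`, `significant`, `direction`
#'   and `specific` columns appended.
#' @export
call_de <- function(results, p_cut = 0.05, fc_cut = 1.5) {
  results$padj <- p.adjust(results$pvalue, method = "BH")
  results$significant <- results$pvalue < p_cut &
    abs(results$log2fc) >= log2(fc_cut)
  results$sig_label <- ifelse(results$significant & results$pvalue < 0.01,
                              "**",
                              ifelse(results$significant, "*", "none"))
  results$direction <- ifelse(!results$significant, "none",
                              ifelse(results$log2fc > 0, "up", "down"))
  results$specific <- ifelse(results$count_ck == 0 & results$count_cd > 0,
                             "Cd_only",
                             ifelse(results$count_cd == 0 &
                                      results$count_ck > 0,
                                    "CK_only", "none"))
  results
}
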