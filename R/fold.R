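#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' Folds a single sequence under the package's nearest-neighbor energy model
#' (see [energy_params()]): Watson-Crick and G:U pairs, sequence-dependent
#' stacking, hairpin/bulge/interior loop penalties (interior size capped at
#' 30 nt) and affine multiloop costs. The dynamic program is deterministic:
#' energy ties are resolved in favour of more base pairs, then the 5'-most
#' pairing. The empty structure is always admissible, so the reported MFE is
#' never positive.
#'
#' @param seq nucleotide sequence, 5 to 600 nt, DNA or RNA alphabet
#'   (T and U are equivalent). Non-ACGT/U symbols are rejected.
#' @return A list with `dotbracket` (structure string), `mfe` (kcal/mol,
#'   <= 0) and `npairs` (number of base pairs).
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(seq) {
  codes <- seq_to_codes(seq)
  n <- length(codes)
  if (n < 5 || n > 600) stop("fold_rna: sequence length must be in [5, 600]")
  res <- fold_rna_cpp(as.integer(codes), energy_params())
  list(dotbracket = res$dotbracket, mfe = res$mfe, npairs = res$npairs)
}

#' Minimal folding free energy index (MFEI)
#'
#' MFEI = (MFE / length * 100) / GC%, the length- and composition-adjusted
#' folding energy used to separate miRNA precursors (typically <= -0.5 in
#' plants) from other RNAs such as tRNA and rRNA.
#'
#' @param mfe minimum free energy in kcal/mol.
#' @param length sequence length in nt (> 0).
#' @param gc_percent GC content in percent, in (0, 100].
#' @return Dimensionless MFEI.
#' @examples
#' mfei(-50, 100, 50)  # -1
#' @export
mfei <- function(mfe, length, gc_percent) {
  if (any(length <= 0)) stop("mfei: length must be positive")
  if (any(gc_percent <= 0 | gc_percent > 100))
    stop("mfei: gc_percent must be in (0, 100]")
  (mfe / length * 100) / gc_percent
}

#' Hybridization energy of a miRNA:target duplex
#'
#' Minimum free energy of the intermolecular duplex between two strands
#' under the same nearest-neighbor model as [fold_rna()] (no intramolecular
#' pairs), including a helix initiation penalty. The empty duplex has energy
#' zero, so the result is never positive.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site_seq target site sequence, 5' to 3' (transcript sense strand).
#' @return Duplex MFE in kcal/mol (<= 0).
#' @export
duplex_mfe <- function(mirna, site_seq) {
  a <- seq_to_codes(mirna)
  b <- seq_to_codes(site_seq)
  if (length(a) < 2 || length(b) < 2) stop("duplex_mfe: sequences too short")
  duplex_mfe_cpp(as.integer(a), as.integer(b), energy_params(),
                 energy_params()$duplex_init)
}
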