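# Nearest-neighbor RNA folding energy model.
#
# A Turner-style free-energy model at 37 C: sequence-dependent stacking
# increments for the six canonical pairs (Watson-Crick plus G:U wobble),
# size-dependent hairpin/bulge/interior loop penalties with
# Jacobson-Stockmayer extrapolation, and an affine multiloop penalty.
# The same parameter set drives the minimum-free-energy folder (src/fold.cpp),
# the intermolecular duplex energy, and eval_structure(), so MFE values and
# structure evaluations are mutually consistent.

# base codes: A=1 C=2 G=3 U/T=4 (DNA input is treated as its RNA transcript)
.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)

# pair types: 1=AU 2=CG 3=GC 4=UA 5=GU 6=UG, 0 = not pairable
.pair_code <- matrix(0L, 4, 4)
.pair_code[1, 4] <- 1L  # A-U
.pair_code[2, 3] <- 2L  # C-G
.pair_code[3, 2] <- 3L  # G-C
.pair_code[4, 1] <- 4L  # U-A
.pair_code[3, 4] <- 5L  # G-U
.pair_code[4, 3] <- 6L  # U-G

# reversal of a pair type: (i,j) closing seen from the other strand
.pair_rev <- c(4L, 3L, 2L, 1L, 6L, 5L)

.RT37 <- 0.6163     # kcal/mol at 37 C
.MIN_HAIRPIN <- 3L  # minimum unpaired bases in a hairpin loop
.MAX_LOOP <- 30L    # cap on interior/bulge loop size in the DP

.build_stack_table <- function() {
  S <- matrix(NA_real_, 6, 6)
  # Watson-Crick / Watson-Crick stacks (Turner 2004 increments, kcal/mol);
  # S[p, q] is the stack of inner pair q on closing pair p (5'->3' outside in)
  S[1, 1] <- -0.93  # 5'AA3'/3'UU5'
  S[1, 4] <- -1.10  # AU/AU
  S[4, 1] <- -1.33  # UA/UA
  S[2, 4] <- -2.08  # CU/AG
  S[2, 1] <- -2.11  # CA/UG
  S[3, 4] <- -2.24  # GU/AC
  S[3, 1] <- -2.35  # GA/UC
  S[2, 3] <- -2.36  # CG/CG
  S[3, 3] <- -3.26  # GG/CC
  S[3, 2] <- -3.42  # GC/GC
  # wobble stacks: class approximation (one G:U next to a C-G class pair,
  # one G:U next to an A-U class pair, two G:U) -- ranking-faithful
  one_gu_cg <- -1.4; one_gu_au <- -1.0; two_gu <- -0.5
  for (p in 1:6) for (q in 1:6) {
    if (!is.na(S[p, q])) next
    n_gu <- (p >= 5) + (q >= 5)
    if (n_gu == 0) next
    S[p, q] <- if (n_gu == 2) two_gu
      else if (any(c(p, q) %in% 2:3)) one_gu_cg else one_gu_au
  }
  # remaining WC entries by strand-reversal symmetry S[p,q] = S[rev(q),rev(p)]
  for (p in 1:6) for (q in 1:6) {
    if (is.na(S[p, q])) S[p, q] <- S[.pair_rev[q], .pair_rev[p]]
  }
  # enforce the symmetry exactly
  Ssym <- S
  for (p in 1:6) for (q in 1:6) {
    Ssym[p, q] <- (S[p, q] + S[.pair_rev[q], .pair_rev[p]]) / 2
  }
  Ssym
}

.STACK <- .build_stack_table()

# loop initiation penalties, extrapolated 1.75*RT*log(n/n0) beyond the tables
.loop_table <- function(base_sizes, base_vals, max_n) {
  n0 <- base_sizes[length(base_sizes)]
  v0 <- base_vals[length(base_vals)]
  out <- rep(NA_real_, max_n)
  out[base_sizes] <- base_vals
  beyond <- seq.int(n0 + 1L, max_n)
  if (n0 < max_n) out[beyond] <- v0 + 1.75 * .RT37 * log(beyond / n0)
  out
}

.MAXLEN <- 600L
.HAIRPIN_E <- .loop_table(3:9, c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4), .MAXLEN)
.BULGE_E <- .loop_table(1:6, c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4), .MAXLEN)
.INTERIOR_E <- .loop_table(2:6, c(1.5, 1.8, 2.0, 2.2, 2.5), .MAXLEN)
.ML_CLOSE <- 3.4   # multiloop initiation
.ML_UNPAIRED <- 0.0
.ML_BRANCH <- 0.4  # per branch, the closing pair included
.DUPLEX_INIT <- 4.1  # intermolecular helix initiation

#' Folding energy model parameters
#'
#' Returns the nearest-neighbor parameter set used by [fold_rna()],
#' [duplex_mfe()] and [eval_structure()]: the 6x6 pair-stack free-energy
#' table, loop initiation penalties and multiloop constants.
#'
#' @return A list with elements `stack` (6x6 matrix, pair order AU, CG, GC,
#'   UA, GU, UG), `hairpin`, `bulge`, `interior` (penalty by loop size),
#'   `ml_close`, `ml_unpaired`, `ml_branch`, `duplex_init`, `min_hairpin`,
#'   `max_loop`. All energies in kcal/mol at 37 C.
#' @export
energy_params <- function() {
  list(stack = .STACK, hairpin = .HAIRPIN_E, bulge = .BULGE_E,
       interior = .INTERIOR_E, ml_close = .ML_CLOSE,
       ml_unpaired = .ML_UNPAIRED, ml_branch = .ML_BRANCH,
       duplex_init = .DUPLEX_INIT, min_hairpin = .MIN_HAIRPIN,
       max_loop = .MAX_LOOP)
}

# integer base codes for a sequence string; stops on anything outside ACGTU
seq_to_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- .base_code[chars]
  if (anyNA(codes)) {
    stop("sequence contains non-ACGT/U symbols: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  }
  unname(codes)
}

pair_type <- function(ci, cj) .pair_code[ci, cj]

#' Parse a dot-bracket string into a pair table
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return Integer vector `pt` with `pt[i] = j` when i pairs j, 0 otherwise.
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (chars[i] != ".") {
      stop("dot-bracket strings may contain only '(', ')' and '.'")
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

#' Free energy of a given secondary structure
#'
#' Evaluates the free energy of an explicit nested structure under the same
#' nearest-neighbor model as [fold_rna()], by decomposing it into hairpin,
#' stack, bulge, interior and multibranch loops. Used as the independent
#' scoring route when checking the MFE folder against structure enumeration.
#'
#' @param seq nucleotide sequence (DNA or RNA alphabet).
#' @param db dot-bracket structure of the same length, or a pair table as
#'   returned by [parse_dotbracket()].
#' @return Free energy in kcal/mol.
#' @export
eval_structure <- function(seq, db) {
  codes <- seq_to_codes(seq)
  pt <- if (is.character(db)) parse_dotbracket(db) else as.integer(db)
  if (length(pt) != length(codes)) stop("structure length != sequence length")
  n <- length(codes)
  # validate pairs
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) {
      if (pair_type(codes[i], codes[j]) == 0L)
        stop("structure pairs non-complementary bases at ", i, ",", j)
      if (j - i - 1L < .MIN_HAIRPIN)
        stop("hairpin loop shorter than ", .MIN_HAIRPIN, " at pair ", i, ",", j)
    }
  }
  loop_energy <- function(i, j) {
    # energy of the loop closed by pair (i, j) plus all loops inside it
    e <- 0
    branches <- integer(0)  # 5' ends of direct inner branches
    k <- i + 1L
    unpaired <- 0L
    while (k < j) {
      if (pt[k] > k) {
        branches <- c(branches, k)
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nb <- length(branches)
    if (nb == 0L) {
      e <- e + .HAIRPIN_E[j - i - 1L]
    } else if (nb == 1L) {
      k <- branches[1]; l <- pt[k]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        e <- e + .STACK[pair_type(codes[i], codes[j]),
                        pair_type(codes[k], codes[l])]
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + .BULGE_E[l1 + l2]
      } else {
        e <- e + .INTERIOR_E[l1 + l2]
      }
    } else {
      e <- e + .ML_CLOSE + .ML_BRANCH * (nb + 1L) + .ML_UNPAIRED * unpaired
    }
    for (k in branches) e <- e + loop_energy(k, pt[k])
    e
  }
  # exterior loop: free bases and branches contribute no penalty
  e <- 0
  k <- 1L
  while (k <= n) {
    if (pt[k] > k) {
      e <- e + loop_energy(k, pt[k])
      k <- pt[k] + 1L
    } else k <- k + 1L
  }
  e
}
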