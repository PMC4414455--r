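# Independent oracles for the folding and duplex energies: exhaustive
# enumeration of all nested structures / duplex pairings under the same
# nearest-neighbor parameter set, scored with eval_structure() or a direct
# loop-decomposition sum. Practical for sequences up to ~20 nt.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# all nested structures (lists of 1-based pairs) with hairpin loops >= minh
enum_structures <- function(seq, minh = 3L) {
  codes <- mirstress:::seq_to_codes(seq)
  n <- length(codes)
  can <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) can[i, j] <- mirstress:::pair_type(codes[i], codes[j]) > 0
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j || j - i < minh + 1L) return(list(list()))
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- rec(i + 1L, j)                      # i unpaired
    for (k in seq(i + minh + 1L, j)) {
      if (!can[i, k]) next
      inner <- rec(i + 1L, k - 1L)
      rest <- rec(k + 1L, j)
      for (s1 in inner) for (s2 in rest) {
        res[[length(res) + 1L]] <- c(list(c(i, k)), s1, s2)
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, n)
}

# minimum free energy over all enumerated structures (empty structure = 0)
oracle_mfe <- function(seq, minh = 3L) {
  structs <- enum_structures(seq, minh)
  n <- nchar(seq)
  best <- 0
  for (s in structs) {
    if (!length(s)) next
    pt <- integer(n)
    for (p in s) { pt[p[1]] <- p[2]; pt[p[2]] <- p[1] }
    e <- eval_structure(seq, pt)
    if (e < best) best <- e
  }
  best
}

# exhaustive intermolecular duplex enumeration: all antiparallel chains of
# pairs (i ascending on a, j descending on b) with consecutive-pair loop
# costs as in the duplex model, plus the initiation term
oracle_duplex <- function(a, b) {
  ep <- energy_params()
  ca <- mirstress:::seq_to_codes(a)
  cb <- mirstress:::seq_to_codes(b)
  n <- length(ca); m <- length(cb)
  pt <- function(x, y) mirstress:::pair_type(x, y)
  cost <- function(i0, j0, i1, j1) {
    l1 <- i1 - i0 - 1L; l2 <- j0 - j1 - 1L
    if (l1 + l2 > ep$max_loop) return(Inf)
    if (l1 == 0 && l2 == 0) {
      return(ep$stack[pt(ca[i0], cb[j0]), pt(ca[i1], cb[j1])])
    }
    if (l1 == 0 || l2 == 0) return(ep$bulge[l1 + l2])
    ep$interior[l1 + l2]
  }
  best <- 0
  extend <- function(i0, j0, e) {
    if (e < best) best <<- e
    for (i1 in seq_len(n)) {
      if (i1 <= i0) next
      for (j1 in seq_len(m)) {
        if (j1 >= j0) next
        if (pt(ca[i1], cb[j1]) == 0) next
        cc <- cost(i0, j0, i1, j1)
        if (is.finite(cc)) extend(i1, j1, e + cc)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (pt(ca[i], cb[j]) > 0) extend(i, j, ep$duplex_init)
  }
  best
}
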