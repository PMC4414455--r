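# Hand-built miniature truth sets for targeted generator tests.

make_mini_truth <- function(premirnas, mean_ck, mean_cd, dispersion = 0,
                            ncrna_fraction = 0, isomir_fraction = 0,
                            bad_fraction = 0) {
  ab <- data.frame(name = premirnas$name, mean_ck = mean_ck,
                   mean_cd = mean_cd,
                   log2fc = log2(mean_cd / mean_ck),
                   stringsAsFactors = FALSE)
  structure(list(premirnas = premirnas, abundance = ab,
                 dispersion = dispersion, ncrna_fraction = ncrna_fraction,
                 isomir_fraction = isomir_fraction,
                 bad_fraction = bad_fraction, seed = NA_integer_),
            class = "truth_set")
}

one_premirna_df <- function(name = "mir_t01", stem_len = 35, loop_len = 10,
                            n_bulges = 0, arm = "5p") {
  p <- gen_premirna(stem_len, loop_len, n_bulges, arm = arm)
  data.frame(name = name, class = "novel", sequence = p$sequence,
             mature_start = p$mature_start, mature_end = p$mature_end,
             mature_seq = p$mature_seq, arm = p$arm,
             stringsAsFactors = FALSE)
}

# substitute bases at given 1-based positions (avoiding the original base)
mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# a minimal tag table
tag_table <- function(seqs, ck, cd = rep(0L, length(seqs))) {
  data.frame(sequence = seqs, count_ck = as.integer(ck),
             count_cd = as.integer(cd), stringsAsFactors = FALSE)
}
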