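# The synthetic-data generator: hairpin construction, transcriptome
# embedding, library composition and reproducibility.

test_that("gen_premirna builds valid hairpins", {
  set.seed(1)
  p <- gen_premirna(30, 8, 0)
  expect_equal(nchar(p$sequence), 68L)
  # a perfect 30-bp stem folds with at least 28 pairs
  expect_gte(fold_rna(p$sequence)$npairs, 28L)
  p2 <- gen_premirna(30, 8, 2)
  expect_equal(nchar(p2$sequence), 70L)
  for (k in 1:30) {
    q <- gen_premirna(sample(30:45, 1), sample(8:14, 1), sample(0:2, 1))
    expect_true(grepl(q$mature_seq, q$sequence, fixed = TRUE))
    expect_identical(substr(q$sequence, q$mature_start + 1, q$mature_end),
                     q$mature_seq)
    expect_gte(nchar(q$sequence), 68L)
    expect_lte(nchar(q$sequence), 255L)
    expect_true((q$mature_end - q$mature_start) %in% 20:22)
  }
  expect_error(gen_premirna(20, 5), "outside")
  expect_error(gen_premirna(130, 5), "outside")
  expect_error(gen_premirna(10, 8), "stem_len")
  expect_error(gen_premirna(30, 2), "loop_len")
})

test_that("generated hairpins all fold below zero", {
  set.seed(2)
  for (k in 1:100) {
    p <- gen_premirna(sample(30:45, 1), sample(8:14, 1), sample(0:2, 1))
    expect_lt(fold_rna(p$sequence)$mfe, 0)
  }
})

test_that("gen_transcriptome bookkeeping and id uniqueness", {
  set.seed(3)
  tr <- simulate_truth(n_conserved = 3, n_novel = 2, n_up = 0, n_down = 0,
                       n_ck_only = 0, n_cd_only = 0, seed = 3)
  specs <- data.frame(mirna = tr$premirnas$name[1:3],
                      mature_seq = tr$premirnas$mature_seq[1:3],
                      n_sites = 1L, n_mismatch = 0L, n_gu = 0L,
                      stringsAsFactors = FALSE)
  tx <- gen_transcriptome(50, tr$premirnas, specs)
  expect_length(tx$transcriptome, 58L)  # 50 background + 5 pre + 3 target
  expect_false(anyDuplicated(names(tx$transcriptome)) > 0)
  expect_equal(nrow(tx$target_truth), 3L)
  # planted precursors are embedded verbatim
  for (i in 1:5) {
    expect_true(grepl(tr$premirnas$sequence[i],
                      tx$transcriptome[paste0("Unigene_pre_",
                                              tr$premirnas$name[i])],
                      fixed = TRUE))
  }
  dup <- tr$premirnas
  dup$name <- rep("same", nrow(dup))
  expect_error(gen_transcriptome(5, dup), "duplicate")
})

test_that("library counts follow the planted condition means", {
  set.seed(4)
  pre <- one_premirna_df()
  truth <- make_mini_truth(pre, mean_ck = 100, mean_cd = 400,
                           dispersion = 0)
  libs <- gen_libraries(truth, depth = 1e4, read_len = 49L)
  ck <- libs$counts$count_ck
  cd <- libs$counts$count_cd
  # CK:Cd ratio ~ 1:4 within 3 Poisson/binomial SDs
  expect_lt(abs(ck - 100), 3 * sqrt(100))
  expect_lt(abs(cd - 400), 3 * sqrt(400))
  # the realized counts are present verbatim in the reads
  ins <- trim_adapter(libs$ck$seq, DEFAULT_ADAPTER3)
  expect_equal(sum(ins == pre$mature_seq, na.rm = TRUE), ck)
})

test_that("every well-formed read ends with a prefix of the 3' adapter", {
  set.seed(5)
  truth <- make_mini_truth(one_premirna_df(), 50, 50)
  libs <- gen_libraries(truth, depth = 500, read_len = 49L)
  prefixes <- vapply(1:nchar(DEFAULT_ADAPTER3),
                     function(k) substr(DEFAULT_ADAPTER3, 1, k),
                     character(1))
  ok <- vapply(libs$ck$seq, function(r)
    any(vapply(prefixes, function(p) endsWith(r, p), logical(1))),
    logical(1))
  expect_true(all(ok))
})

test_that("bad reads are injected at the stated fraction and cleaned away", {
  set.seed(6)
  pre <- one_premirna_df()
  truth <- make_mini_truth(pre, 100, 100, bad_fraction = 0.1)
  libs <- gen_libraries(truth, depth = 1e4)
  cl <- clean_library(libs$ck, DEFAULT_ADAPTER3, DEFAULT_ADAPTER5)
  removed <- sum(cl$stats$removed_by_reason)
  expect_equal(cl$stats$raw_reads, nrow(libs$ck))
  expect_lt(abs(removed - 1000), 100)
})

test_that("identical seeds give byte-identical datasets", {
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  d3 <- file.path(tempdir(), "sim_c")
  small <- list(depth = 2000, n_conserved = 4L, n_novel = 2L, n_up = 0L,
                n_down = 0L, n_ck_only = 0L, n_cd_only = 0L,
                mean_range = c(20, 100))
  do.call(simulate_dataset, c(list(d1, seed = 42), small))
  do.call(simulate_dataset, c(list(d2, seed = 42), small))
  do.call(simulate_dataset, c(list(d3, seed = 43), small))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_false(identical(readLines(file.path(d1, "ck.fastq")),
                         readLines(file.path(d3, "ck.fastq"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("round trip: planted counts are recovered exactly in the noise-free world", {
  set.seed(7)
  pres <- do.call(rbind, lapply(1:3, function(i)
    one_premirna_df(sprintf("mir_t%02d", i))))
  pres$class <- c("conserved", "conserved", "novel")
  truth <- make_mini_truth(pres, mean_ck = c(50, 80, 40),
                           mean_cd = c(50, 20, 40), dispersion = 0,
                           ncrna_fraction = 0.1)
  libs <- gen_libraries(truth, depth = 5000)
  cl_ck <- clean_library(libs$ck, DEFAULT_ADAPTER3, DEFAULT_ADAPTER5)
  cl_cd <- clean_library(libs$cd, DEFAULT_ADAPTER3, DEFAULT_ADAPTER5)
  tags <- collapse_tags(cl_ck$inserts, cl_cd$inserts)
  mature_ref <- setNames(pres$mature_seq[1:2], c("refA", "refB"))
  hits <- match_conserved(tags, mature_ref)
  members <- data.frame(group = hits$ref, sequence = hits$sequence,
                        count_ck = hits$count_ck, count_cd = hits$count_cd,
                        ref_seq = mature_ref[hits$ref],
                        stringsAsFactors = FALSE)
  rec <- cluster_and_quantify(members, "conserved")
  expect_equal(rec$expr_ck[match(c("refA", "refB"), rec$name)],
               libs$counts$count_ck[1:2])
  expect_equal(rec$expr_cd[match(c("refA", "refB"), rec$name)],
               libs$counts$count_cd[1:2])
})
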