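# Perfect-match mapping and the single-assignment priority rule.

test_that("map_perfect finds exact substrings with 0-based offsets", {
  refs <- c(rec1 = "ACGTACGTACGTACGTACGTGGGG",
            rec2 = "TTTTACGTACGTACGTACGTACGT")
  hits <- map_perfect("ACGTACGTACGTACGTACGT", refs)
  expect_equal(sort(hits$ref), c("rec1", "rec2"))
  expect_equal(hits$offset[hits$ref == "rec1"], 0L)
  expect_equal(hits$offset[hits$ref == "rec2"], 4L)
  # one mismatch anywhere kills the hit
  mm <- mutate_at("ACGTACGTACGTACGTACGT", 10)
  expect_equal(nrow(map_perfect(mm, refs)), 0L)
})

test_that("map_perfect equals a brute-force substring scan", {
  set.seed(10)
  refs <- setNames(vapply(1:8, function(i) random_seq(120), character(1)),
                   paste0("r", 1:8))
  tags <- c(vapply(1:50, function(i) random_seq(sample(15:25, 1)),
                   character(1)),
            vapply(1:50, function(i) {
              r <- sample(8, 1)
              l <- sample(15:25, 1)
              s0 <- sample(120 - l, 1)
              substr(refs[r], s0 + 1, s0 + l)
            }, character(1)))
  tags <- unique(tags)
  hits <- map_perfect(tags, refs)
  brute <- do.call(rbind, lapply(tags, function(tg) {
    do.call(rbind, lapply(names(refs), function(r) {
      m <- gregexpr(tg, refs[[r]], fixed = TRUE)[[1]]
      if (m[1] < 0) return(NULL)
      data.frame(tag = tg, ref = r, offset = as.integer(m) - 1L,
                 stringsAsFactors = FALSE)
    }))
  }))
  brute <- brute[order(brute$tag, brute$ref, brute$offset), ]
  rownames(brute) <- NULL
  expect_equal(hits, brute)
})

test_that("priority rule: ncRNA > known miRNA > other > unannotated", {
  ncrna <- c("n1 type=rRNA source=GenBank" = "ACGTACGTACGTACGTACGTAAAA",
             "n2 type=tRNA source=Rfam" = "CCCCGGGGCCCCGGGGCCCCGGGG")
  mirna <- c(miR1 = "ACGTACGTACGTACGTACGT",
             miR2 = "TTTTTTTTTTGGGGGGGGGG")
  tags <- c("ACGTACGTACGTACGTACGT",  # rRNA beats known miRNA
            "TTTTTTTTTTGGGGGGGGGG",  # miRNA only
            "ATATATATATATATATATAT")  # nothing
  tg <- tag_table(tags, ck = c(1L, 1L, 1L))
  ann <- annotate_tags(tg, ncrna, mirna)
  expect_equal(ann$category, c("rRNA", "known_miRNA", "unannotated"))
  expect_equal(ann$source, c("GenBank", "miRBase", "none"))
})

test_that("GenBank is consulted before Rfam for the same sequence", {
  seqs <- "GGGGAAAACCCCGGGGAAAACCCC"
  ncrna_a <- c("g type=rRNA source=GenBank" = seqs,
               "r type=snoRNA source=Rfam" = seqs)
  ncrna_b <- ncrna_a[c(2, 1)]  # permuted evaluation order
  tg <- tag_table(substr(seqs, 1, 20), 1L)
  a <- annotate_tags(tg, ncrna_a, c(m = "TTTTTTTTTTTTTTTTTTTT"))
  b <- annotate_tags(tg, ncrna_b, c(m = "TTTTTTTTTTTTTTTTTTTT"))
  expect_equal(a$category, "rRNA")
  expect_equal(a$source, "GenBank")
  expect_identical(a, b)
})

test_that("classification is invariant under reference permutation", {
  set.seed(11)
  ncrna <- gen_ncrna_reference()
  mirna <- setNames(vapply(1:4, function(i) random_seq(21), character(1)),
                    paste0("m", 1:4))
  tags <- c(vapply(seq_along(ncrna), function(i) {
    substr(ncrna[[i]], 5, 26)
  }, character(1)), unname(mirna),
  vapply(1:10, function(i) random_seq(20), character(1)))
  tg <- tag_table(unique(tags), rep(1L, length(unique(tags))))
  a <- annotate_tags(tg, ncrna, mirna)
  b <- annotate_tags(tg, rev(ncrna), rev(mirna))
  expect_identical(a, b)
})

test_that("composition conserves unique and total counts", {
  set.seed(12)
  ncrna <- gen_ncrna_reference()
  tags <- tag_table(
    c(substr(ncrna[[1]], 10, 30), substr(ncrna[[3]], 2, 20),
      vapply(1:8, function(i) random_seq(21), character(1))),
    ck = c(5L, 3L, rep(2L, 8)), cd = c(1L, 0L, rep(1L, 8)))
  ann <- annotate_tags(tags, ncrna, c(m1 = random_seq(21)))
  comp <- summarize_composition(ann)
  expect_equal(sum(comp$total_ck), sum(tags$count_ck))
  expect_equal(sum(comp$total_cd), sum(tags$count_cd))
  expect_equal(sum(comp$unique_ck), sum(tags$count_ck > 0))
  expect_equal(sum(comp$total_ck_pct), 100, tolerance = 0.01)
  expect_equal(sum(comp$total_cd_pct), 100, tolerance = 0.01)
  # all-unannotated input lands 100% in unannotated
  tg2 <- tag_table(vapply(1:10, function(i) random_seq(18), character(1)),
                   rep(1L, 10))
  comp2 <- summarize_composition(annotate_tags(tg2, ncrna,
                                               c(m1 = random_seq(21))))
  expect_equal(comp2$total_ck_pct[comp2$category == "unannotated"], 100)
})
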