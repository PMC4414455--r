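# Adapter trimming, read cleaning, tag collapsing and the summary
# distributions.

A3 <- DEFAULT_ADAPTER3
A5 <- DEFAULT_ADAPTER5

test_that("trim_adapter recovers inserts and drops adapter-only reads", {
  ins <- "ACGTACGTACGTACGTACGT"
  expect_equal(trim_adapter(paste0(ins, A3), A3), ins)
  # adapter-adapter ligation: no insert
  expect_true(is.na(trim_adapter(A3, A3)))
  # no adapter at all: boundary unknowable
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGTACGTACGTACGT", A3)))
  # truncated adapter at the read end: longest >= 6 nt suffix-prefix match
  expect_equal(trim_adapter(paste0(ins, substr(A3, 1, 7)), A3), ins)
  expect_equal(trim_adapter(paste0(ins, substr(A3, 1, 6)), A3), ins)
  expect_true(is.na(trim_adapter(paste0(ins, substr(A3, 1, 5)), A3)))
  # left-most adapter occurrence wins
  expect_equal(trim_adapter(paste0("AAAA", A3, "CCCC", A3), A3), "AAAA")
  expect_error(trim_adapter("ACGT", "ACGT"), "at least 6")
})

test_that("clean_library applies the filters in order with one reason each", {
  reads <- c(
    paste0(strrep("ACGT", 5), A3),               # clean, 20 nt
    paste0(strrep("ACGTACG", 2), A3),            # clean, 14 nt -> too_short
    paste0(strrep("ACGTACGTACG", 3), "", A3),    # 33 nt -> too_long
    paste0(strrep("A", 16), A3),                 # poly(A)
    A3,                                          # no insert
    paste0(substr(A5, nchar(A5) - 7, nchar(A5)),
           "ACGTACGTACGT", A3),                  # 5' contaminant
    paste0("ACGNACGTACGTACGTACGT", A3))          # N -> low quality
  cl <- clean_library(reads, A3, A5)
  expect_equal(cl$stats$raw_reads, 7L)
  expect_equal(cl$stats$clean_reads, 1L)
  r <- cl$stats$removed_by_reason
  expect_equal(unname(r["too_short"]), 1L)
  expect_equal(unname(r["too_long"]), 1L)
  expect_equal(unname(r["polyA"]), 1L)
  expect_equal(unname(r["no_insert"]), 1L)
  expect_equal(unname(r["contaminant_5p"]), 1L)
  expect_equal(unname(r["low_quality"]), 1L)
  expect_equal(cl$stats$raw_reads, cl$stats$clean_reads + sum(r))
})

test_that("quality filter uses the Phred threshold fraction", {
  ins <- "ACGTACGTACGTACGTACGT"  # 20 nt insert + 21 nt adapter = 41 nt read
  read <- paste0(ins, A3)
  hi <- strrep("I", 41)
  lo <- paste0(strrep("#", 5), strrep("I", 36))    # 12% below Q20
  borderline <- paste0(strrep("#", 4), strrep("I", 37))  # 9.8%
  cl <- clean_library(data.frame(seq = rep(read, 3),
                                 qual = c(hi, lo, borderline)), A3, A5)
  expect_equal(cl$stats$clean_reads, 2L)
  expect_equal(unname(cl$stats$removed_by_reason["low_quality"]), 1L)
})

test_that("poly(A) rule: fraction or terminal run", {
  frac <- paste0(strrep("A", 17), "CGT")  # 85% A
  run <- paste0("ACGTACGTCCGT", strrep("A", 8))  # ends with 8 As
  okread <- "ACGTAACGTAACGTAACGTA"
  cl <- clean_library(paste0(c(frac, run, okread), A3), A3, A5)
  expect_equal(unname(cl$stats$removed_by_reason["polyA"]), 2L)
  expect_equal(cl$stats$clean_reads, 1L)
})

test_that("cleaning is idempotent on already-clean inserts", {
  set.seed(8)
  reads <- paste0(vapply(sample(16:28, 40, replace = TRUE),
                         function(l) random_seq(l, 0.45), character(1)), A3)
  cl1 <- clean_library(reads, A3, A5)
  cl2 <- clean_library(paste0(cl1$inserts, A3), A3, A5)
  expect_equal(length(cl2$inserts), length(cl1$inserts))
  expect_equal(sum(cl2$stats$removed_by_reason), 0L)
})

test_that("collapse_tags counts, conserves and orders deterministically", {
  out <- collapse_tags(c("AAGCT", "AAGCT"), c("AAGCT", "GGCAT"))
  expect_equal(out$sequence, c("AAGCT", "GGCAT"))
  expect_equal(out$count_ck, c(2L, 0L))
  expect_equal(out$count_cd, c(1L, 1L))
  expect_equal(nrow(collapse_tags(character(0), character(0))), 0L)
  # brute-force recount on random input
  set.seed(9)
  ck <- sample(c("AC", "GT", "CA", "TG"), 200, replace = TRUE)
  cd <- sample(c("AC", "GT", "TT"), 150, replace = TRUE)
  tg <- collapse_tags(ck, cd)
  expect_equal(sum(tg$count_ck), 200L)
  expect_equal(sum(tg$count_cd), 150L)
  for (i in seq_len(nrow(tg))) {
    expect_equal(tg$count_ck[i], sum(ck == tg$sequence[i]))
    expect_equal(tg$count_cd[i], sum(cd == tg$sequence[i]))
  }
  # descending total count, ties alphabetical
  tot <- tg$count_ck + tg$count_cd
  expect_true(all(diff(tot) <= 0))
})

test_that("length distribution in total and unique modes", {
  tg <- tag_table(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTACGT"),
                  ck = c(3L, 1L))
  tot <- length_distribution(tg, "total")
  expect_equal(tot$ck_percent[tot$length == 21], 75)
  expect_equal(tot$ck_percent[tot$length == 24], 25)
  uni <- length_distribution(tg, "unique")
  expect_equal(uni$ck_percent[uni$length == 21], 50)
  expect_equal(uni$ck_percent[uni$length == 24], 50)
  expect_equal(sum(tot$ck_percent), 100)
  one <- length_distribution(tag_table("ACGTACGTACGTACGTACGTA", 5L), "total")
  expect_equal(one$ck_percent[one$length == 21], 100)
})

test_that("first-base bias rows are per-length fractions summing to 1", {
  tg <- tag_table(c("TAAGACGTACGTACGTACGTA", "CAAGACGTACGTACGTACGTA"),
                  ck = c(5L, 1L))
  fb <- first_base_bias(tg)
  expect_equal(nrow(fb), 1L)  # only 21 nt occupied; empty lengths omitted
  expect_equal(fb$length, 21L)
  expect_equal(fb$U, 0.5)
  expect_equal(fb$C, 0.5)
  expect_equal(unname(rowSums(fb[, c("A", "C", "G", "U")])), 1)
  one <- first_base_bias(tag_table("TACGTACGTACGTACGTACGT", 2L))
  expect_equal(one$U, 1.0)
})
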