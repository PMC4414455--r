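# Conserved matching, cluster quantification, novel hairpin prediction,
# star detection and isomiR enumeration.

test_that("match_conserved honours the two-mismatch bound", {
  set.seed(13)
  ref <- c(miRX = random_seq(21, 0.5))
  t0 <- ref[[1]]
  t2 <- mutate_at(t0, c(3, 15))
  t3 <- mutate_at(t0, c(3, 9, 15))
  tg <- tag_table(c(t0, t2, t3), c(10L, 5L, 7L))
  hits <- match_conserved(tg, ref)
  expect_equal(hits$sequence, c(t0, t2))
  expect_equal(hits$mismatches, c(0L, 2L))
  # length tolerance: +-2 nt allowed, 3 nt not
  short <- substr(t0, 3, 21)       # 2 nt 5' trim
  shorter <- substr(t0, 4, 21)     # 3 nt
  h2 <- match_conserved(tag_table(c(short, shorter), c(1L, 1L)), ref)
  expect_equal(h2$sequence, short)
  expect_equal(h2$mismatches, 0L)
})

test_that("best hit per tag: fewest mismatches, then first reference name", {
  set.seed(14)
  s <- random_seq(21)
  refs <- c(zeta = mutate_at(s, 5), alpha = s, beta = s)
  hits <- match_conserved(tag_table(s, 1L), refs)
  expect_equal(hits$ref, "alpha")
  expect_equal(hits$mismatches, 0L)
})

test_that("clusters take the dominant representative and sum expression", {
  set.seed(15)
  a <- random_seq(21)
  b <- mutate_at(a, 4)
  mem <- data.frame(group = "g1", sequence = c(a, b),
                    count_ck = c(10L, 3L), count_cd = c(0L, 0L),
                    stringsAsFactors = FALSE)
  rec <- cluster_and_quantify(mem, "conserved")
  expect_equal(rec$representative_seq, a)
  expect_equal(rec$expr_ck, 13L)
  # tie on counts: alphabetically smallest wins
  mem2 <- mem; mem2$count_ck <- c(5L, 5L)
  rec2 <- cluster_and_quantify(mem2, "conserved")
  expect_equal(rec2$representative_seq, min(a, b))
})

test_that("novel expression rule: end deviations ok, middle mismatches not", {
  set.seed(16)
  mat <- random_seq(21)
  middle_sub <- mutate_at(mat, 11)
  end_sub <- mutate_at(mat, 2)
  trim3 <- substr(mat, 1, 19)       # 2 nt trimmed at the 3' end
  trim4 <- substr(mat, 1, 17)       # 4 nt: exceeds the bound
  mem <- data.frame(group = "n1",
                    sequence = c(mat, middle_sub, end_sub, trim3, trim4),
                    count_ck = c(20L, 4L, 2L, 1L, 8L),
                    count_cd = rep(0L, 5), ref_seq = mat,
                    stringsAsFactors = FALSE)
  rec <- cluster_and_quantify(mem, "novel")
  expect_equal(rec$representative_seq, mat)
  # mat + end_sub + trim3 counted; middle_sub and trim4 excluded
  expect_equal(rec$expr_ck, 20L + 2L + 1L)
  expect_setequal(rec$members[[1]], c(mat, end_sub, trim3))
})

test_that("expression sums are invariant to member order", {
  set.seed(17)
  mat <- random_seq(21)
  mem <- data.frame(group = "n1",
                    sequence = c(mat, mutate_at(mat, 2), substr(mat, 2, 21)),
                    count_ck = c(9L, 5L, 2L), count_cd = c(1L, 0L, 4L),
                    ref_seq = mat, stringsAsFactors = FALSE)
  r1 <- cluster_and_quantify(mem, "novel")
  r2 <- cluster_and_quantify(mem[c(3, 1, 2), ], "novel")
  expect_equal(r1$expr_ck, r2$expr_ck)
  expect_equal(r1$expr_cd, r2$expr_cd)
  expect_equal(r1$representative_seq, r2$representative_seq)
})

test_that("planted hairpins are recovered as novel miRNAs", {
  set.seed(18)
  pre <- one_premirna_df(arm = "5p")
  tx <- c(Unigene1 = paste0(random_seq(120), pre$sequence, random_seq(150)),
          Unigene2 = random_seq(800))
  tags <- tag_table(c(pre$mature_seq, random_seq(21)), c(25L, 12L))
  nv <- predict_novel(tags, tx)
  expect_equal(nrow(nv$candidates), 1L)
  expect_equal(nv$candidates$unigene, "Unigene1")
  expect_equal(nv$candidates$arm, "5p")
  expect_lte(nv$candidates$mfe, -18)
  expect_lte(nv$candidates$mfei, -0.5)
  expect_equal(nv$records$representative_seq, pre$mature_seq)
  expect_equal(nv$records$expr_ck, 25L)
  # the accepted candidate satisfies every criterion when re-checked
  cand <- nv$candidates
  pt <- parse_dotbracket(cand$dotbracket)
  mat <- (cand$mature_start + 1):cand$mature_end
  expect_gte(sum(pt[mat] > 0), 16)
  expect_lte(sum(pt[mat] == 0), 4)
  partners <- pt[mat][pt[mat] > 0]
  expect_true(all(partners > cand$mature_end) ||
                all(partners <= cand$mature_start))
  expect_equal(eval_structure(cand$precursor_seq, cand$dotbracket),
               cand$mfe, tolerance = 1e-6)
})

test_that("tags on unstructured transcripts yield no candidates", {
  set.seed(19)
  tag <- random_seq(21)
  tx <- c(U1 = paste0(random_seq(200), tag, random_seq(200)))
  nv <- predict_novel(tag_table(tag, 30L), tx)
  expect_equal(nrow(nv$candidates), 0L)
})

test_that("a mature straddling the loop is rejected", {
  set.seed(20)
  stem <- random_seq(33, 0.55)
  hp <- paste0(stem, random_seq(10, 0.3), mirstress:::revcomp(stem))
  # tag centered on the terminal loop
  tag <- substr(hp, 25, 45)
  tx <- c(U1 = paste0(random_seq(100), hp, random_seq(100)))
  nv <- predict_novel(tag_table(tag, 30L), tx)
  expect_equal(nrow(nv$candidates), 0L)
})

test_that("known-mature hairpins are reported as conserved loci", {
  set.seed(21)
  pre <- one_premirna_df()
  tx <- c(U1 = paste0(random_seq(100), pre$sequence, random_seq(100)))
  tags <- tag_table(pre$mature_seq, 40L)
  nv <- predict_novel(tags, tx, known_mature = c(ref1 = pre$mature_seq))
  expect_equal(nrow(nv$candidates), 0L)
  expect_equal(nrow(nv$known_loci), 1L)
  # an isomiR-seeded hairpin at the same locus is attributed by position
  iso <- substr(pre$sequence, pre$mature_start - 2, pre$mature_end + 1)
  nv2 <- predict_novel(tag_table(iso, 40L), tx,
                       known_mature = c(ref1 = pre$mature_seq))
  expect_equal(nrow(nv2$candidates), 0L)
  expect_equal(nrow(nv2$known_loci), 1L)
})

test_that("star detection requires the 2-nt overhang duplex geometry", {
  set.seed(22)
  stem <- random_seq(40, 0.55)
  loop <- random_seq(10, 0.3)
  hp <- paste0(stem, loop, mirstress:::revcomp(stem))
  n <- nchar(hp)
  ms <- 5L; me <- 26L  # 21-nt mature on the 5p arm, 0-based [5, 26)
  mature <- substr(hp, ms + 1, me)
  # perfect-stem partner of 1-based position q is n + 1 - q; star span
  # 0-based [n - me + 2, n - ms + 2)
  star <- substr(hp, n - me + 3, n - ms + 2)
  shifted <- substr(hp, n - me - 2, n - ms - 3)  # 5 nt off
  tx <- c(U1 = paste0(random_seq(80), hp, random_seq(80)))
  tags <- tag_table(c(mature, star, shifted), c(30L, 8L, 8L))
  nv <- predict_novel(tags, tx)
  expect_equal(nrow(nv$candidates), 1L)
  st <- detect_star(nv$candidates[1, ], tags)
  expect_false(is.null(st))
  expect_equal(st$star_seq, star)
  expect_equal(st$arm, "3p")
  # without the star tag: nothing on the opposite arm
  st2 <- detect_star(nv$candidates[1, ], tag_table(mature, 30L))
  expect_null(st2)
  # a 5-nt shifted tag violates the overhang tolerance
  st3 <- detect_star(nv$candidates[1, ], tag_table(c(mature, shifted),
                                                   c(30L, 8L)))
  expect_null(st3)
})

test_that("isomiR offsets follow the trim/extension convention", {
  set.seed(23)
  pre <- one_premirna_df(stem_len = 40)
  cand <- list(precursor_seq = pre$sequence,
               mature_start = pre$mature_start,
               mature_end = pre$mature_end, mature_seq = pre$mature_seq)
  mat <- pre$mature_seq
  minus_first <- substr(pre$sequence, pre$mature_start + 2, pre$mature_end)
  ext3 <- substr(pre$sequence, pre$mature_start + 1, pre$mature_end + 2)
  tg <- tag_table(c(mat, minus_first, ext3), c(50L, 7L, 3L))
  iso <- enumerate_isomirs(cand, tg)
  expect_equal(nrow(iso), 3L)
  i0 <- iso[iso$sequence == mat, ]
  expect_equal(c(i0$offset_5p, i0$offset_3p), c(0L, 0L))
  expect_true(i0$is_canonical && i0$is_dominant)
  i1 <- iso[iso$sequence == minus_first, ]
  expect_equal(c(i1$offset_5p, i1$offset_3p), c(1L, 0L))
  i2 <- iso[iso$sequence == ext3, ]
  expect_equal(c(i2$offset_5p, i2$offset_3p), c(0L, -2L))
  expect_equal(iso$count_ck[match(c(mat, minus_first, ext3),
                                  iso$sequence)], c(50L, 7L, 3L))
})
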