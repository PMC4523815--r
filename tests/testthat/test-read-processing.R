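mkread <- function(seq, q) {
  tag_reads("r1", seq, intToUtf8(rep(q, nchar(seq)) + 33L))
}

test_that("qc_filter honors the literal rule boundaries", {
  len <- 150
  base <- strrep("A", len)
  q40 <- intToUtf8(rep(40 + 33L, len))
  clean <- tag_reads("a", base, q40)
  expect_true(qc_filter(clean, "lenient")$pass)
  expect_true(qc_filter(clean, "stringent")$pass)

  # exactly 1 N: passes lenient (reject at >5), fails stringent (>=1)
  one_n <- tag_reads("b", paste0("N", strrep("A", len - 1)), q40)
  expect_true(qc_filter(one_n, "lenient")$pass)
  r <- qc_filter(one_n, "stringent")
  expect_false(r$pass)
  expect_match(r$reasons, "too_many_n")

  # exactly 4 bases below Q20: fails stringent ("more than 3"), passes lenient
  q <- rep(40L, len); q[1:4] <- 19L
  four_low <- tag_reads("c", base, intToUtf8(q + 33L))
  expect_false(qc_filter(four_low, "stringent")$pass)
  expect_true(qc_filter(four_low, "lenient")$pass)
  q[4] <- 40L # exactly 3: boundary passes stringent
  expect_true(qc_filter(tag_reads("c2", base, intToUtf8(q + 33L)),
                        "stringent")$pass)

  # exactly 10 bases at Q14 with mean >= 30: boundary passes lenient
  q <- rep(40L, len); q[1:10] <- 14L
  expect_true(mean(q) >= 30)
  expect_true(qc_filter(tag_reads("d", base, intToUtf8(q + 33L)),
                        "lenient")$pass)
  q[11] <- 14L # 11 low bases: rejected
  expect_false(qc_filter(tag_reads("d2", base, intToUtf8(q + 33L)),
                         "lenient")$pass)

  # empty read fails with its own reason
  r0 <- qc_filter(tag_reads("e", "", ""), "lenient")
  expect_false(r0$pass)
  expect_equal(r0$reasons, "empty")
})

test_that("qc_filter agrees with a brute-force recount on 1000 random reads", {
  reads <- random_reads(1000, len = 60, seed = 33)
  for (prof_name in c("lenient", "stringent")) {
    prof <- qc_profile(prof_name)
    got <- qc_filter(reads, prof)$pass
    want <- vapply(seq_len(nrow(reads)), function(i)
      oracle_qc(reads$seq[i], reads$qual[i], prof), TRUE)
    expect_identical(got, want)
  }
})

test_that("stringent-pass reads are a subset of lenient-pass reads", {
  reads <- random_reads(800, len = 100, seed = 44, q_range = c(10, 41))
  s <- qc_filter(reads, "stringent")$pass
  l <- qc_filter(reads, "lenient")$pass
  expect_true(all(l[s]))
})

test_that("window_trim matches a brute-force sliding mean and is idempotent", {
  # all high: unchanged; all low: emptied
  expect_equal(window_trim(mkread(strrep("A", 50), 40))$seq, strrep("A", 50))
  expect_equal(nchar(window_trim(mkread(strrep("A", 50), 10))$seq), 0)
  # shorter than the window: unchanged
  expect_equal(window_trim(mkread(strrep("A", 10), 5))$seq, strrep("A", 10))

  # derived case: Q40 for 60 bases then Q20; oracle finds the first
  # failing window start
  q <- c(rep(40L, 60), rep(20L, 40))
  rd <- tag_reads("x", strrep("A", 100), intToUtf8(q + 33L))
  oracle_cut <- function(q, w = 20, minq = 30) {
    for (s in 1:(length(q) - w + 1))
      if (mean(q[s:(s + w - 1)]) < minq) return(s - 1L)
    length(q)
  }
  tr <- window_trim(rd)
  expect_equal(nchar(tr$seq), oracle_cut(q))

  # property: idempotent, never lengthens (random reads)
  reads <- random_reads(100, len = 70, seed = 5, q_range = c(15, 41))
  t1 <- window_trim(reads)
  t2 <- window_trim(t1)
  expect_identical(t1$seq, t2$seq)
  expect_true(all(nchar(t1$seq) <= nchar(reads$seq)))
})

test_that("merge_pairs handles exact, noisy and impossible overlaps", {
  set.seed(8)
  tmpl <- random_seq(110)
  r1 <- tag_reads("p/1", substr(tmpl, 1, 70), strrep("I", 70))   # Q40
  r2seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tmpl, 41, 110))))
  r2 <- tag_reads("p/2", r2seq, strrep("I", 70))
  m <- merge_pairs(r1, r2)
  expect_false(m$failed)
  expect_equal(m$merged$seq, tmpl)          # 30-base overlap reconstructs
  expect_equal(nchar(m$merged$seq), 70 + 70 - 30)

  # disjoint sequences fail
  d1 <- tag_reads("q/1", random_seq(40), strrep("I", 40))
  d2 <- tag_reads("q/2", random_seq(40), strrep("I", 40))
  expect_true(merge_pairs(d1, d2)$failed)

  # disagreeing bases follow the higher quality
  a <- strrep("A", 30)
  b <- strrep("A", 30); substr(b, 10, 10) <- "C" # disagrees at overlap pos 10
  qa <- rep(20L, 30); qb <- rep(35L, 30)
  p1 <- tag_reads("z/1", a, intToUtf8(qa + 33L))
  p2 <- tag_reads("z/2", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(b))), intToUtf8(rev(qb) + 33L))
  mm <- merge_pairs(p1, p2, min_overlap = 30, max_mismatch_density = 0.25)
  expect_false(mm$failed)
  expect_equal(substr(mm$merged$seq, 10, 10), "C") # r2 base had higher quality
  expect_equal(utf8ToInt(mm$merged$qual) - 33L, pmax(qa, qb))
})

test_that("merging error-free simulated pairs reconstructs the template", {
  refs <- world_refs1()
  d1 <- community_design(names(refs$genes), 1, 3.4e6, 2)
  m <- platform_error_model(0, 0, 0, read_length = 170, paired = TRUE)
  s <- simulate_sample(d1, refs, "V4", m, 40, stagger_max = 0, seed = 2)
  mg <- merge_pairs(s$r1, s$r2)
  expect_false(any(mg$failed))
  amps <- region_sequences(refs, "V4")
  expect_true(all(mg$merged$seq %in% amps))
})

test_that("primer/stagger trimming follows IUPAC semantics and offsets", {
  primer <- "ACGY"
  insert <- "GGTTGGTTGG"
  rd <- function(s) tag_reads("r", s, strrep("I", nchar(s)))
  # exact match behind a 2-base stagger
  out <- trim_primer_stagger(rd(paste0("NN", "ACGT", insert)), primer,
                             stagger_max = 3)
  expect_equal(out$offset, 2L)
  expect_equal(out$trimmed$seq, insert)
  # no primer: failure
  out2 <- trim_primer_stagger(rd(insert), primer, stagger_max = 3)
  expect_true(is.na(out2$offset))
  expect_equal(nrow(out2$failed), 1)
  # one mismatch at offset 1, allowed when max_mismatches = 1:
  # primer ACGY vs read AGGT mismatches only at position 2 (C vs G)
  out3 <- trim_primer_stagger(rd(paste0("T", "AGGT", insert)), primer,
                              stagger_max = 3, max_mismatches = 1)
  expect_equal(out3$offset, 1L)
  expect_equal(out3$trimmed$seq, insert)
  # smallest offset wins when several match
  out4 <- trim_primer_stagger(rd(paste0("ACGT", "ACGT", insert)), primer,
                              stagger_max = 3)
  expect_equal(out4$offset, 0L)
  expect_error(trim_primer_stagger(rd("ACGT"), "", 0), "non-empty")
})

test_that("kmer screen flags contaminated reads on either strand", {
  set.seed(10)
  contam <- random_seq(120)
  reads <- tag_reads(
    c("hit", "revhit", "clean", "onesub"),
    c(substr(contam, 20, 80),
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contam, 30, 90)))),
      random_seq(60),
      { x <- substr(contam, 10, 69) # central substitution, flanks intact
        substr(x, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                     substr(x, 30, 30))[1]; x }),
    strrep("I", c(61, 61, 60, 60)))
  sc <- kmer_screen(reads, contam, k = 21, min_hits = 1)
  expect_setequal(sc$flagged$id, c("hit", "revhit", "onesub"))
  expect_equal(sc$kept$id, "clean")
  expect_equal(nrow(sc$kept) + nrow(sc$flagged), nrow(reads))
  # read shorter than k is trivially kept
  short <- tag_reads("s", "ACGTACGT", "IIIIIIII")
  expect_equal(nrow(kmer_screen(short, contam, k = 21)$kept), 1)
  expect_error(kmer_screen(short, character(0)), "empty")
})

test_that("qc_report percentages and undefined markers", {
  rep <- qc_report(c("a", "b", "c"), c(200, 100, 10), c(100, 80, 0),
                   c(50, 80, 0))
  expect_equal(rep$pct_passing, c(50.00, 100.00, NA_real_))
})

test_that("stringent pass percentage never exceeds lenient on simulated data", {
  refs <- world_refs1()
  d1 <- community_design(names(refs$genes), 1, 3.4e6, 2)
  s <- simulate_sample(d1, refs, "V4", miseq_error_model(read_length = 320,
                                                         paired = FALSE),
                       600, seed = 19)
  pl <- mean(qc_filter(s$reads, "lenient")$pass)
  ps <- mean(qc_filter(s$reads, "stringent")$pass)
  expect_lte(ps, pl)
  expect_gt(pl, 0) # the stated world is not degenerate
})

test_that("truncate_reads is a hard prefix cut", {
  reads <- random_reads(10, len = 50, seed = 3)
  tr <- truncate_reads(reads, 20)
  expect_true(all(nchar(tr$seq) == 20))
  expect_identical(tr$seq, substr(reads$seq, 1, 20))
  expect_identical(truncate_reads(reads, 99)$seq, reads$seq)
})
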