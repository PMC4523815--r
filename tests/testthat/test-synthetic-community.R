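test_that("reference sets are deterministic and structurally sound", {
  r1 <- generate_reference_set(9, 1, seed = 1)
  expect_length(r1$genes, 9)
  expect_equal(length(r1$tree$tip.label), 9) # one copy each: tips = organisms

  r2 <- generate_reference_set(1, 2, seed = 1)
  copies <- r2$genes[[1]]$copies
  expect_length(copies, 2)
  a <- strsplit(copies[1], "")[[1]]; b <- strsplit(copies[2], "")[[1]]
  expect_lte(mean(a != b), 0.02) # copies differ at <= 2% of sites

  ra <- generate_reference_set(9, 2, seed = 7)
  rb <- generate_reference_set(9, 2, seed = 7)
  expect_identical(ra$genes, rb$genes)
  expect_identical(ape::write.tree(ra$tree), ape::write.tree(rb$tree))
  expect_equal(length(ra$tree$tip.label), 18)

  # distinct genus lineages, 6 ranks each
  lin <- vapply(ra$genes, function(g) g$lineage, "")
  expect_equal(anyDuplicated(vapply(strsplit(lin, ";"), `[`, "", 6)), 0L)
  expect_true(all(lengths(strsplit(lin, ";")) == 6))

  expect_error(generate_reference_set(0, 1, seed = 1), "empty")
})

test_that("primer binding sites are embedded at the region boundaries", {
  refs <- world_refs9()
  p <- tag_primers()
  for (g in refs$genes) {
    for (region in c("V4", "V6V8", "V7V8")) {
      rc <- g$region_coords[[region]]
      for (cp in g$copies) {
        amp <- substr(cp, rc[1] + 1, rc[2])
        fwd <- p[[region]]$fwd
        rev <- p[[region]]$rev
        # forward primer at the start, reverse complement site at the end
        expect_equal(trim_primer_stagger(
          tag_reads("x", amp, strrep("I", nchar(amp))), fwd,
          stagger_max = 0)$offset, 0L)
        tail_seq <- substr(amp, nchar(amp) - nchar(rev) + 1, nchar(amp))
        expect_equal(trim_primer_stagger(
          tag_reads("x", as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(tail_seq))),
            strrep("I", nchar(rev))), rev, stagger_max = 0)$offset, 0L)
      }
    }
  }
})

test_that("zero-rate model emits templates verbatim with stagger prefixes", {
  refs <- world_refs9()
  m0 <- platform_error_model(0, 0, 0, read_length = 500)
  s <- simulate_sample(world_design(), refs, "V4", m0, 200,
                       stagger_max = 0, seed = 3)
  amps <- region_sequences(refs, "V4")
  expect_true(all(s$reads$seq %in% amps))
  expect_equal(sum(s$truth$n_sub) + sum(s$truth$n_ins) + sum(s$truth$n_del), 0)

  s3 <- simulate_sample(world_design(), refs, "V4", m0, 200,
                        stagger_max = 3, seed = 3)
  expect_true(all(s3$truth$stagger %in% 0:3))
  ok <- mapply(function(seq, st) substr(seq, st + 1, nchar(seq)) %in% amps,
               s3$reads$seq, s3$truth$stagger)
  expect_true(all(ok))
})

test_that("injected substitutions follow the binomial oracle", {
  refs <- world_refs1()
  d1 <- community_design(names(refs$genes), 1, 3.4e6, 2)
  m <- platform_error_model(0.002, 0, 0, read_length = 400)
  s <- simulate_sample(d1, refs, "V4", m, 10000, stagger_max = 0, seed = 9)
  total_bases <- sum(nchar(s$reads$seq)) + sum(s$truth$n_del) # template bases
  exp_subs <- 0.002 * total_bases
  sd3 <- 3 * sqrt(total_bases * 0.002 * 0.998)
  expect_lt(abs(sum(s$truth$n_sub) - exp_subs), sd3)
  expect_equal(sum(s$truth$n_ins), 0)
  expect_equal(sum(s$truth$n_del), 0)
})

test_that("per-read truth records are internally consistent", {
  refs <- world_refs9()
  m <- pyro454_error_model(read_length = 480)
  s <- simulate_sample(world_design(), refs, "V6V8", m, 300,
                       stagger_max = 2, chimera_fraction = 0.1, seed = 4)
  npos <- function(x) ifelse(nzchar(x), lengths(strsplit(x, ",")), 0L)
  expect_equal(npos(s$truth$sub_pos), s$truth$n_sub)
  expect_equal(npos(s$truth$ins_pos), s$truth$n_ins)
  expect_equal(npos(s$truth$del_pos), s$truth$n_del)
  expect_equal(anyDuplicated(s$truth$read_id), 0L)
  expect_setequal(s$truth$read_id, s$reads$id)
  chim <- s$truth[s$truth$chimera, ]
  expect_true(all(!is.na(chim$parent1) & !is.na(chim$parent2)))
  expect_true(all(chim$parent1 != chim$parent2))
})

test_that("sample composition converges to MEND", {
  refs <- world_refs9()
  d <- world_design()
  m <- platform_error_model(0, 0, 0, read_length = 400)
  s <- simulate_sample(d, refs, "V4", m, 10000, stagger_max = 0, seed = 12)
  mend <- expected_composition(d)$mend
  counts <- table(factor(s$truth$organism, levels = d$organism))
  for (i in seq_along(mend)) {
    sd3 <- 3 * sqrt(10000 * mend[i] * (1 - mend[i]))
    expect_lt(abs(as.numeric(counts[i]) - 10000 * mend[i]), sd3 + 1e-9)
  }
})

test_that("indel positions are uniform when the homopolymer boost is off", {
  refs <- world_refs1()
  d1 <- community_design(names(refs$genes), 1, 3.4e6, 2)
  # flat quality profile so error weights are position-independent
  m <- platform_error_model(0, 0.004, 0.004, homopolymer_multiplier = 1,
                            quality_decay = function(p) rep(35, length(p)),
                            quality_sd = 0, read_length = 400)
  s <- simulate_sample(d1, refs, "V4", m, 5000, stagger_max = 0, seed = 21)
  pos <- as.integer(unlist(strsplit(
    c(s$truth$ins_pos, s$truth$del_pos)[
      nzchar(c(s$truth$ins_pos, s$truth$del_pos))], ",")))
  L <- nchar(region_sequences(refs, "V4")[1])
  bins <- cut(pos, breaks = seq(0, L, length.out = 11))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("chimera parameters are validated and zero reads are legal", {
  refs <- world_refs9()
  m <- platform_error_model(read_length = 300)
  expect_error(simulate_sample(world_design(), refs, "V4", m, 10,
                               chimera_fraction = 1.5), "chimera_fraction")
  s0 <- simulate_sample(world_design(), refs, "V4", m, 0, seed = 1)
  expect_equal(nrow(s0$reads), 0)
  expect_equal(nrow(s0$truth), 0)
  expect_error(simulate_sample(world_design(), refs, "V9", m, 10), "region")
})

test_that("fixtures round-trip with stable checksums", {
  refs <- world_refs1()
  d1 <- community_design(names(refs$genes), 1, 3.4e6, 2)
  m <- platform_error_model(0.001, 0, 0, read_length = 300)
  s <- simulate_sample(d1, refs, "V4", m, 50, seed = 6, sample_id = "T1")
  dir1 <- withr::local_tempdir()
  man1 <- write_fixture(list(s), dir1, design = d1, refs = refs)
  # fastq + truth + design + fasta + lineages + tree (+ manifest on disk)
  expect_equal(nrow(man1), 6)
  back <- read_fastq(file.path(dir1, "T1.fastq.gz"))
  expect_equal(back$seq, s$reads$seq)
  expect_equal(back$qual, s$reads$qual)
  expect_equal(back$id, s$reads$id)
  refs_back <- read_fasta(file.path(dir1, "references.fasta"))
  expect_equal(unname(refs_back), unname(reference_sequences(refs)))

  s2 <- simulate_sample(d1, refs, "V4", m, 50, seed = 6, sample_id = "T1")
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture(list(s2), dir2, design = d1, refs = refs)
  expect_equal(man1$md5[man1$file != "T1.fastq.gz"],
               man2$md5[man2$file != "T1.fastq.gz"])
  # gzip may embed mtime; compare decompressed payloads instead
  expect_identical(readLines(gzfile(file.path(dir1, "T1.fastq.gz"))),
                   readLines(gzfile(file.path(dir2, "T1.fastq.gz"))))
})
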