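test_that("dereplication collapses identical sequences with per-sample counts", {
  seqs <- c("AAAA", "CCCC", "AAAA", "GGGG", "AAAA", "CCCC")
  samp <- c("S1", "S1", "S2", "S2", "S1", "S2")
  cl <- dereplicate(seqs, samp)
  expect_equal(cl$sequence, c("AAAA", "CCCC", "GGGG"))
  expect_equal(cluster_sizes(cl), c(3L, 2L, 1L))
  expect_equal(unname(cl$counts[1, ]), c(2L, 1L))
  expect_equal(unname(cl$counts[2, ]), c(1L, 1L))
  # hash-count oracle on a random multiset
  set.seed(3)
  pool <- replicate(12, random_seq(20))
  draws <- sample(pool, 300, replace = TRUE)
  cl2 <- dereplicate(draws, "S1")
  want <- sort(as.integer(table(draws)), decreasing = TRUE)
  expect_equal(cluster_sizes(cl2), want)
  expect_equal(sum(cluster_sizes(cl2)), 300)
  # all distinct
  cl3 <- dereplicate(pool, "S1")
  expect_true(all(cluster_sizes(cl3) == 1L))
})

test_that("greedy clustering merges by identity threshold deterministically", {
  set.seed(11)
  s1 <- random_seq(100)
  v <- strsplit(s1, "")[[1]]
  v[50] <- setdiff(c("A", "C", "G", "T"), v[50])[1]
  near <- paste(v, collapse = "") # 99% identical
  w <- strsplit(s1, "")[[1]]
  at <- sample(100, 10)
  w[at] <- vapply(w[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  far <- paste(w, collapse = "") # ~90% identical

  cl <- dereplicate(c(rep(s1, 5), rep(near, 3), rep(far, 4)), "S1")
  at97 <- greedy_cluster(cl, 0.97)
  expect_equal(length(at97$sequence), 2) # near joins, far stays apart
  expect_equal(sum(cluster_sizes(at97)), 12)
  expect_equal(at97$sequence[1], s1) # centroid = most abundant member

  at999 <- greedy_cluster(cl, 1.0)
  expect_equal(length(at999$sequence), 3) # threshold 1 on derep = identity
  expect_error(greedy_cluster(cl, 0), "identity_threshold")
  expect_error(greedy_cluster(cl, 1.2), "identity_threshold")
})

test_that("min-size filtering reports discarded reads", {
  cl <- dereplicate(c(rep("AAAA", 10), rep("CCCC", 2), "GGGG"), "S1")
  f <- filter_min_size(cl, 3)
  expect_equal(cluster_sizes(f), 10L)
  expect_equal(attr(f, "discarded_reads"), 3L)
  f1 <- filter_min_size(cl, 1)
  expect_equal(length(f1$sequence), 3)
  expect_equal(attr(f1, "discarded_reads"), 0L)
})

test_that("constructed chimeras are flagged; parents and kin are not", {
  set.seed(21)
  A <- random_seq(200)
  v <- strsplit(A, "")[[1]]
  at <- sample(200, 20) # B is ~10% divergent from A
  v[at] <- vapply(v[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  B <- paste(v, collapse = "")
  chim <- paste0(substr(A, 1, 100), substr(B, 101, 200))
  cl <- dereplicate(c(rep(A, 40), rep(B, 40), rep(chim, 5)), "S1")
  flags <- chimera_flag_denovo(cl)
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  # candidate identical to a parent is never flagged
  cl2 <- dereplicate(c(rep(A, 40), rep(B, 40), rep(A, 5)), "S1")
  expect_false(any(chimera_flag_denovo(cl2)))
  # fewer than two eligible parents: unflagged
  cl3 <- dereplicate(c(rep(A, 40), rep(chim, 5)), "S1")
  expect_false(any(chimera_flag_denovo(cl3)))
  rm <- remove_flagged(cl, flags)
  expect_equal(length(rm$sequence), 2)
  expect_equal(attr(rm, "discarded_reads"), 5L)
})

test_that("OTU tables conserve counts and can exclude eukaryotes", {
  cl <- dereplicate(c(rep("AAAA", 4), rep("CCCC", 3), rep("GGGG", 2)),
                    c(rep("S1", 5), rep("S2", 4)))
  tab <- build_otu_table(cl)
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(sum(tab), 9)
  lineage <- c("Bacteria;x;x;x;x;g1", "Eukaryota;y;y;y;y;g2",
               "Bacteria;z;z;z;z;g3")
  tab2 <- build_otu_table(cl, lineage = lineage, exclude_eukaryotes = TRUE)
  expect_equal(nrow(tab2), 2L)
  expect_false(any(grepl("^Eukaryota", attr(tab2, "lineage"))))
  tab3 <- build_otu_table(cl, lineage = lineage, exclude_eukaryotes = FALSE)
  expect_equal(nrow(tab3), 3L)
})

test_that("rarefaction subsamples exactly and drops shallow columns", {
  tab <- matrix(c(50, 30, 20, 5, 3, 2), nrow = 3,
                dimnames = list(paste0("o", 1:3), c("S1", "S2")))
  expect_warning(r <- rarefy(tab, depth = 50, seed = 1), "below depth")
  expect_equal(colnames(r), "S1")
  expect_equal(sum(r), 50)
  # column total equal to depth is returned unchanged
  r2 <- rarefy(tab[, 1, drop = FALSE], depth = 100, seed = 1)
  expect_equal(unname(r2[, 1]), c(50, 30, 20))
  # deterministic per seed
  expect_identical(rarefy(tab[, 1, drop = FALSE], 60, seed = 9),
                   rarefy(tab[, 1, drop = FALSE], 60, seed = 9))
  expect_error(rarefy(tab, depth = 0), "positive")
})

test_that("rarefied OTU means follow the hypergeometric expectation", {
  counts <- c(400, 100, 40, 10, 4, 2)
  tab <- matrix(counts, ncol = 1, dimnames = list(paste0("o", 1:6), "S1"))
  depth <- 200
  draws <- vapply(1:100, function(s) rarefy(tab, depth, seed = s)[, 1],
                  numeric(6))
  # per-OTU mean count ~ depth * n_k / N within 3 SD over 100 seeds
  N <- sum(counts)
  for (k in seq_along(counts)) {
    mu <- depth * counts[k] / N
    v <- depth * (counts[k] / N) * (1 - counts[k] / N) * (N - depth) / (N - 1)
    expect_lt(abs(mean(draws[k, ]) - mu), 3 * sqrt(v / 100) + 1e-9)
  }
  # observed-OTU count is non-decreasing in depth on average (exact here)
  obs <- vapply(c(10, 50, 150, 300), function(d)
    mean(vapply(1:20, function(s) sum(rarefy(tab, d, seed = s)[, 1] > 0), 1)),
    1)
  expect_true(all(diff(obs) >= 0))
})

test_that("reads are conserved through the whole pipeline", {
  refs <- world_refs9()
  m <- miseq_error_model(read_length = 400, paired = FALSE)
  s <- simulate_sample(world_design(), refs, "V4", m, 1500,
                       stagger_max = 0, chimera_fraction = 0.03, seed = 13)
  n0 <- nrow(s$reads)
  dr <- dereplicate(s$reads, "S1")
  expect_equal(sum(cluster_sizes(dr)), n0)
  dn <- greedy_cluster(dr, 0.99)
  expect_equal(sum(cluster_sizes(dn)), n0)
  fl <- filter_min_size(dn, 3)
  expect_equal(sum(cluster_sizes(fl)) + attr(fl, "discarded_reads"), n0)
  flags <- chimera_flag_denovo(fl)
  kept <- remove_flagged(fl, flags)
  expect_equal(sum(cluster_sizes(kept)) + attr(kept, "discarded_reads"),
               sum(cluster_sizes(fl)))
  ot <- greedy_cluster(kept, 0.97)
  expect_equal(sum(cluster_sizes(ot)), sum(cluster_sizes(kept)))
  tab <- build_otu_table(ot)
  expect_equal(sum(tab), sum(cluster_sizes(kept)))
})

test_that("error-free chimera-free data recovers the sampled organisms as OTUs", {
  refs <- world_refs9()
  m0 <- platform_error_model(0, 0, 0, read_length = 400)
  s <- simulate_sample(world_design(), refs, "V4", m0, 3000,
                       stagger_max = 0, seed = 2)
  dr <- dereplicate(s$reads, "S1")
  dn <- greedy_cluster(dr, 0.99)
  fl <- filter_min_size(dn, 3)
  ot <- greedy_cluster(fl, 0.97)
  designed <- sum(table(s$truth$organism) >= 3) # organisms above min size
  expect_equal(length(ot$sequence), designed)
})
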