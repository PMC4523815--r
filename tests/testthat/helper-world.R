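# shared fixtures and independent oracles ------------------------------

# memoized expensive fixtures (built once per test run)
.world <- new.env(parent = emptyenv())

world_design <- function() mock_community_design()

world_refs9 <- function() {
  if (is.null(.world$refs9))
    .world$refs9 <- generate_reference_set(
      9, 2, seed = 42, organism_ids = world_design()$organism)
  .world$refs9
}

world_refs1 <- function() { # single-organism, two copies (error profiling)
  if (is.null(.world$refs1))
    .world$refs1 <- generate_reference_set(1, 2, seed = 5)
  .world$refs1
}

random_reads <- function(n, len = 80, seed = 1, n_prob = 0.02,
                         q_range = c(2, 41)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = ""),
    "")
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(q_range[1]:q_range[2], len, replace = TRUE) + 33L), "")
  tag_reads(sprintf("r%04d", seq_len(n)), seqs, quals)
}

random_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- oracle: plain-matrix affine DP, reference end gaps free ----------
oracle_semiglobal_score <- function(q, r, sc = alignment_scoring()) {
  qq <- strsplit(q, "")[[1]]; rr <- strsplit(r, "")[[1]]
  n <- length(qq); m <- length(rr)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 2:(n + 1)) I[i, 1] <- sc$gap_open + (i - 1) * sc$gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qq[i - 1] == rr[j - 1]) sc$match else sc$mismatch
      M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + s
      I[i, j] <- max(M[i - 1, j] + sc$gap_open + sc$gap_extend,
                     I[i - 1, j] + sc$gap_extend)
      D[i, j] <- max(M[i, j - 1] + sc$gap_open + sc$gap_extend,
                     D[i, j - 1] + sc$gap_extend)
    }
  }
  max(M[n + 1, ], I[n + 1, ], D[n + 1, ])
}

# --- oracle: per-branch UniFrac by nodepath enumeration ---------------
oracle_unifrac <- function(tab, tree, weighted, normalized = TRUE) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  # tips under each edge, via independent root-to-tip path walks
  paths <- lapply(seq_len(nt), function(t) ape::nodepath(tree, root, t))
  n <- ncol(tab)
  cnt <- matrix(0, nt, n, dimnames = list(tree$tip.label, colnames(tab)))
  cnt[rownames(tab), ] <- tab
  totals <- colSums(cnt)
  d <- matrix(0, n, n, dimnames = list(colnames(tab), colnames(tab)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- 0; den <- 0; uni <- 0; either <- 0
    for (e in seq_len(nrow(tree$edge))) {
      child <- tree$edge[e, 2]
      tips <- which(vapply(paths, function(p) child %in% p, TRUE))
      la <- sum(cnt[tips, a]); lb <- sum(cnt[tips, b])
      len <- tree$edge.length[e]
      if (weighted) {
        pa <- la / totals[a]; pb <- lb / totals[b]
        num <- num + len * abs(pa - pb)
        den <- den + len * (pa + pb)
      } else {
        if (xor(la > 0, lb > 0)) uni <- uni + len
        if (la > 0 || lb > 0) either <- either + len
      }
    }
    d[a, b] <- d[b, a] <- if (weighted) {
      if (normalized) { if (den > 0) num / den else 0 } else num
    } else {
      if (either > 0) uni / either else 0
    }
  }
  d
}

# --- oracle: closed-form expected observed OTUs under rarefaction ----
# P(OTU k absent) via the cumulative product form (independent of the
# package's lchoose-based formula)
oracle_expected_otus <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  sum(vapply(counts, function(nk) {
    i <- seq_len(depth) - 1
    1 - prod((N - nk - i) / (N - i))
  }, 1))
}

# simple QC recount by character loops (independent of qc_filter)
oracle_qc <- function(seq, qual, profile) {
  bases <- strsplit(seq, "")[[1]]
  q <- utf8ToInt(qual) - 33L
  if (length(bases) == 0) return(FALSE)
  n_n <- sum(!toupper(bases) %in% c("A", "C", "G", "T"))
  !(n_n > profile$max_n || mean(q) < profile$min_avg_q ||
      sum(q < profile$low_q_threshold) > profile$max_low_q_bases)
}
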