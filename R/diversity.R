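#' Rarefaction curve of observed OTUs
#'
#' For each depth, each sample column is subsampled without replacement
#' `reps` times and the mean (and SD) number of OTUs with non-zero counts
#' is recorded. Depths exceeding a sample's total skip that sample with a
#' warning.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @param depths integer vector of subsampling depths.
#' @param reps subsamples per depth (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `depth`, `mean_otus`,
#'   `sd_otus`.
#' @export
rarefaction_curve <- function(table, depths, reps = 10L, seed = 1L) {
  set.seed(seed)
  totals <- colSums(table)
  out <- list()
  for (s in seq_len(ncol(table))) {
    col <- table[, s]
    pool <- rep.int(seq_along(col), col)
    for (d in depths) {
      if (d > totals[s]) {
        warning("depth ", d, " exceeds total of sample ", colnames(table)[s],
                "; skipped")
        next
      }
      obs <- vapply(seq_len(reps), function(r)
        length(unique(sample(pool, d))), 1L)
      out[[length(out) + 1L]] <- data.frame(
        sample = colnames(table)[s], depth = d, mean_otus = mean(obs),
        sd_otus = stats::sd(obs), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Closed-form expected observed OTUs under rarefaction
#'
#' Hypergeometric expectation: E\[S_obs at depth d\] =
#' sum_k (1 - choose(N - n_k, d) / choose(N, d)) over OTUs k with counts
#' n_k and column total N.
#'
#' @param counts integer vector of OTU counts for one sample.
#' @param depth subsampling depth.
#' @return expected number of observed OTUs.
#' @export
expected_observed_otus <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum |a_k - b_k| / sum (a_k + b_k) over OTUs k. Two all-zero
#' samples are assigned distance 0 with a warning.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @return symmetric distance matrix (samples x samples) with zero
#'   diagonal.
#' @export
bray_curtis <- function(table) {
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- table[, i]; b <- table[, j]
    denom <- sum(a + b)
    if (denom == 0) {
      warning("two all-zero samples; distance set to 0")
      d[i, j] <- d[j, i] <- 0
    } else {
      d[i, j] <- d[j, i] <- sum(abs(a - b)) / denom
    }
  }
  d
}

# per-edge descendant tip index list of an ape tree (postorder)
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  list(tree = tr, desc = desc)
}

#' UniFrac phylogenetic distances
#'
#' Unweighted UniFrac between two samples is the branch length unique to
#' one of them divided by the total branch length covered by either.
#' Weighted UniFrac is sum_b l_b |p_b^A - p_b^B| where p_b is the
#' fraction of a sample's reads descending from branch b; when
#' `normalized`, it is divided by sum_b l_b (p_b^A + p_b^B), constraining
#' it to \[0, 1\].
#'
#' @param table OTU count matrix; rownames must map to tree tips.
#' @param tree an `ape::phylo` with non-negative branch lengths.
#' @param weighted use abundance weighting.
#' @param normalized divide weighted UniFrac by its normalization term.
#' @return symmetric distance matrix (samples x samples).
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ets <- edge_tip_sets(tree)
  tr <- ets$tree
  nedge <- nrow(tr$edge)
  # per-edge per-sample descendant counts
  tipcount <- matrix(0, nrow = length(tr$tip.label), ncol = ncol(table),
                     dimnames = list(tr$tip.label, colnames(table)))
  tipcount[rownames(table), ] <- table
  edge_counts <- matrix(0, nrow = nedge, ncol = ncol(table))
  for (e in seq_len(nedge)) {
    tips <- ets$desc[[tr$edge[e, 2]]]
    edge_counts[e, ] <- colSums(tipcount[tips, , drop = FALSE])
  }
  len <- tr$edge.length
  totals <- colSums(tipcount)
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (weighted) {
      pa <- edge_counts[, i] / max(totals[i], 1)
      pb <- edge_counts[, j] / max(totals[j], 1)
      num <- sum(len * abs(pa - pb))
      val <- if (normalized) {
        den <- sum(len * (pa + pb))
        if (den > 0) num / den else 0
      } else num
    } else {
      ina <- edge_counts[, i] > 0; inb <- edge_counts[, j] > 0
      either <- sum(len[ina | inb])
      unique_len <- sum(len[xor(ina, inb)])
      val <- if (either > 0) unique_len / either else 0
    }
    d[i, j] <- d[j, i] <- val
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for positive-eigenvalue axes only
#' (no Lingoes/Cailliez correction). Axis signs are fixed so the
#' largest-magnitude loading on each axis is positive.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @return list of class `pcoa_coordinates`: `points` (samples x axes),
#'   `eigenvalues` (positive ones, decreasing).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (dm^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1e-12)
  keep <- eig$values > tol
  if (!any(keep)) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(dm), "PC1"))
    return(structure(list(points = pts, eigenvalues = numeric(0)),
                     class = "pcoa_coordinates"))
  }
  vec <- eig$vectors[, keep, drop = FALSE]
  val <- eig$values[keep]
  for (a in seq_along(val)) { # deterministic axis orientation
    m <- which.max(abs(vec[, a]))
    if (vec[m, a] < 0) vec[, a] <- -vec[, a]
  }
  pts <- sweep(vec, 2, sqrt(val), `*`)
  dimnames(pts) <- list(rownames(dm), paste0("PC", seq_along(val)))
  structure(list(points = pts, eigenvalues = val),
            class = "pcoa_coordinates")
}

# center and scale a configuration to unit sum of squares
procrustes_normalize <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  ss <- sqrt(sum(x^2))
  if (ss == 0) stop("degenerate configuration (all points coincide)")
  x / ss
}

#' Procrustes comparison of two ordinations
#'
#' Matches samples by label, truncates both configurations to the common
#' axis count (capped at `max_axes`), centers and scales each to unit sum
#' of squares, and finds the orthogonal rotation (plus uniform scaling)
#' minimizing the residual sum of squares. The misfit statistic is
#' M2 = 1 - (sum of singular values of X'Y)^2. Significance is a
#' one-sided lower-tail Monte Carlo test permuting the sample labels of
#' the second configuration:
#' p = (1 + #permuted M2 <= observed M2) / (1 + n_permutations).
#'
#' @param coords_a,coords_b `pcoa_coordinates` or plain coordinate
#'   matrices with rownames; at least 3 shared samples required.
#' @param n_permutations Monte Carlo permutations (default 10000).
#' @param seed integer seed.
#' @param max_axes cap on the number of axes compared (default 3).
#' @return list of class `procrustes_result`: `m2`, `p_value`,
#'   `n_permutations`, `n_axes`, `n_samples`.
#' @export
procrustes_compare <- function(coords_a, coords_b, n_permutations = 10000L,
                               seed = 1L, max_axes = 3L) {
  A <- if (inherits(coords_a, "pcoa_coordinates")) coords_a$points else as.matrix(coords_a)
  B <- if (inherits(coords_b, "pcoa_coordinates")) coords_b$points else as.matrix(coords_b)
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < nrow(A) || length(shared) < nrow(B))
    if (length(setdiff(rownames(A), rownames(B))) +
        length(setdiff(rownames(B), rownames(A))) > 0)
      stop("sample label mismatch between configurations")
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  k <- min(ncol(A), ncol(B), max_axes)
  X <- procrustes_normalize(A[shared, seq_len(k), drop = FALSE])
  Y <- procrustes_normalize(B[shared, seq_len(k), drop = FALSE])
  m2_of <- function(Yp) {
    1 - sum(svd(crossprod(X, Yp))$d)^2
  }
  m2 <- m2_of(Y)
  set.seed(seed)
  n <- length(shared)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    # row permutation leaves centering and scale unchanged
    Yp <- Y[sample.int(n), , drop = FALSE]
    if (m2_of(Yp) <= m2) count <- count + 1L
  }
  structure(list(m2 = m2, p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations, n_axes = k,
                 n_samples = n),
            class = "procrustes_result")
}
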