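# internal constructor: clusters are a centroid vector plus a
# cluster x sample count matrix and per-cluster member read ids
new_seq_clusters <- function(sequence, counts, members) {
  stopifnot(length(sequence) == nrow(counts),
            length(members) == nrow(counts))
  structure(list(sequence = sequence, counts = counts, members = members),
            class = "seq_clusters")
}

#' @export
print.seq_clusters <- function(x, ...) {
  cat("seq_clusters:", length(x$sequence), "clusters,",
      sum(x$counts), "reads,", ncol(x$counts), "sample(s)\n")
  invisible(x)
}

#' Cluster sizes
#' @param clusters a `seq_clusters` object.
#' @return integer vector of total reads per cluster.
#' @export
cluster_sizes <- function(clusters) as.integer(rowSums(clusters$counts))

#' Dereplicate reads at 100\% identity
#'
#' Collapses identical sequences (pooled across samples) into clusters
#' carrying per-sample counts, ordered by decreasing size with ties broken
#' by first occurrence.
#'
#' @param reads a [tag_reads()] or character vector of sequences.
#' @param sample_ids per-read sample labels (recycled scalar allowed).
#' @return a `seq_clusters` object.
#' @export
dereplicate <- function(reads, sample_ids = "S1") {
  seqs <- if (inherits(reads, "tag_reads") || is.data.frame(reads))
    reads$seq else as.character(reads)
  ids <- if (is.data.frame(reads)) reads$id else
    sprintf("r%06d", seq_along(seqs))
  sample_ids <- rep_len(as.character(sample_ids), length(seqs))
  samples <- unique(sample_ids)
  uniq <- unique(seqs) # order of first occurrence
  grp <- match(seqs, uniq)
  counts <- matrix(0L, nrow = length(uniq), ncol = length(samples),
                   dimnames = list(NULL, samples))
  tab <- table(grp, factor(sample_ids, levels = samples))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  members <- split(ids, grp)
  ord <- order(-rowSums(counts), seq_along(uniq))
  new_seq_clusters(uniq[ord], counts[ord, , drop = FALSE],
                   unname(members[as.character(ord)]))
}

#' Greedy abundance-sorted centroid clustering
#'
#' Processes clusters in decreasing-size order: each joins the first
#' existing centroid (in founding order) whose pairwise identity reaches
#' `identity_threshold`, else founds a new centroid. Identity is matching
#' columns over alignment columns of a global alignment, end gaps
#' excluded. Applied at 0.99 this is the denoising step; at 0.97 it
#' produces OTUs. Because input is abundance-sorted, each centroid is its
#' cluster's most abundant member.
#'
#' @param clusters a `seq_clusters` object (sorted by decreasing size).
#' @param identity_threshold fraction in (0, 1].
#' @param scoring an [alignment_scoring()].
#' @return a `seq_clusters` object with merged counts/members.
#' @export
greedy_cluster <- function(clusters, identity_threshold,
                           scoring = alignment_scoring()) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must lie in (0, 1]")
  sz <- cluster_sizes(clusters)
  if (is.unsorted(rev(sz))) { # enforce decreasing size
    ord <- order(-sz)
    clusters <- new_seq_clusters(clusters$sequence[ord],
                                 clusters$counts[ord, , drop = FALSE],
                                 clusters$members[ord])
  }
  assign <- .cpp_greedy_cluster(clusters$sequence, identity_threshold,
                                scoring$match, scoring$mismatch,
                                scoring$gap_open, scoring$gap_extend)
  cent <- unique(assign)
  counts <- matrix(0L, nrow = length(cent), ncol = ncol(clusters$counts),
                   dimnames = list(NULL, colnames(clusters$counts)))
  members <- vector("list", length(cent))
  for (k in seq_along(cent)) {
    idx <- which(assign == cent[k])
    counts[k, ] <- colSums(clusters$counts[idx, , drop = FALSE])
    members[[k]] <- unlist(clusters$members[idx], use.names = FALSE)
  }
  ord <- order(-rowSums(counts), seq_along(cent))
  new_seq_clusters(clusters$sequence[cent][ord], counts[ord, , drop = FALSE],
                   members[ord])
}

#' Discard low-abundance clusters
#'
#' Removes clusters with fewer than `min_size` reads (default 3), the
#' abundance filter that purges spurious singleton/doubleton error
#' clusters. The number of discarded reads is attached as attribute
#' `discarded_reads`.
#'
#' @param clusters a `seq_clusters` object.
#' @param min_size minimum cluster size to keep.
#' @return filtered `seq_clusters` with attribute `discarded_reads`.
#' @export
filter_min_size <- function(clusters, min_size = 3L) {
  sz <- cluster_sizes(clusters)
  keep <- sz >= min_size
  out <- new_seq_clusters(clusters$sequence[keep],
                          clusters$counts[keep, , drop = FALSE],
                          clusters$members[keep])
  attr(out, "discarded_reads") <- sum(sz[!keep])
  out
}

#' De novo chimera flagging
#'
#' Simplified two-parent chimera scan over abundance-sorted clusters.
#' Candidate parents for a cluster are clusters at least
#' `parent_min_ratio` (default 2) times its size that have not themselves
#' been flagged (clusters are visited in decreasing size order, so parent
#' flags are already decided; a chimera must not vouch for its smaller
#' siblings). A candidate is flagged
#' chimeric when some ordered parent pair (A, B) admits a single-crossover
#' model whose identity to the candidate exceeds the best single-parent
#' identity by at least `margin` (default 0.02) while both segments match
#' their parents at `segment_identity` (default 0.99) or better. With
#' fewer than two eligible parents the candidate is left unflagged.
#'
#' @param clusters a `seq_clusters` object sorted by decreasing size.
#' @param margin required identity gain of the two-parent model.
#' @param parent_min_ratio minimum parent/candidate size ratio.
#' @param segment_identity minimum per-segment identity to the parents.
#' @param scoring an [alignment_scoring()].
#' @return logical vector, one flag per cluster.
#' @export
chimera_flag_denovo <- function(clusters, margin = 0.02,
                                parent_min_ratio = 2,
                                segment_identity = 0.99,
                                scoring = alignment_scoring()) {
  n <- length(clusters$sequence)
  sz <- cluster_sizes(clusters)
  flags <- logical(n)
  if (n < 3L) return(flags)
  ord <- order(-sz) # visit largest first so parent flags are known
  for (i in ord) {
    parents <- which(sz >= parent_min_ratio * sz[i] & seq_len(n) != i &
                       !flags)
    if (length(parents) < 2L) next
    cand <- clusters$sequence[i]
    L <- nchar(cand)
    mv <- lapply(parents, function(p)
      .cpp_match_vector(cand, clusters$sequence[p], scoring$match,
                        scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend))
    pid <- vapply(mv, function(v) sum(v) / L, 1)
    best_single <- max(pid)
    pref <- lapply(mv, cumsum) # prefix match counts
    tot <- vapply(mv, sum, 1)
    found <- FALSE
    for (ai in seq_along(parents)) {
      if (found) break
      for (bi in seq_along(parents)) {
        if (bi == ai) next
        # crossover after position k: left from A, right from B
        k <- seq_len(L - 1L)
        left <- pref[[ai]][k]
        right <- tot[bi] - pref[[bi]][k]
        two <- (left + right) / L
        seg_ok <- (left / k >= segment_identity) &
          (right / (L - k) >= segment_identity)
        hit <- two >= best_single + margin & seg_ok
        if (any(hit)) { found <- TRUE; break }
      }
    }
    flags[i] <- found
  }
  flags
}

#' Drop flagged clusters
#'
#' @param clusters a `seq_clusters` object.
#' @param flags logical per cluster (e.g. from [chimera_flag_denovo()]).
#' @return `seq_clusters` without flagged clusters; attribute
#'   `discarded_reads` counts their reads.
#' @export
remove_flagged <- function(clusters, flags) {
  out <- new_seq_clusters(clusters$sequence[!flags],
                          clusters$counts[!flags, , drop = FALSE],
                          clusters$members[!flags])
  attr(out, "discarded_reads") <- sum(cluster_sizes(clusters)[flags])
  out
}

#' Build an OTU table
#'
#' Assembles the samples x OTUs count matrix from final clusters,
#' optionally attaching lineages and excluding rows classified as
#' Eukaryota.
#'
#' @param clusters a `seq_clusters` object (rows become OTUs).
#' @param lineage optional character vector of per-cluster lineages.
#' @param exclude_eukaryotes drop OTUs whose lineage starts with
#'   "Eukaryota".
#' @return an integer matrix (OTUs x samples) of class `otu_table` with
#'   attributes `centroids` and optionally `lineage`.
#' @export
build_otu_table <- function(clusters, lineage = NULL,
                            exclude_eukaryotes = FALSE) {
  counts <- clusters$counts
  rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  keep <- rep(TRUE, nrow(counts))
  if (exclude_eukaryotes) {
    if (is.null(lineage)) stop("lineage required to exclude eukaryotes")
    keep <- !grepl("^Eukaryota", lineage)
  }
  if (any(colSums(counts) == 0L))
    warning("sample(s) with zero reads: ",
            paste(colnames(counts)[colSums(counts) == 0L], collapse = ", "))
  out <- counts[keep, , drop = FALSE]
  attr(out, "centroids") <- clusters$sequence[keep]
  if (!is.null(lineage)) attr(out, "lineage") <- lineage[keep]
  class(out) <- c("otu_table", class(out))
  out
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample column without replacement to exactly `depth`
#' reads. Columns whose total is below `depth` are dropped with a warning
#' (standard rarefaction semantics; no resampling with replacement).
#'
#' @param table an OTU count matrix (OTUs x samples).
#' @param depth target depth (default 2893, the least abundant sample of
#'   the reference datasets).
#' @param seed integer seed.
#' @return rarefied matrix; every retained column sums to `depth`.
#' @export
rarefy <- function(table, depth = 2893L, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  totals <- colSums(table)
  if (any(totals < depth)) {
    warning("dropping sample(s) below depth: ",
            paste(colnames(table)[totals < depth], collapse = ", "))
    table <- table[, totals >= depth, drop = FALSE]
  }
  out <- apply(table, 2, function(col) {
    picked <- sample(rep.int(seq_along(col), col), depth)
    tabulate(picked, nbins = length(col))
  })
  rownames(out) <- rownames(table)
  storage.mode(out) <- "integer"
  out
}
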