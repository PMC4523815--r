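# distinct k-mer codes (0-based) of a sequence; windows containing
# non-ACGT bases are skipped
kmer_codes <- function(seq, k = 8L) {
  s <- utf8ToInt(toupper(seq))
  v <- match(s, BASE_CODES) - 1L # 0..3, NA for non-ACGT
  L <- length(v)
  if (L < k) return(integer(0))
  idx <- stats::embed(seq_len(L), k)[, k:1, drop = FALSE]
  m <- matrix(v[idx], ncol = k)
  ok <- rowSums(is.na(m)) == 0L
  if (!any(ok)) return(integer(0))
  codes <- as.integer(m[ok, , drop = FALSE] %*% 4L^((k - 1L):0L))
  unique(codes)
}

#' Train the k-mer naive-Bayes taxonomic classifier
#'
#' Reimplements the word-matching naive-Bayes scheme popularized for rRNA
#' classification: for each genus, the probability that a sequence of the
#' genus contains word w is estimated with word-prior smoothing as
#' (m(w) + Pw) / (M + 1), where m(w) is the number of the genus' training
#' sequences containing w, M the genus' training count, and
#' Pw = (n(w) + 0.5) / (N + 1) the corpus-wide word prior. Lineages must
#' have exactly 6 ranks (domain to genus) and be rank-consistent: one
#' genus cannot descend from two different parents.
#'
#' @param seqs named character vector of training sequences.
#' @param lineages character vector (same length) of semicolon-separated
#'   6-rank lineages.
#' @param k word length (default 8).
#' @return a list of class `trained_classifier` with the per-genus
#'   log-probability matrix (4^k x genera), genus lineages and training
#'   counts.
#' @export
train_classifier <- function(seqs, lineages, k = 8L) {
  stopifnot(length(seqs) == length(lineages))
  ranks <- strsplit(lineages, ";")
  if (any(lengths(ranks) != 6L))
    stop("every lineage must have exactly 6 ranks")
  genus <- vapply(ranks, `[`, "", 6L)
  for (g in unique(genus)) {
    par <- unique(lineages[genus == g])
    if (length(par) > 1L)
      stop("rank-inconsistent lineage for genus ", g)
  }
  genera <- unique(genus)
  nw <- 4L^k
  n_total <- length(seqs)
  word_seq_count <- integer(nw) # n(w): sequences containing w
  per_genus_count <- matrix(0L, nrow = nw, ncol = length(genera),
                            dimnames = list(NULL, genera))
  words <- lapply(seqs, kmer_codes, k = k)
  for (i in seq_along(seqs)) {
    w <- words[[i]] + 1L
    word_seq_count[w] <- word_seq_count[w] + 1L
    gi <- match(genus[i], genera)
    per_genus_count[w, gi] <- per_genus_count[w, gi] + 1L
  }
  prior <- (word_seq_count + 0.5) / (n_total + 1)
  M <- as.integer(table(factor(genus, levels = genera)))
  logp <- log(sweep(per_genus_count, 1, prior, `+`)) -
    rep(log(M + 1), each = nw)
  structure(list(k = k, logp = logp, genera = genera,
                 genus_lineage = stats::setNames(
                   lineages[match(genera, genus)], genera),
                 training_count = stats::setNames(M, genera)),
            class = "trained_classifier")
}

#' Bootstrap classification of one sequence
#'
#' Scores the query's distinct words against every genus and assigns the
#' maximum-likelihood genus; confidence is estimated by bootstrap: in each
#' of `n_bootstrap` trials, ceiling(W/8) of the query's W distinct words
#' are drawn with replacement and scored, and the per-rank confidence is
#' the fraction of trials whose winning genus shares the assigned genus'
#' lineage down to that rank.
#'
#' @param seq nucleotide string (length >= k).
#' @param classifier a [train_classifier()] result.
#' @param n_bootstrap number of bootstrap trials (default 100).
#' @param seed integer seed.
#' @return a list of class `classification`: `taxon` and `confidence`
#'   per rank (length 6), plus `genus` (the assigned genus).
#' @export
classify_bootstrap <- function(seq, classifier, n_bootstrap = 100L,
                               seed = 1L) {
  w <- kmer_codes(seq, classifier$k)
  if (length(w) == 0L)
    stop("sequence shorter than k (or no valid words)")
  set.seed(seed)
  logp <- classifier$logp
  full <- colSums(logp[w + 1L, , drop = FALSE])
  best <- which.max(full)
  best_lineage <- strsplit(classifier$genus_lineage[[best]], ";")[[1]]
  nsub <- ceiling(length(w) / 8)
  lineage_mat <- do.call(rbind,
    strsplit(unname(classifier$genus_lineage), ";"))
  agree <- matrix(0L, nrow = n_bootstrap, ncol = 6L)
  for (b in seq_len(n_bootstrap)) {
    ws <- w[sample.int(length(w), nsub, replace = TRUE)]
    sc <- colSums(logp[ws + 1L, , drop = FALSE])
    win <- which.max(sc)
    agree[b, ] <- cumprod(lineage_mat[win, ] == best_lineage)
  }
  structure(list(taxon = best_lineage, confidence = colMeans(agree),
                 genus = classifier$genera[best]),
            class = "classification")
}

#' Deepest lineage meeting a confidence threshold
#'
#' Returns the assigned lineage truncated to the deepest rank whose
#' bootstrap confidence reaches `threshold` (default 0.50); the empty
#' ("root") lineage if no rank qualifies.
#'
#' @param classification a [classify_bootstrap()] result.
#' @param threshold confidence threshold in \[0, 1\].
#' @return character vector of taxa from domain down to the deepest
#'   qualifying rank (length 0 for root).
#' @export
assign_deepest <- function(classification, threshold = 0.50) {
  ok <- classification$confidence >= threshold
  deepest <- if (any(ok)) max(which(ok)) else 0L
  classification$taxon[seq_len(deepest)]
}

#' Classify many sequences
#'
#' @param seqs character vector of sequences.
#' @param classifier a [train_classifier()] result.
#' @param threshold confidence threshold for [assign_deepest()].
#' @param n_bootstrap,seed passed to [classify_bootstrap()].
#' @return data.frame with per-rank taxa and confidences plus the
#'   thresholded `assigned` lineage (semicolon-joined).
#' @export
classify_sequences <- function(seqs, classifier, threshold = 0.50,
                               n_bootstrap = 100L, seed = 1L) {
  rank_names <- c("domain", "phylum", "class", "order", "family", "genus")
  rows <- lapply(seq_along(seqs), function(i) {
    cl <- classify_bootstrap(seqs[i], classifier, n_bootstrap,
                             seed = seed + i - 1L)
    out <- c(stats::setNames(as.list(cl$taxon), rank_names),
             stats::setNames(as.list(cl$confidence),
                             paste0(rank_names, "_conf")),
             assigned = paste(assign_deepest(cl, threshold), collapse = ";"))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
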