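#' Quality-control profiles
#'
#' Two named filter profiles are defined. The lenient profile rejects a
#' read with more than 5 Ns, average quality below 30, or more than 10
#' bases below Q15. The stringent profile rejects a read with 1 N or more,
#' average quality below 33, or more than 3 bases below Q20. Any base
#' outside A/C/G/T (case-insensitive) counts as an N; "average quality" is
#' the arithmetic mean of the integer Phred scores; "more than"/"lower
#' than" are strict.
#'
#' @param name `"lenient"` or `"stringent"`, or pass the thresholds
#'   explicitly.
#' @param max_n maximum tolerated N count (reject at `> max_n`).
#' @param min_avg_q minimum mean Phred (reject when mean `< min_avg_q`).
#' @param low_q_threshold Phred defining a "low quality" base (strictly
#'   below).
#' @param max_low_q_bases maximum tolerated low-quality bases (reject at
#'   `> max_low_q_bases`).
#' @return a list of class `qc_profile`.
#' @export
qc_profile <- function(name = c("lenient", "stringent"), max_n = NULL,
                       min_avg_q = NULL, low_q_threshold = NULL,
                       max_low_q_bases = NULL) {
  if (is.null(max_n)) {
    name <- match.arg(name)
    p <- switch(name,
      lenient = list(name = "lenient", max_n = 5L, min_avg_q = 30,
                     low_q_threshold = 15L, max_low_q_bases = 10L),
      stringent = list(name = "stringent", max_n = 0L, min_avg_q = 33,
                       low_q_threshold = 20L, max_low_q_bases = 3L))
  } else {
    p <- list(name = if (is.character(name)) name[1] else "custom",
              max_n = as.integer(max_n), min_avg_q = as.numeric(min_avg_q),
              low_q_threshold = as.integer(low_q_threshold),
              max_low_q_bases = as.integer(max_low_q_bases))
  }
  class(p) <- "qc_profile"
  p
}

#' Quality-filter reads
#'
#' Applies a [qc_profile()] to each read. A read fails if its N count
#' exceeds `max_n`, its mean quality is below `min_avg_q`, or it has more
#' than `max_low_q_bases` bases with quality strictly below
#' `low_q_threshold`. Empty reads fail with reason `"empty"`. All
#' triggered reasons are reported.
#'
#' @param reads a [tag_reads()].
#' @param profile a [qc_profile()] or profile name.
#' @return a data.frame with columns `id`, `pass` and `reasons`
#'   (comma-separated; `""` when passing).
#' @export
qc_filter <- function(reads, profile = "stringent") {
  if (is.character(profile)) profile <- qc_profile(profile)
  n <- nrow(reads)
  len <- nchar(reads$seq)
  # any base outside A/C/G/T counts as an N
  n_count <- len - nchar(gsub("[^ACGTacgt]", "", reads$seq, perl = TRUE))
  q <- qual_ints(reads)
  mean_q <- vapply(q, function(x) if (length(x)) mean(x) else NaN, 1)
  low_q <- vapply(q, function(x) sum(x < profile$low_q_threshold), 1L)
  reasons <- character(n)
  fail_empty <- len == 0L
  fail_n <- !fail_empty & n_count > profile$max_n
  fail_avg <- !fail_empty & mean_q < profile$min_avg_q
  fail_low <- !fail_empty & low_q > profile$max_low_q_bases
  add <- function(cur, flag, tag) ifelse(flag, ifelse(cur == "", tag,
                                                      paste(cur, tag, sep = ",")), cur)
  reasons <- add(reasons, fail_empty, "empty")
  reasons <- add(reasons, fail_n, "too_many_n")
  reasons <- add(reasons, fail_avg, "low_mean_quality")
  reasons <- add(reasons, fail_low, "too_many_low_q_bases")
  data.frame(id = reads$id, pass = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Sliding-window 3' quality trimming
#'
#' Starting from the 5' end, a window of `window` bases moves toward the
#' 3' end; the read is cut immediately before the first window start whose
#' mean quality is below `min_mean_q`. Reads shorter than the window are
#' returned unchanged. The operation is idempotent and never lengthens a
#' read.
#'
#' @param reads a [tag_reads()].
#' @param window window width in bases (default 20).
#' @param min_mean_q minimum mean Phred within a window (default 30).
#' @return a [tag_reads()] with trimmed sequences/qualities (possibly of
#'   length zero).
#' @export
window_trim <- function(reads, window = 20L, min_mean_q = 30) {
  if (window < 1L) stop("window must be >= 1")
  q <- qual_ints(reads)
  cut_at <- vapply(q, function(x) {
    L <- length(x)
    if (L < window) return(L)
    cs <- cumsum(c(0, x))
    means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
    bad <- which(means < min_mean_q)
    if (length(bad) == 0L) L else bad[1L] - 1L
  }, 1L)
  tag_reads(reads$id, substr(reads$seq, 1L, cut_at),
            substr(reads$qual, 1L, cut_at))
}

# all k-mers of a character vector of sequences (forward strand)
seq_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  unlist(out, use.names = FALSE)
}

#' k-mer contaminant screening
#'
#' Flags a read when at least `min_hits` of its k-mers (on either strand)
#' occur in the contaminant k-mer set, emulating k-mer matching tools used
#' for PhiX/adapter removal. Reads shorter than `k` are trivially kept.
#'
#' @param reads a [tag_reads()].
#' @param contaminant_seqs character vector of contaminant sequences
#'   (non-empty).
#' @param k k-mer length (>= 11; default 21).
#' @param min_hits minimum shared k-mers to flag (default 1).
#' @return list with `kept` and `flagged` [tag_reads()] partitions (their
#'   union is the input) and `hits`, the per-read shared k-mer count.
#' @export
kmer_screen <- function(reads, contaminant_seqs, k = 21L, min_hits = 1L) {
  if (length(contaminant_seqs) == 0L) stop("contaminant set is empty")
  if (k < 11L) stop("k must be >= 11")
  ref <- unique(seq_kmers(c(contaminant_seqs, revcomp(contaminant_seqs)), k))
  hits <- vapply(reads$seq, function(s) {
    km <- seq_kmers(s, k)
    if (length(km) == 0L) return(0L)
    sum(km %in% ref)
  }, 1L, USE.NAMES = FALSE)
  flagged <- hits >= min_hits
  list(kept = reads[!flagged, , drop = FALSE],
       flagged = reads[flagged, , drop = FALSE], hits = hits)
}

# IUPAC-aware per-character primer/base match matrix lookup
iupac_match <- function(primer_chars, read_chars) {
  mapply(function(p, b) b %in% iupac_expand(p), primer_chars, read_chars,
         USE.NAMES = FALSE)
}

#' Trim stagger prefix and primer from reads
#'
#' Scans stagger offsets 0..`stagger_max` for a primer match (IUPAC
#' semantics: the read base must be one of the primer code's expansions)
#' with at most `max_mismatches` mismatches. The smallest matching offset
#' wins; on success, everything through the primer end is removed. Reads
#' without a match are returned as failures and should be excluded
#' downstream.
#'
#' @param reads a [tag_reads()].
#' @param primer IUPAC primer sequence as it appears at the read 5' end.
#' @param stagger_max maximum stagger offset (0-3).
#' @param max_mismatches tolerated mismatches within the primer.
#' @return list with `trimmed` ([tag_reads()] of successfully trimmed
#'   reads), `failed` (untouched failures) and `offset` (matched offset
#'   per input read; `NA` on failure).
#' @export
trim_primer_stagger <- function(reads, primer, stagger_max = 3L,
                                max_mismatches = 0L) {
  if (nchar(primer) == 0L) stop("primer must be non-empty")
  if (stagger_max < 0L || stagger_max > 3L)
    stop("stagger_max must lie in [0, 3]")
  pc <- strsplit(toupper(primer), "")[[1]]
  plen <- length(pc)
  offset <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- toupper(reads$seq[i])
    for (off in 0:stagger_max) {
      if (nchar(s) < off + plen) break
      rc <- strsplit(substr(s, off + 1L, off + plen), "")[[1]]
      mm <- sum(!iupac_match(pc, rc))
      if (mm <= max_mismatches) { offset[i] <- off; break }
    }
  }
  ok <- !is.na(offset)
  cut <- offset + plen
  trimmed <- tag_reads(reads$id[ok],
                       substr(reads$seq[ok], cut[ok] + 1L, nchar(reads$seq[ok])),
                       substr(reads$qual[ok], cut[ok] + 1L, nchar(reads$qual[ok])))
  list(trimmed = trimmed, failed = reads[!ok, , drop = FALSE],
       offset = offset)
}

#' Merge overlapping read pairs
#'
#' Reverse-complements read 2, then scans candidate overlap lengths from
#' `min_overlap` up to the shorter read length, choosing the overlap with
#' the smallest mismatch density (ties broken toward the longest overlap).
#' The pair merges when that density is at most `max_mismatch_density`;
#' within the overlap, disagreeing positions take the higher-quality base
#' (ties keep read 1) and the merged quality is the maximum of the two.
#'
#' @param r1,r2 [tag_reads()] of equal row count (mates in order).
#' @param min_overlap minimum admissible overlap (default 10).
#' @param max_mismatch_density maximum mismatches/overlap (default 0.25).
#' @return list with `merged` ([tag_reads()]) and `failed` (logical per
#'   pair).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L,
                        max_mismatch_density = 0.25) {
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  merged_id <- character(0); merged_seq <- character(0); merged_q <- character(0)
  failed <- logical(n)
  q1l <- qual_ints(r1)
  r2rc <- revcomp(r2$seq)
  q2l <- lapply(qual_ints(r2), rev)
  for (i in seq_len(n)) {
    a <- utf8ToInt(r1$seq[i]); b <- utf8ToInt(r2rc[i])
    qa <- q1l[[i]]; qb <- q2l[[i]]
    la <- length(a); lb <- length(b)
    maxov <- min(la, lb)
    if (maxov < min_overlap) { failed[i] <- TRUE; next }
    best_ov <- NA_integer_; best_d <- Inf
    for (ov in min_overlap:maxov) {
      mm <- sum(a[(la - ov + 1L):la] != b[1:ov])
      d <- mm / ov
      if (d < best_d || (d == best_d && !is.na(best_ov) && ov > best_ov)) {
        best_d <- d; best_ov <- ov
      }
    }
    if (best_d > max_mismatch_density) { failed[i] <- TRUE; next }
    ov <- best_ov
    ia <- (la - ov + 1L):la; ib <- 1:ov
    take_b <- a[ia] != b[ib] & qb[ib] > qa[ia]
    cons <- a[ia]; cons[take_b] <- b[ib][take_b]
    consq <- pmax(qa[ia], qb[ib])
    out_seq <- c(a[seq_len(la - ov)], cons, b[ov + seq_len(lb - ov)])
    out_q <- c(qa[seq_len(la - ov)], consq, qb[ov + seq_len(lb - ov)])
    merged_id <- c(merged_id, sub("/1$", "", r1$id[i]))
    merged_seq <- c(merged_seq, intToUtf8(out_seq))
    merged_q <- c(merged_q, phred_encode(list(out_q)))
  }
  list(merged = tag_reads(merged_id, merged_seq, merged_q), failed = failed)
}

#' Hard-truncate reads to a fixed length
#'
#' Platform-specific pre-trim applied before assembly (e.g. 220 bases for
#' pyrosequencing reads, 150 for short paired-end reads). Reads shorter
#' than `length` are unchanged.
#'
#' @param reads a [tag_reads()].
#' @param length truncation length.
#' @return a [tag_reads()].
#' @export
truncate_reads <- function(reads, length) {
  tag_reads(reads$id, substr(reads$seq, 1L, length),
            substr(reads$qual, 1L, length))
}

#' Per-sample read-accounting report
#'
#' Summarizes read recovery per sample: total raw reads, pre-QC
#' (assembled or screened) reads, QC-passed reads, and the percentage
#' passing QC (QC-passed / pre-QC x 100, 2 decimals; `NA` when no pre-QC
#' reads exist rather than 0).
#'
#' @param sample,total_reads,pre_qc,qc_passed equal-length vectors of
#'   per-sample counters.
#' @return a data.frame with a `pct_passing` column.
#' @export
qc_report <- function(sample, total_reads, pre_qc, qc_passed) {
  pct <- ifelse(pre_qc > 0, round_half_up(qc_passed / pre_qc * 100), NA_real_)
  data.frame(sample = sample, total_reads = total_reads, pre_qc = pre_qc,
             qc_passed = qc_passed, pct_passing = pct,
             stringsAsFactors = FALSE)
}
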