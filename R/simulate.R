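# --- error injection ---------------------------------------------------

BASE_CODES <- c(65L, 67L, 71L, 84L) # A C G T

# draw per-base qualities for one template: positional decay plus a
# per-read offset (cluster-to-cluster variation), clipped to [2, 41]
draw_qualities <- function(len, model) {
  off <- stats::rnorm(1L, 0, model$read_quality_sd)
  q <- as.integer(round(stats::rnorm(len, model$quality_decay(seq_len(len)) + off,
                                     model$quality_sd)))
  pmin(pmax(q, 2L), 41L)
}

# inject sequencing errors into one template given its qualities; returns
# the mutated read and the truth record (counts + template positions).
# Errors are drawn independently per base in template order; insertions
# land after their template base and inherit its quality. Per-base error
# probabilities are the model rates scaled by the base's quality-implied
# error weight 10^(-q/10) over the normalizer `z` (the sample-mean
# weight), so low-quality reads carry proportionally more errors while
# the sample-wide expectation stays at the nominal rate.
inject_errors <- function(seq, model, q = NULL, z = NULL) {
  s <- utf8ToInt(seq)
  L <- length(s)
  if (L == 0L)
    return(list(seq = "", qual = integer(0), n_sub = 0L, n_ins = 0L,
                n_del = 0L, sub_pos = integer(0), ins_pos = integer(0),
                del_pos = integer(0)))
  if (is.null(q)) q <- draw_qualities(L, model)
  w <- 10^(-q / 10)
  if (is.null(z)) z <- mean(w)
  w <- w / z
  # homopolymer boost for indels inside runs >= 3
  r <- rle(s)
  hp <- rep(ifelse(r$lengths >= 3L, model$homopolymer_multiplier, 1),
            r$lengths)
  p_sub <- pmin(model$substitution_rate * w, 0.5)
  p_ins <- pmin(model$insertion_rate * w * hp, 0.5)
  p_del <- pmin(model$deletion_rate * w * hp, 0.5)
  del <- stats::runif(L) < p_del
  sub <- stats::runif(L) < p_sub & !del
  ins <- stats::runif(L) < p_ins
  s2 <- s
  if (any(sub)) {
    idx <- match(s[sub], BASE_CODES)
    others <- rbind(c(67L, 71L, 84L), c(65L, 71L, 84L),
                    c(65L, 67L, 84L), c(65L, 67L, 71L))
    ok <- !is.na(idx) # leave non-ACGT untouched
    pick <- sample.int(3L, sum(ok), replace = TRUE)
    s2[which(sub)[ok]] <- others[cbind(idx[ok], pick)]
    sub[which(sub)[!ok]] <- FALSE
  }
  keep <- !del
  tpos <- which(keep)
  ipos <- which(ins)
  ib <- sample(BASE_CODES, length(ipos), replace = TRUE)
  ord <- order(c(tpos, ipos + 0.5))
  outb <- c(s2[keep], ib)[ord]
  outq <- c(q[keep], q[ipos])[ord]
  list(seq = intToUtf8(outb), qual = outq,
       n_sub = sum(sub), n_ins = length(ipos), n_del = sum(del),
       sub_pos = which(sub), ins_pos = ipos, del_pos = which(del))
}

# --- sample simulation -------------------------------------------------

#' Simulate an amplicon sequencing sample with ground truth
#'
#' Draws reads from a mock community: organisms are sampled in proportion
#' to their rRNA-copy-normalized expected distribution (MEND) -- amplicon
#' reads sample rRNA genes, not genomes -- and gene copies uniformly within
#' an organism. Each read is a 0..`stagger_max` random-base stagger prefix,
#' followed by the primer-inclusive amplicon of the chosen template,
#' truncated to the model read length and passed through the platform
#' error model. A `chimera_fraction` of reads are instead two-parent
#' crossovers: parents are drawn abundance-weighted from distinct
#' organisms and spliced at a uniform breakpoint in the central 25-75\% of
#' the amplicon.
#'
#' @param design a [community_design()]; organism labels must name entries
#'   of `refs`.
#' @param refs a [generate_reference_set()] result.
#' @param region amplified region label present in `refs`.
#' @param model a [platform_error_model()].
#' @param n_reads number of reads to simulate (0 allowed).
#' @param stagger_max maximum stagger length (0-3).
#' @param chimera_fraction probability a read is a chimera, in \[0, 1\].
#' @param seed integer seed.
#' @param sample_id label stored in read ids.
#'
#' @return a list of class `tag_sample`: `reads` (a [tag_reads()]; for
#'   paired models `r1`/`r2` instead), `truth` (per-read data.frame with
#'   source organism/copy, stagger length, injected error counts and
#'   template positions, chimera flag, parents and breakpoint) and
#'   `composition` (realized organism read fractions).
#' @export
simulate_sample <- function(design, refs, region, model, n_reads,
                            stagger_max = 3L, chimera_fraction = 0,
                            seed = 1L, sample_id = "S1") {
  if (chimera_fraction < 0 || chimera_fraction > 1)
    stop("chimera_fraction must lie in [0, 1]")
  if (!region %in% names(refs$layout$regions))
    stop("region not present in reference set: ", region)
  set.seed(seed)
  comp <- expected_composition(design)
  orgs <- design$organism
  if (!all(orgs %in% names(refs$genes)))
    stop("design organisms missing from reference set: ",
         paste(setdiff(orgs, names(refs$genes)), collapse = ", "))
  amps <- lapply(orgs, function(o) {
    g <- refs$genes[[o]]
    rc <- g$region_coords[[region]]
    vapply(g$copies, function(s) substr(s, rc[1] + 1L, rc[2]), "")
  })
  names(amps) <- orgs
  mend <- comp$mend

  empty_truth <- data.frame(
    read_id = character(0), organism = character(0), copy = integer(0),
    stagger = integer(0), n_sub = integer(0), n_ins = integer(0),
    n_del = integer(0), sub_pos = character(0), ins_pos = character(0),
    del_pos = character(0), chimera = logical(0), parent1 = character(0),
    parent2 = character(0), breakpoint = integer(0),
    stringsAsFactors = FALSE)

  if (n_reads == 0L) {
    out <- list(reads = tag_reads(character(0), character(0), character(0)),
                truth = empty_truth, composition = stats::setNames(
                  rep(0, length(orgs)), orgs), region = region,
                sample_id = sample_id)
    class(out) <- "tag_sample"
    return(out)
  }

  org_idx <- sample.int(length(orgs), n_reads, replace = TRUE, prob = mend)
  n_copies <- vapply(amps, length, 1L)
  copy_idx <- vapply(org_idx, function(o)
    sample.int(n_copies[o], 1L), 1L)
  is_chim <- stats::runif(n_reads) < chimera_fraction
  stag_len <- sample.int(stagger_max + 1L, n_reads, replace = TRUE) - 1L

  ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  seqs <- character(n_reads); quals <- vector("list", n_reads)
  rec <- vector("list", n_reads)
  bases <- c("A", "C", "G", "T")
  p1 <- character(n_reads); p2 <- character(n_reads); bp <- rep(NA_integer_, n_reads)
  templates <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (is_chim[i]) {
      oa <- sample.int(length(orgs), 1L, prob = mend)
      ob <- sample.int(length(orgs) - 1L, 1L,
                       prob = mend[-oa] / sum(mend[-oa]))
      ob <- seq_along(orgs)[-oa][ob]
      ca <- sample.int(n_copies[oa], 1L); cb <- sample.int(n_copies[ob], 1L)
      A <- amps[[oa]][ca]; B <- amps[[ob]][cb]
      L <- min(nchar(A), nchar(B))
      k <- as.integer(round(stats::runif(1, 0.25, 0.75) * L))
      templates[i] <- paste0(substr(A, 1L, k), substr(B, k + 1L, nchar(B)))
      p1[i] <- names(amps[[oa]])[ca]; p2[i] <- names(amps[[ob]])[cb]
      bp[i] <- k
      org_idx[i] <- NA_integer_; copy_idx[i] <- NA_integer_
    } else {
      templates[i] <- amps[[org_idx[i]]][copy_idx[i]]
    }
    if (stag_len[i] > 0L)
      templates[i] <- paste0(paste(sample(bases, stag_len[i], replace = TRUE),
                                   collapse = ""), templates[i])
  }
  # single-end reads sequence the first read_length cycles of the
  # molecule; paired reads are cut later from both ends of the full
  # error-bearing molecule
  tmpl <- if (model$paired) templates else
    substr(templates, 1L, model$read_length)
  qlist <- lapply(nchar(tmpl), draw_qualities, model = model)
  z <- mean(10^(-unlist(qlist) / 10)) # sample-wide weight normalizer
  for (i in seq_len(n_reads)) {
    e <- inject_errors(tmpl[i], model, q = qlist[[i]], z = z)
    seqs[i] <- e$seq; quals[[i]] <- e$qual
    rec[[i]] <- e
  }

  fmt_pos <- function(p, off) paste(p - off, collapse = ",")
  truth <- data.frame(
    read_id = ids,
    organism = ifelse(is.na(org_idx), NA_character_, orgs[org_idx]),
    copy = copy_idx, stagger = stag_len,
    n_sub = vapply(rec, function(e) e$n_sub, 1L),
    n_ins = vapply(rec, function(e) e$n_ins, 1L),
    n_del = vapply(rec, function(e) e$n_del, 1L),
    sub_pos = mapply(function(e, o) fmt_pos(e$sub_pos, o), rec, stag_len),
    ins_pos = mapply(function(e, o) fmt_pos(e$ins_pos, o), rec, stag_len),
    del_pos = mapply(function(e, o) fmt_pos(e$del_pos, o), rec, stag_len),
    chimera = is_chim, parent1 = ifelse(is_chim, p1, NA_character_),
    parent2 = ifelse(is_chim, p2, NA_character_), breakpoint = bp,
    stringsAsFactors = FALSE)

  reads <- tag_reads(ids, seqs, phred_encode(quals))
  realized <- table(factor(truth$organism, levels = orgs))
  out <- list(reads = reads, truth = truth,
              composition = as.numeric(realized) / max(sum(realized), 1L),
              region = region, sample_id = sample_id)
  names(out$composition) <- orgs
  if (model$paired) {
    # paired mode: R1 = 5' read, R2 = reverse-complement 3' read of the
    # same error-bearing molecule, each truncated to the read length
    rl <- model$read_length
    r1 <- substr(seqs, 1L, rl)
    q1 <- lapply(quals, function(q) q[seq_len(min(length(q), rl))])
    rc2 <- revcomp(seqs)
    r2 <- substr(rc2, 1L, rl)
    q2 <- lapply(quals, function(q) rev(q)[seq_len(min(length(q), rl))])
    out$r1 <- tag_reads(paste0(ids, "/1"), r1, phred_encode(q1))
    out$r2 <- tag_reads(paste0(ids, "/2"), r2, phred_encode(q2))
  }
  class(out) <- "tag_sample"
  out
}

#' Write simulated samples and their ground truth to disk
#'
#' Serializes a set of simulated samples: one gzip FASTQ per sample (or an
#' R1/R2 pair for paired models), the per-read truth TSV, the community
#' design TSV, the reference genes FASTA, the lineage map TSV and the true
#' tree in Newick format, plus a manifest of MD5 checksums.
#'
#' @param samples a list of [simulate_sample()] results.
#' @param dir output directory (created if needed).
#' @param design the [community_design()] used.
#' @param refs the [generate_reference_set()] used.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_fixture <- function(samples, dir, design = NULL, refs = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  files <- character(0)
  for (s in samples) {
    if (!is.null(s$r1)) {
      f1 <- file.path(dir, paste0(s$sample_id, "_R1.fastq.gz"))
      f2 <- file.path(dir, paste0(s$sample_id, "_R2.fastq.gz"))
      write_fastq(s$r1, f1); write_fastq(s$r2, f2)
      files <- c(files, f1, f2)
    } else {
      f <- file.path(dir, paste0(s$sample_id, ".fastq.gz"))
      write_fastq(s$reads, f)
      files <- c(files, f)
    }
    ft <- file.path(dir, paste0(s$sample_id, "_truth.tsv"))
    utils::write.table(s$truth, ft, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, ft)
  }
  if (!is.null(design)) {
    fd <- file.path(dir, "design.tsv")
    write_design_tsv(design, fd)
    files <- c(files, fd)
  }
  if (!is.null(refs)) {
    fr <- file.path(dir, "references.fasta")
    write_fasta(reference_sequences(refs), fr)
    fl <- file.path(dir, "lineages.tsv")
    utils::write.table(refs$lineages, fl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fn <- file.path(dir, "tree.nwk")
    ape::write.tree(refs$tree, fn)
    files <- c(files, fr, fl, fn)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
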