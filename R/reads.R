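#' Sequencing read sets
#'
#' Reads are held in a plain `data.frame` of class `tag_reads` with columns
#' `id` (unique label), `seq` (bases over A/C/G/T/N) and `qual`
#' (Phred+33-encoded per-base qualities, same length as `seq`). This mirrors
#' one FASTQ record per row and keeps serialization trivial.
#'
#' @param id,seq,qual character vectors of equal length.
#' @return a `tag_reads` data.frame.
#' @export
tag_reads <- function(id, seq, qual) {
  id <- as.character(id); seq <- as.character(seq); qual <- as.character(qual)
  if (length(seq) != length(id) || length(qual) != length(id))
    stop("id, seq and qual must have equal length")
  bad <- nchar(seq) != nchar(qual)
  if (any(bad))
    stop("length(bases) != length(quals) for reads: ",
         paste(utils::head(id[bad]), collapse = ", "))
  out <- data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
  class(out) <- c("tag_reads", "data.frame")
  out
}

#' Per-read integer Phred scores
#'
#' @param reads a [tag_reads()] object.
#' @return a list of integer vectors (one per read), Phred+33 decoded.
#' @export
qual_ints <- function(reads) {
  lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
}

# encode a list of integer phred vectors to +33 strings
phred_encode <- function(qlist) {
  vapply(qlist, function(q) intToUtf8(pmin(pmax(q, 0L), 60L) + 33L), "")
}

#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings FASTQ support; gzip is handled
#' transparently by file extension.
#'
#' @param path FASTQ file path (".gz" accepted).
#' @return [read_fastq()] returns a [tag_reads()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tag_reads(names(x), as.character(x),
            as.character(S4Vectors::mcols(x)$qualities))
}

#' @param reads a [tag_reads()].
#' @param compress gzip the output (default from ".gz" suffix).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path, compress = grepl("\\.gz$", path)) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = compress)
  invisible(path)
}

#' @return [read_fasta()] returns a named character vector of sequences.
#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fastq
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# reverse complement for plain character vectors (IUPAC aware)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
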