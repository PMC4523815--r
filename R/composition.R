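#' Construct a mock-community design table
#'
#' A community design lists, for each organism pooled into a defined (mock)
#' community, the DNA quantity added, the genome size and the rRNA gene
#' copy number. These three columns are the inputs of the expected
#' composition calculation (see [expected_composition()]).
#'
#' @param organism character vector of unique organism labels.
#' @param quantity_ug DNA quantity added per organism, in micrograms
#'   (positive).
#' @param genome_size_bp genome size per organism, in base pairs (positive).
#' @param rrna_copies rRNA gene (operon) copy number per organism
#'   (integer >= 1).
#' @param lineage optional character vector of semicolon-separated
#'   6-rank lineages (domain to genus).
#'
#' @return A `data.frame` of class `community_design` with columns
#'   `organism`, `quantity_ug`, `genome_size_bp`, `rrna_copies` and
#'   optionally `lineage`.
#' @export
#' @examples
#' community_design(c("a", "b"), c(1, 1), c(4e6, 4e6), c(2, 1))
community_design <- function(organism, quantity_ug, genome_size_bp,
                             rrna_copies, lineage = NULL) {
  organism <- as.character(organism)
  if (anyDuplicated(organism))
    stop("organism labels must be unique")
  if (length(organism) == 0L)
    stop("empty community design")
  quantity_ug <- as.numeric(quantity_ug)
  genome_size_bp <- as.numeric(genome_size_bp)
  rrna_copies <- as.numeric(rrna_copies)
  if (any(!is.finite(quantity_ug)) || any(quantity_ug <= 0))
    stop("quantity_ug must be positive")
  if (any(!is.finite(genome_size_bp)) || any(genome_size_bp <= 0))
    stop("genome_size_bp must be positive")
  if (any(!is.finite(rrna_copies)) || any(rrna_copies < 1) ||
      any(rrna_copies != round(rrna_copies)))
    stop("rrna_copies must be integers >= 1")
  d <- data.frame(organism = organism, quantity_ug = quantity_ug,
                  genome_size_bp = genome_size_bp,
                  rrna_copies = as.integer(rrna_copies),
                  stringsAsFactors = FALSE)
  if (!is.null(lineage)) {
    stopifnot(length(lineage) == nrow(d))
    d$lineage <- as.character(lineage)
  }
  class(d) <- c("community_design", "data.frame")
  d
}

#' Read / write a community design TSV
#'
#' The TSV schema has columns `organism`, `quantity_ug`, `genome_size_bp`,
#' `rrna_copies` and optionally `lineage`.
#'
#' @param path file path.
#' @return [read_design_tsv()] returns a `community_design`.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  community_design(d$organism, d$quantity_ug, d$genome_size_bp,
                   d$rrna_copies, lineage = d$lineage)
}

#' @param design a `community_design`.
#' @rdname read_design_tsv
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The nine-organism reference mock community
#'
#' The defined DNA pool used throughout the package examples and tests:
#' nine organisms spanning Bacteria and Archaea mixed at quantities from
#' 3.5 ug down to 0.02 ug (10 ug total), with genome sizes and rRNA gene
#' copy numbers per organism. Copy numbers range from 1 to 8, so the
#' genome-size-normalized (MED) and copy-number-normalized (MEND) expected
#' distributions differ sharply: the most abundant organism by rRNA copies
#' contributes ~71% of expected amplicon reads but only ~30% of genomes.
#'
#' @return A `community_design` of 9 rows with 6-rank lineages.
#' @seealso [expected_composition()]
#' @export
mock_community_design <- function() {
  community_design(
    organism = c(
      "Clostridium phytofermentans ISDg",
      "Natrinema pellirubrum str. J7-2",
      "Pantoea sp. AB-valens",
      "Rhodanobacter sp. 2APBS1",
      "Natronobacterium gregoryi SP2",
      "Pseudoxanthomonas suwonensis 11-1",
      "Mycobacterium smegmatis JS623",
      "Halobacterium sp. str DL1",
      "Paenibacillus lactis 154"),
    quantity_ug = c(3.50, 3.00, 1.50, 1.00, 0.68, 0.20, 0.06, 0.04, 0.02),
    genome_size_bp = c(4847594, 3697626, 4368708, 4225490, 3788356,
                       3419049, 6464916, 2846968, 6805951),
    rrna_copies = c(8, 1, 1, 2, 3, 2, 2, 1, 1),
    lineage = c(
      "Bacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Clostridium",
      "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Natrialbaceae;Natrinema",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacteriales;Enterobacteriaceae;Pantoea",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Xanthomonadaceae;Rhodanobacter",
      "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Halobacteriaceae;Natronobacterium",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Xanthomonadaceae;Pseudoxanthomonas",
      "Bacteria;Actinobacteria;Actinobacteria;Actinomycetales;Mycobacteriaceae;Mycobacterium",
      "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Halobacteriaceae;Halobacterium",
      "Bacteria;Firmicutes;Bacilli;Bacillales;Paenibacillaceae;Paenibacillus"))
}

# round half away from zero to `digits` decimals (display convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Expected composition of a mock community (MED / MEND)
#'
#' Computes the expected organism distribution of a defined DNA pool. The
#' genome-size-normalized distribution (MED) divides the DNA quantity of
#' each organism by its genome size, giving a value proportional to the
#' number of genome copies added, and normalizes over the community:
#' \deqn{MED(i) = \frac{Q(i)/GS(i)}{\sum_j Q(j)/GS(j)}}
#' The copy-number-normalized distribution (MEND) additionally multiplies
#' by the rRNA gene copy number, the relevant expectation for amplicon
#' read counts since reads sample rRNA genes, not genomes:
#' \deqn{MEND(i) = \frac{Q(i) \cdot RR(i)/GS(i)}{\sum_j Q(j) \cdot RR(j)/GS(j)}}
#'
#' @param design a [community_design()].
#' @return A `data.frame` with one row per organism and columns
#'   `organism`, `fraction_of_mix` (Q / sum Q), `med`, `mend` (full
#'   precision fractions summing to 1), and their display percentages
#'   `pct_of_mix`, `med_pct`, `mend_pct` (x100, rounded half away from
#'   zero to 2 decimals).
#' @export
#' @examples
#' expected_composition(mock_community_design())
expected_composition <- function(design) {
  if (!inherits(design, "community_design"))
    design <- community_design(design$organism, design$quantity_ug,
                               design$genome_size_bp, design$rrna_copies,
                               lineage = design$lineage)
  q <- design$quantity_ug
  gs <- design$genome_size_bp
  rr <- design$rrna_copies
  frac <- q / sum(q)
  med <- (q / gs) / sum(q / gs)
  mend <- (q * rr / gs) / sum(q * rr / gs)
  out <- data.frame(
    organism = design$organism,
    fraction_of_mix = frac, med = med, mend = mend,
    pct_of_mix = round_half_up(100 * frac),
    med_pct = round_half_up(100 * med),
    mend_pct = round_half_up(100 * mend),
    stringsAsFactors = FALSE)
  class(out) <- c("composition_table", "data.frame")
  out
}

#' @param x a `composition_table`.
#' @param path output TSV path.
#' @rdname expected_composition
#' @export
write_composition_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
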