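#' Primer definitions for the three amplified hypervariable regions
#'
#' Forward/reverse primer sequences (IUPAC) for the V4, V6-V8 and V7-V8
#' regions of the 16S rRNA gene, with the stagger range used by the
#' staggered sequencing strategy (0-3 random bases prefixed to the primer
#' to restore base-composition diversity on the flow cell).
#'
#' @return a named list of regions, each with `fwd`, `rev` and
#'   `stagger_range`.
#' @export
tag_primers <- function() {
  list(
    V4   = list(fwd = "GTGCCAGCMGCCGCGGTAA", rev = "GGACTACHVGGGTWTCTAAT",
                stagger_range = 0:3),
    V6V8 = list(fwd = "AAACTYAAAKGAATTGRCGG", rev = "ACGGGCGGTGTGTRC",
                stagger_range = 0:3),
    V7V8 = list(fwd = "GGGTTGCGCTCGTTG", rev = "ACGGGCGGTGTGTRC",
                stagger_range = 0:3))
}

iupac_expand <- function(code) {
  map <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
              R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
              Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
              H = c("A", "C", "T"), D = c("A", "G", "T"),
              B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  map[[code]]
}

# concrete primer site: first base of each IUPAC expansion
primer_site <- function(primer) {
  paste(vapply(strsplit(primer, "")[[1]],
               function(ch) iupac_expand(ch)[1], ""), collapse = "")
}

# fixed layout of primer binding sites on the simulated gene (0-based,
# half-open); spans are primer-inclusive amplified regions
gene_layout <- function() {
  p <- tag_primers()
  f515 <- nchar(p$V4$fwd); r806 <- nchar(p$V4$rev)
  f926 <- nchar(p$V6V8$fwd); f1114 <- nchar(p$V7V8$fwd)
  r1392 <- nchar(p$V6V8$rev)
  list(
    gene_length = 1450L,
    sites = list( # start, primer, strand
      list(start = 480L, primer = p$V4$fwd, strand = "+"),
      list(start = 780L - r806, primer = p$V4$rev, strand = "-"),
      list(start = 900L, primer = p$V6V8$fwd, strand = "+"),
      list(start = 1080L, primer = p$V7V8$fwd, strand = "+"),
      list(start = 1372L - r1392, primer = p$V6V8$rev, strand = "-")),
    regions = list(V4 = c(480L, 780L), V6V8 = c(900L, 1372L),
                   V7V8 = c(1080L, 1372L)))
}

#' Generate a synthetic 16S reference gene set with a known phylogeny
#'
#' Builds `n_organisms` full-length (~1450 bp) 16S-like genes by evolving
#' a random ancestor down a random coalescent organism phylogeny
#' (ultrametric, root-to-tip divergence `organism_divergence`), then
#' adding `copies_per_organism` slightly different rRNA gene copies per
#' organism (multi-copy operons commonly differ at a handful of
#' positions). All genes share exact primer binding sites for the V4,
#' V6-V8 and V7-V8 regions at fixed coordinates, so amplicons are
#' positionally comparable across organisms. Organisms receive distinct
#' genus-level 6-rank lineages; the returned tree has one tip per gene
#' copy and records the true genealogy with branch lengths in expected
#' substitutions per site.
#'
#' @param n_organisms number of organisms (>= 1).
#' @param copies_per_organism rRNA gene copies per organism (>= 1).
#' @param seed integer seed; output is byte-identical for a given seed.
#' @param organism_divergence expected root-to-tip per-site substitution
#'   probability outside primer sites (default 0.10).
#' @param min_organism_divergence terminal-branch extension ensuring every
#'   organism pair differs at >= 2x this fraction of sites (default 0.04,
#'   i.e. >= 8\% pairwise divergence -- distinct genera, as in a mock
#'   community); the remaining depth is coalescent structure.
#' @param copy_divergence per-site substitution probability between copies
#'   of one organism (default 0.005; capped so copies differ pairwise at
#'   <= 2\% of positions).
#' @param organism_ids optional organism labels (default `org1`, `org2`, ...).
#'
#' @return a list of class `reference_set` with elements `genes` (per
#'   organism: `organism_id`, `copies` named character vector, `lineage`,
#'   `region_coords`), `tree` (an `ape::phylo` whose tips are gene copies),
#'   `lineages` (data.frame mapping copy ids to 6-rank lineages) and
#'   `layout`.
#' @export
generate_reference_set <- function(n_organisms, copies_per_organism = 2L,
                                   seed = 1L, organism_divergence = 0.10,
                                   copy_divergence = 0.005,
                                   min_organism_divergence = 0.04,
                                   organism_ids = NULL) {
  if (n_organisms < 1) stop("empty design: n_organisms must be >= 1")
  if (copies_per_organism < 1) stop("copies_per_organism must be >= 1")
  set.seed(seed)
  lay <- gene_layout()
  L <- lay$gene_length
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  prot <- rep(FALSE, L) # positions protected from mutation (primer sites)
  for (s in lay$sites) {
    site <- primer_site(s$primer)
    if (s$strand == "-") site <- revcomp(site)
    idx <- (s$start + 1L):(s$start + nchar(site))
    anc[idx] <- strsplit(site, "")[[1]]
    prot[idx] <- TRUE
  }
  free <- which(!prot)
  if (is.null(organism_ids)) organism_ids <- paste0("org", seq_len(n_organisms))
  stopifnot(length(organism_ids) == n_organisms)
  # newick-safe slugs used for gene-copy ids and tree tip labels
  slugs <- make.unique(gsub("[^A-Za-z0-9]+", "_", organism_ids), sep = "_")

  mutate_sites <- function(x, sites) {
    for (i in sites) x[i] <- sample(setdiff(bases, x[i]), 1L)
    x
  }
  mutate_p <- function(x, p) {
    n_mut <- stats::rbinom(1L, length(free), min(p, 1))
    mutate_sites(x, sample(free, n_mut))
  }
  max_copy_mut <- floor(0.01 * L) # pairwise copy divergence stays <= 2%

  # organism phylogeny: random coalescent, rescaled so every root-to-tip
  # path equals organism_divergence; sequences evolve along its edges
  if (n_organisms > 1L) {
    otree <- ape::rcoal(n_organisms, tip.label = slugs)
    depth <- max(ape::node.depth.edgelength(otree))
    coal_part <- max(organism_divergence - min_organism_divergence, 0)
    otree$edge.length <- otree$edge.length / depth * coal_part
    term <- otree$edge[, 2] <= n_organisms
    otree$edge.length[term] <- otree$edge.length[term] +
      min(min_organism_divergence, organism_divergence)
    nnode <- n_organisms + otree$Nnode
    node_seq <- vector("list", nnode)
    root <- n_organisms + 1L
    node_seq[[root]] <- anc
    edges <- stats::reorder(otree, "cladewise")$edge
    elens <- stats::reorder(otree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      node_seq[[edges[e, 2]]] <- mutate_p(node_seq[[edges[e, 1]]], elens[e])
    }
    org_seqs <- node_seq[seq_len(n_organisms)]
    names(org_seqs) <- otree$tip.label
    org_seqs <- org_seqs[slugs]
  } else {
    otree <- NULL
    org_seqs <- list(mutate_p(anc, organism_divergence))
    names(org_seqs) <- slugs
  }

  genes <- vector("list", n_organisms)
  tip_labels <- character(0)
  lineage_rows <- list()
  for (o in seq_len(n_organisms)) {
    base_seq <- org_seqs[[slugs[o]]]
    copies <- character(copies_per_organism)
    for (cp in seq_len(copies_per_organism)) {
      s <- base_seq
      if (cp > 1L) {
        n_cm <- min(stats::rbinom(1L, length(free), copy_divergence),
                    max_copy_mut)
        s <- mutate_sites(s, sample(free, n_cm))
      }
      copies[cp] <- paste(s, collapse = "")
    }
    names(copies) <- paste0(slugs[o], "_c", seq_len(copies_per_organism))
    grp <- (o - 1L) %/% 3L + 1L
    lineage <- paste(c("Bacteria", paste0("Phylum", grp),
                       paste0("Class", grp), paste0("Order", grp),
                       paste0("Family", o), paste0("Genus", o)),
                     collapse = ";")
    genes[[o]] <- list(organism_id = organism_ids[o], copies = copies,
                       lineage = lineage, region_coords = lay$regions)
    tip_labels <- c(tip_labels, names(copies))
    lineage_rows[[o]] <- data.frame(sequence_id = names(copies),
                                    lineage = lineage,
                                    organism_id = organism_ids[o],
                                    stringsAsFactors = FALSE)
  }
  names(genes) <- organism_ids

  # true genealogy: organism coalescent with a cherry of copies per tip
  clade_text <- function(g) {
    nm <- names(g$copies)
    if (length(nm) == 1L) nm # single copy replaces the tip label in place
    else paste0("(", paste(paste0(nm, ":", copy_divergence), collapse = ","),
                ")")
  }
  if (is.null(otree)) {
    tree <- ape::read.tree(text = paste0(
      "(", clade_text(genes[[1]]), ":", organism_divergence, ");"))
  } else {
    nwk <- ape::write.tree(otree)
    for (o in seq_len(n_organisms)) {
      # graft the copy cherry onto the organism tip, keeping its branch;
      # tips are always preceded by "(" or "," in newick
      nwk <- sub(paste0("([(,])", slugs[o], ":"),
                 paste0("\\1", clade_text(genes[[o]]), ":"), nwk)
    }
    tree <- ape::read.tree(text = nwk)
  }

  structure(list(genes = genes, tree = tree,
                 lineages = do.call(rbind, lineage_rows),
                 layout = lay),
            class = "reference_set")
}

#' Extract per-copy amplicon sequences for a region
#'
#' @param refs a [generate_reference_set()] result.
#' @param region one of `"V4"`, `"V6V8"`, `"V7V8"`.
#' @return named character vector of primer-inclusive amplicon sequences,
#'   one per gene copy.
#' @export
region_sequences <- function(refs, region) {
  out <- character(0)
  for (g in refs$genes) {
    rc <- g$region_coords[[region]]
    if (is.null(rc)) stop("region not present in reference set: ", region)
    out <- c(out, vapply(g$copies, function(s)
      substr(s, rc[1] + 1L, rc[2]), ""))
  }
  out
}

#' @rdname region_sequences
#' @return `reference_fasta_table()` returns a named character vector of
#'   all full-length gene copies.
#' @export
reference_sequences <- function(refs) {
  seqs <- unlist(lapply(refs$genes, function(g) g$copies), use.names = FALSE)
  names(seqs) <- unlist(lapply(refs$genes, function(g) names(g$copies)),
                        use.names = FALSE)
  seqs
}
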