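# tagbench

Benchmarking 16S rRNA tag (amplicon) sequencing pipelines against
defined mock communities.

Amplicon surveys of the 16S rRNA gene are the workhorse of microbial
ecology, but their results depend on choices the biology does not make:
which hypervariable region is amplified (V4, V6–V8, V7–V8), which
platform sequences it, how aggressively reads are quality-filtered, and
how sequences are clustered into OTUs. `tagbench` is for
bioinformaticians who build or evaluate such pipelines and want every
stage tested against a community whose ground truth is known: a defined
DNA pool with known organisms, quantities, genome sizes and rRNA gene
copy numbers, plus a read simulator that records exactly which errors it
injected into every read.

## What it computes

**Expected composition (MED/MEND).** For organism *i* with quantity
*Q(i)* (µg), genome size *GS(i)* (bp) and rRNA copy number *RR(i)*:

    MED(i)  = (Q(i)/GS(i)) / Σⱼ Q(j)/GS(j)            — genome copies
    MEND(i) = (Q(i)·RR(i)/GS(i)) / Σⱼ Q(j)·RR(j)/GS(j) — rRNA gene copies

MEND is the expectation amplicon reads should match, since reads sample
rRNA genes, not genomes.

**The rest of the pipeline:** a synthetic-community generator (coalescent
phylogeny, multi-copy genes, embedded primer sites) and read simulator
(platform error models with quality-correlated errors, homopolymer-boosted
indels, staggered primers, chimeras, per-read truth tables); read QC
(lenient/stringent filters, sliding-window trimming, paired-end merging,
k-mer contaminant screening); alignment-based error profiling
(insertions/deletions/substitutions per 1000 reads and per reference
position, best-copy attribution for multi-copy genes); OTU clustering
(dereplication, 99% denoising, minimum-size filter, de novo chimera
flagging, 97% OTUs, rarefaction); bootstrap 8-mer naive-Bayes taxonomy
with the deepest-lineage ≥ 0.50 rule; and diversity analysis
(rarefaction curves, Bray-Curtis, weighted/unweighted UniFrac, PCoA,
Procrustes M² with a Monte Carlo permutation test).

## Worked example

```r
library(tagbench)

design <- mock_community_design()
expected_composition(design)[, c("organism", "pct_of_mix", "med_pct", "mend_pct")]
#>                           organism pct_of_mix med_pct mend_pct
#>   Clostridium phytofermentans ISDg       35.0   30.37    71.35
#>    Natrinema pellirubrum str. J7-2       30.0   34.12    10.02
#>              Pantoea sp. AB-valens       15.0   14.44     4.24
#>           Rhodanobacter sp. 2APBS1       10.0    9.95     5.85
#>      Natronobacterium gregoryi SP2        6.8    7.55     6.65
#>  Pseudoxanthomonas suwonensis 11-1        2.0    2.46     1.45
#>      Mycobacterium smegmatis JS623        0.6    0.39     0.23
#>          Halobacterium sp. str DL1        0.4    0.59     0.17
#>           Paenibacillus lactis 154        0.2    0.12     0.04
```

The first column is the naive mass fraction; `med_pct` corrects for
genome size and `mend_pct` additionally for rRNA copy number. The
8-copy *Clostridium* is 35% of the DNA mass but 71% of expected reads.

Simulate a single-organism V4 library and profile its sequencing errors
against the organism's two slightly different gene copies:

```r
refs <- generate_reference_set(9, 2, seed = 42,
                               organism_ids = design$organism)
ps <- community_design("Pseudoxanthomonas suwonensis 11-1", 0.2, 3419049, 2)
model <- miseq_error_model(read_length = 400, paired = FALSE)
reads <- simulate_sample(ps, refs, "V4", model, n_reads = 10000,
                         stagger_max = 0, seed = 5)
copies <- region_sequences(refs, "V4")[
  c("Pseudoxanthomonas_suwonensis_11_1_c1",
    "Pseudoxanthomonas_suwonensis_11_1_c2")]
profile_sample(reads$reads, copies, n_subsample = 10000, seed = 1)$summary
#>          type count rate_per_1000 rate_per_aligned_base
#>     insertion    23           2.3          7.666667e-06
#>      deletion    26           2.6          8.666667e-06
#>  substitution  3027         302.7          1.009000e-03
```

The truth table recorded 23 insertions, 26 deletions and 3027
substitutions — the profiler recovered every count exactly. Re-profiling
the same subsample after the stringent QC filter drops the substitution
rate to 255.0 per 1000 reads (8427 reads surviving): the filter removes
error-rich low-quality reads, as it does on real data.

Cluster a mock-community sample into OTUs:

```r
mock <- simulate_sample(design, refs, "V4", model, n_reads = 5000,
                        chimera_fraction = 0.02, seed = 7)
keep <- qc_filter(mock$reads, "stringent")$pass     # 4204 of 5000 pass
cl <- dereplicate(mock$reads[keep, ], "mock1")
cl <- greedy_cluster(cl, 0.99)                      # denoise
cl <- filter_min_size(cl, 3)                        # drop size-1/2 clusters
cl <- remove_flagged(cl, chimera_flag_denovo(cl))   # de novo chimera scan
otus <- build_otu_table(greedy_cluster(cl, 0.97))   # 97% OTUs
nrow(otus)
#> [1] 10
```

Ten OTUs from a nine-organism pool at these settings (one surviving
low-abundance chimera cluster); with error-free, chimera-free reads the
pipeline returns exactly one OTU per sampled organism.

## Documentation

The methods vignette (`vignettes/tagbench-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic world does and does not emulate, and
the numerical design choices (alignment scoring, identity definition,
chimera margin, rarefaction semantics, Procrustes variant).
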