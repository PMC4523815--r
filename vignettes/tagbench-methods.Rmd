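---
title: "tagbench: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tagbench: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tagbench` is a benchmarking toolkit for 16S rRNA tag (amplicon)
sequencing pipelines. Its premise is that every stage of a tag pipeline --
read quality control, error profiling, OTU clustering, taxonomic
classification, beta-diversity comparison -- can be validated against a
*defined* community: a DNA pool whose organisms, quantities, genome sizes
and rRNA gene copy numbers are known, so the expected composition and the
per-read ground truth are computable. This vignette documents the models,
the tunable parameters, and the design decisions where the design was
genuinely open.

## Expected composition of a defined DNA pool

For organism $i$ with DNA quantity $Q(i)$ (µg), genome size $GS(i)$ (bp)
and rRNA gene copy number $RR(i)$, the genome-size-normalized expected
distribution and its copy-number-normalized counterpart are

$$\mathrm{MED}(i) = \frac{Q(i)/GS(i)}{\sum_j Q(j)/GS(j)}, \qquad
  \mathrm{MEND}(i) = \frac{Q(i)\,RR(i)/GS(i)}{\sum_j Q(j)\,RR(j)/GS(j)}.$$

$Q/GS$ is proportional to the number of genome copies added; multiplying
by $RR$ converts genome copies to rRNA gene copies, which is what amplicon
reads actually sample. `expected_composition()` retains full precision
internally and prints percentages rounded half-away-from-zero to two
decimals, matching the usual printed-table convention. The built-in
nine-organism design (`mock_community_design()`) spans quantities from
3.5 µg down to 0.02 µg and copy numbers from 1 to 8; its most
copy-rich organism contributes ~30% of genomes but ~71% of expected
reads, which is exactly the distinction MED/MEND is meant to expose.

The simulator weights organisms by MEND, not MED: reads sample rRNA
genes. Within an organism, gene copies are drawn uniformly.

## The synthetic world

`generate_reference_set()` evolves one random ~1450 bp ancestor down a
random coalescent organism phylogeny (`ape::rcoal`), rescaled so every
root-to-tip path equals `organism_divergence` (default 0.10
substitutions/site). A terminal-branch extension
(`min_organism_divergence`, default 0.04) guarantees every organism pair
differs at ≥ 8% of sites -- mock communities are assembled from distinct
genera, and without this floor coalescent sister taxa can be nearly
identical, which collapses OTUs and has no analogue in a real mock. Each
organism receives `copies_per_organism` gene copies differing at ≤ 2% of
sites (default per-site probability 0.005, hard-capped at 1%), emulating
multi-copy rRNA operons with "slightly different sequences". Exact primer
binding sites for V4 (515F/806R), V6--V8 (926F/1392R) and V7--V8
(1114F/1392R) are embedded at fixed coordinates, so amplicons are
positionally comparable; IUPAC codes are instantiated deterministically
(first base of the expansion). The returned tree has one tip per gene
copy and is the ground truth for UniFrac.

### Qualities and errors

Per-base Phred scores are drawn from a normal around a non-increasing
positional decay curve, plus a per-read offset
(`read_quality_sd`), clipped to [2, 41]. The per-read offset is not
cosmetic: with only per-base noise, the per-read mean quality is almost
deterministic (SD ≈ `quality_sd`/√L), so mean-quality filters pass either
every read or none. Real runs vary cluster-to-cluster; the offset
reproduces realistic pass rates (~74% stringent for the MiSeq-like
preset, ~18% for the 454-like preset, in the range of published
recovery tables) and makes read-level QC informative.

Errors are injected independently per base in template order.
The per-base probability of each error type is the nominal model rate
scaled by the base's quality-implied error weight $10^{-q/10}$,
normalized by the sample-mean weight. Consequences: (i) expected totals
equal the nominal rate exactly, so realized rates converge to model rates
(verified at 3 binomial SD); (ii) low-quality *reads* carry
proportionally more errors, so stringent QC lowers measured error rates,
as observed on real data. Insertions land after their template base and
inherit its quality; indel probabilities are multiplied by
`homopolymer_multiplier` inside runs of ≥ 3 identical bases (the 454-like
preset uses 4, emulating pyrosequencing's homopolymer weakness; the
MiSeq-like preset uses 1). With the multiplier at 1 and a flat decay,
indel positions are uniform over the template (verified by chi-square).

Neither preset claims to match a particular instrument's measured rates
-- the published error figures are graphical -- so the presets are
configurable defaults: MiSeq-like (substitutions 10⁻³, indels 10⁻⁵,
decay Phred 38→30) and 454-like (substitutions 5×10⁻⁴, indels 2×10⁻³,
boost 4, decay 34→26).

Staggered primers are emulated by prefixing 0..`stagger_max` random
bases. Chimeras are two-parent single-crossover splices: parents are
drawn abundance-weighted from *distinct* organisms (unconstrained draws
would make half the "chimeras" same-parent splices, which are not
chimeras), with a breakpoint uniform over the central 25--75% of the
amplicon so the detector has detectable two-parent structure.

### What a green test does not establish

The generator emulates composition, divergence structure, quality decay,
quality-correlated errors, homopolymer indels, stagger and chimeras. It
does not emulate: PCR amplification efficiency differences (primer bias
must be imposed explicitly, as in the metric-robustness property),
flowgram-space 454 errors, position-specific motifs other than
homopolymers, contamination, or the read-2 "hard stop" GC failure.
Green tests establish algorithmic correctness against this stated world,
not instrument realism.

## Read processing

The two QC profiles follow the quoted rules literally, with "more than"
and "lower than" strict: lenient rejects > 5 Ns, mean Q < 30, or > 10
bases < Q15; stringent rejects ≥ 1 N, mean Q < 33, or > 3 bases < Q20.
Any base outside A/C/G/T counts as an N (conservative superset); average
quality is the arithmetic mean of Phred integers, the convention of the
era's read filters. The stringent-pass set is provably a subset of the
lenient-pass set; consequently the stringent pass *percentage* can never
exceed the lenient one.

`merge_pairs()` reimplements overlap merging: reverse-complement read 2,
scan overlaps from `min_overlap` (10) up, choose minimum mismatch
density (ties: longest overlap), accept at density ≤ 0.25 -- the cited
assembler's documented defaults, since the source protocol names the tool
without parameters. Disagreements take the higher-quality base (ties keep
read 1); merged quality is the per-position maximum. `window_trim()`
cuts immediately before the first 20-base window whose mean quality drops
below Q30, is idempotent, and returns reads shorter than the window
unchanged. `kmer_screen()` flags reads sharing ≥ 1 21-mer (either
strand) with the contaminant set; the screening tool it stands in for
has unstated parameters, so standard contaminant-screen sensitivity is
used. `trim_primer_stagger()` scans stagger offsets 0..3 and takes the
smallest matching offset (then fewest mismatches) under IUPAC semantics.

## Alignment and error profiling

`align_semiglobal()` is an affine-gap aligner with end gaps free on the
reference only: the query (read) aligns in full, unaligned reference
flanks cost nothing. Freeing the query's end gaps as well would silently
absorb read-edge errors into unpenalized overhangs and bias error rates
downward. Scoring is fixed and documented: match +2, mismatch −3, gap of
length $k$ costs $2 + 2k$; traceback ties prefer diagonal > up > left. A
more conventional gap opening of −5 was evaluated and rejected: with a
single-base gap at −7, a deletion one base from a read end is always
re-explained as a substitution (−3 beats −5), which depresses measured
deletion rates by ~1.3% of their value at high rates -- a systematic
estimator bias of roughly 3 binomial SD at n = 10,000 reads. With −2 the
terminal gap (−4 + 2 match) still beats the mismatch and all nine cells
of the rate-recovery grid pass with |z| ≤ ~1.2. Deletions at the
*final* template position remain invisible to any aligner (an
information-theoretic limit).

`profile_sample()` follows the published procedure literally: uniform
subsample of 10,000 raw reads, *then* optional QC, each read aligned to
every gene copy, best score kept (ties: fewest total errors, then first
copy). Errors are counted over the aligned portion only; insertions are
attributed to the reference position left of the inserted run (a run of
k counts k insertions at one anchor), positions are per-gene 1-based
coordinates. Rates are reported both per 1000 reads (the figure-axis
convention; the package counts errors, not error-containing reads, and
documents that reading) and per aligned reference base (the natural
per-base probability). Raw staggered reads profiled against full genes
show inflated edge errors -- the stagger bases are junk by construction
-- mirroring the edge hotspots seen in real profiles; trim first if that
is not wanted.

## OTU pipeline

Identity is matching columns over alignment columns of a *global*
alignment with end-gap runs excluded -- close to the cited tool family's
default notion. Denoising is greedy abundance-sorted centroid clustering
at 0.99 (a clustering step, not an error model); OTU formation repeats it
at 0.97; clusters under 3 reads are discarded in between. Samples are
pooled before dereplication with per-sample counts retained (the
processing order leaves per-sample vs pooled dereplication unstated;
pooling is the simpler invariant-preserving choice).

The de novo chimera scan is deliberately simplified: candidate parents
are unflagged clusters ≥ 2× the candidate's size (visited largest-first,
so a chimera cannot vouch for its smaller siblings -- without this
exclusion, abundant chimera clusters shadow rarer ones with similar
breakpoints and sensitivity drops below target); a candidate is flagged
when some ordered parent pair admits a single-crossover model beating the
best single parent by ≥ 0.02 identity with both segments ≥ 99% identical
to their parents. The 0.02 margin is the single documented knob standing
in for the reference tool's heuristics.

`rarefy()` subsamples each column without replacement to exactly the
target depth (default 2893, the least abundant sample of the reference
datasets); columns below depth are dropped, not resampled. Chimera
sensitivity and false-positive rate are measured at cluster level using
the centroid read's truth label, because individual chimeric reads with
unique breakpoints are removed by the min-size filter before the chimera
stage ever sees them.

## Taxonomy

The classifier is the published word-matching naive Bayes: 8-mers,
per-genus conditional word probabilities $(m(w) + P_w)/(M + 1)$ with
corpus prior $P_w = (n(w)+0.5)/(N+1)$, 100 bootstrap trials of
⌈W/8⌉ words drawn with replacement from the query's W distinct words;
per-rank confidence is the fraction of trials whose winner shares the
assigned genus' lineage down to that rank. Constants are the published
algorithm's, since the source names the tool without parameters.
`assign_deepest()` keeps the deepest rank with confidence ≥ 0.50 -- the
only threshold the source states (for shotgun reads); the OTU-level
threshold is unstated there, so 0.50 is the default and it is
configurable. Confidences need not be monotone across ranks; only the
deepest-≥-threshold contract is asserted.

## Diversity

Bray-Curtis is $\sum_k |a_k - b_k| / \sum_k (a_k + b_k)$. Unweighted
UniFrac is branch length unique to one community over branch length
covered by either; weighted UniFrac is $\sum_b \ell_b\,|p_b^A - p_b^B|$
with $p_b$ the descendant fraction of the community total, divided by
$\sum_b \ell_b (p_b^A + p_b^B)$ when normalized (the default; whether
the published comparisons normalized is not stated, so the flag is
recorded in output). PCoA is classical scaling with negative eigenvalues
dropped (no Lingoes/Cailliez correction) and axis signs fixed by making
the largest-magnitude loading positive. Procrustes uses orthogonal
rotation, uniform scaling and translation with symmetric normalization
(both configurations scaled to unit sum of squares), $M^2 = 1 - (\sum_i
\sigma_i)^2$; the Monte Carlo test is one-sided lower-tail (small $M^2$
means concordance), permuting the second configuration's sample labels,
with $p = (1 + \#\{M^2_{perm} \le M^2\})/(1 + n_{perm})$. Ordinations
are compared on at most 3 axes (3-D PCoA convention).

## The metric-robustness regression

The published headline -- weighted UniFrac ordinations are the least
robust to primer/platform bias, Bray-Curtis and unweighted UniFrac the
most -- is not desk-reproducible (it needs the archived datasets), so it
is replaced by a fixed-seed regression on a stated world: 24 taxa on an
interior-rich coalescent tree (`min_organism_divergence = 0.01`; natural
communities span a continuum of relatedness, unlike the well-separated
mock genera), 8 samples with lognormal(0, 1.2) abundances at 70%
presence, and two "primer" datasets made by multiplying per-taxon
abundances with lognormal(0, 0.8) vectors times per-clade lognormal(0,
1.5) factors over 4 clades -- primer bias is lineage-specific (entire
archaeal clades drop out of some primer sets). At the frozen seed the
weighted-UniFrac Procrustes $M^2$ (0.55) exceeds Bray-Curtis (0.50) and
unweighted UniFrac (0.47), the published ordering. The ordering also
holds in the majority of nearby seeds but is asserted only at the frozen
seed; it is a regression property of a stated world, not a theorem. On a
*star* phylogeny weighted UniFrac reduces algebraically to Bray-Curtis,
which is why the tree's interior structure matters.

## Numerical notes and limitations

* All randomized functions take explicit seeds and call `set.seed()`
  internally; they clobber the caller's RNG state by design (documented
  determinism beats statefulness here).
* Alignment scores are accumulated in single-precision floats; all
  attainable scores are small integers, exactly representable.
* Quality "truncation" to [2, 41] is clipping, not resampling.
* The error-rate estimator cannot see deletions at the final aligned
  position and re-explains some near-edge events; at rates ≤ 10⁻² and
  n = 10,000 the residual bias is within ~1 binomial SD under the
  package scoring.
* Reference coordinates in positional histograms are per-gene, not
  standard numbering against a reference organism.
* The simulator does not model PCR chimera formation kinetics; the
  chimera fraction is an explicit parameter.
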