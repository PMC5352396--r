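---
title: "Methods: calling TF direct targets from ChIP-seq and knockdown RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling TF direct targets from ChIP-seq and knockdown RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regtarget)
```

## The question and the inference

A transcription factor's ChIP-seq experiment yields thousands of binding
sites; a knockdown RNA-seq contrast yields hundreds of responsive
transcripts. Neither alone identifies *direct* regulation. The inference
this package implements treats a transcript as a candidate direct target
when two independent observations coincide: its expression responds to
depleting the factor, and the factor demonstrably binds near its
transcription start site. The statistical backbone is a distance argument —
if binding drives the expression response, the nearest-peak distances of
responsive transcripts must be stochastically smaller than those of the
annotated transcriptome at large — tested with a two-sample
Kolmogorov–Smirnov (KS) statistic against that background.

The pipeline assumes: peak calling and differential-expression modelling
have already happened upstream (inputs are narrowPeak files and a DE table
with log2 fold changes and adjusted p-values); coordinates are 0-based
half-open everywhere; and regulation direction can be read off the sign of
the knockdown contrast (down upon knockdown = activated by the factor).

## Stages and their parameters

**Replicate concordance** (`replicate_concordance`). Two peaks are shared
when their intervals overlap by at least 1 bp; pairing is one-to-one and
greedy in genomic order so Venn-style counts never double-count a peak.
Concordance is `n_shared / min(n_a, n_b)` by default; the smaller replicate
bounds how many pairs can exist, so this is the least pessimistic
denominator. A mean-of-both-fractions alternative is available via
`denominator = "mean"`. The conventional QC gate is 0.8: the pipeline warns
below it but still combines, because the threshold justifies combining
replicates rather than defining a hard failure. Greedy pairing assumes
peaks within one set do not overlap each other (true of standard peak
callers); with heavily nested peaks the greedy count could depend on
orientation.

**High-confidence peaks** (`high_confidence_peaks`). Each shared pair
becomes one site: interval union, summit and score from the higher-scoring
member, ties to replicate one. Upstream conventions do not specify how the
two members are merged; the union-plus-best-summit rule keeps the stronger
replicate's localization while never shrinking the evidence interval.

**Signal and correlation.** Binding signal is quantified on
summit-centered windows of `width = 100` bp (the scale at which summit
localization is meaningful), clipped at chromosome ends, with overlapping
windows merged across samples before cross-sample comparison (the union is
the default reference set; no filtered subset is imposed). Counts are
normalized to reads per million and compared by Spearman's rho, which is
invariant to monotone distortions of ChIP efficiency. Binding-pattern
clustering uses average linkage on `1 - rho`; the expression heatmap uses
Ward linkage on euclidean distances of row-standardized values
(`method = "ward"` maps to `hclust`'s classic `"ward.D"` update). Constant
expression rows standardize to zero rather than erroring. Zero rank
variance makes Spearman's rho undefined; it is returned as `NA` with a
warning rather than silently as 0.

**DE filtering** (`filter_de`). `fold_threshold = 2.0` with a *strict*
inequality: a transcript at exactly 2-fold is excluded (and counted in
`n_boundary`, so boundary cases are visible). X/Y transcripts are removed
before anything else is counted; the autosomal universe is used
consistently downstream, including for enrichment. No adjusted-p filter is
applied by default — the fold rule alone defines the filtered set —
because adding one silently changes every downstream count; `padj_threshold`
is available for users who want it.

**Distances, CDFs, KS** (`nearest_peak_distance`, `distance_ecdf`,
`ks_two_sample`). Distance is TSS-to-summit, unstranded and absolute;
summit-to-TSS is the natural point-to-point measure once summits exist
(`reference = "edge"` measures to the peak boundary instead). A transcript
whose chromosome has no peak gets an infinite distance: it stays in ECDF
denominators (absence of nearby binding is evidence, not missingness) but
can never contribute to the supremum below it. The KS statistic is
evaluated at every observed value, so ties are exact. Three p-value
routes:

* exact enumeration of all `choose(n1+n2, n1)` splits when that count is
  at most 2e5 and the pooled sample is small (covers `n1 = n2 = 10`,
  where `C(20,10) = 184,756`), valid under ties;
* a seeded Monte-Carlo permutation estimate (10^4 permutations, add-one
  estimator) when exactness is requested but not enumerable;
* the asymptotic Kolmogorov tail with Stephens' small-sample factor,
  `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D`,
  `Q = 2 * sum_j (-1)^(j-1) exp(-2 j^2 lambda^2)`, series truncated below
  1e-10 and clamped into (0, 1].

A caution worth stating plainly: at `n1 = n2 = 10` the asymptotic form
deviates from the exact permutation p by up to about 0.1 in the mid-range
(it is accurate in the tails and improves quickly with `ne`); the exact
route is therefore the default whenever it is enumerable. The background
sample for the enrichment test is the nearest-peak distance of *all*
annotated autosomal transcripts; DE transcripts are not removed from it
(at realistic DE fractions of a few percent the contamination is
negligible, and keeping the background fixed makes the two per-direction
tests comparable). A seeded subsample of the background is available via
`background = k`.

**Target calling** (`call_direct_targets`). `cutoff = 50,000` bp,
*inclusive* ("within 50 kb"), applied to the filtered transcripts per
direction; exact-boundary cases are counted in `n_boundary`. The 50-kb
choice follows the observation that TF-binding/expression correlation
decays beyond ~100 kb; targets are monotone in the cutoff by construction.
Multiple peaks per transcript are not weighted — only the nearest matters —
and no decay score or looping model is applied.

**Enrichment** (`enrich_gene_sets`). Hypergeometric upper tail
`P(X >= k)` via `phyper` with BH adjustment across all sets tested in one
run; runs are per direction, mirroring direction-split enrichment tables.
The universe is all autosomal genes of the annotation (consistent with the
X/Y omission); transcripts collapse to genes before counting so a gene
contributes at most 1 to any overlap. Sets with no member in the universe
are skipped, not reported at p = 1. The ranked-list, weighted-KS flavour
of gene-set analysis is deliberately out of scope: no ranking metric is
defined for a plain target list.

**Motif stage** (`consensus_motif_enrichment`). IUPAC consensus matching
(default `TTCNNNGAA`, 9 bp with fixed spacer) on both strands via
Biostrings; the null is a per-sequence seeded mononucleotide shuffle and
the p-value a binomial upper tail at the observed number of matching
sequences. This is a consensus-scan enrichment, not de novo motif
discovery, and no position-weight-matrix scoring is attempted.

## What the synthetic generator emulates — and what it does not

`simulate_scenario()` produces every pipeline input with planted truth.
The *separated* design plants `n_targets = 50` direct targets whose single
peak falls uniformly within 50 kb of the TSS, `n_background_peaks = 200`
peaks at least 100 kb from every TSS, and `n_null_de = 25` DE-but-untargeted
decoys drawn from transcripts verified (brute force) to be at least 100 kb
from every peak — so about one third of filtered DE transcripts lack a
nearby site, matching the fraction such studies observe. Replicates keep
each true peak independently with probability `concordance = 0.9`
(comfortably above the 0.8 gate, as published replicate pairs are) and
jitter boundaries by Normal(0, 10 bp). The DE effect is
`|log2FC| = 2 ± 0.2`, just beyond the strict 2-fold rule, with sign set by
the planted direction. Counts are gamma-Poisson (dispersion 0.1) with a
4-fold effect on 30% of peaks in one sample group, giving within-group >
between-group correlation. One gene set per direction contains 90% of that
direction's target genes plus filler; 20 decoy sets of 50 genes are drawn
uniformly from the 1,000-gene universe.

The default genome is two 120-Mb autosomes plus a 60-Mb chrX holding 10%
of the 1,000 transcripts. This is deliberately larger than a "toy"
genome: planting 50 isolated targets while keeping every decoy 100 kb from
every peak requires exclusion windows whose total exceeds a few tens of
megabases, so a smaller genome makes the separated design geometrically
infeasible (the generator detects this and errors rather than looping).
Targets are chosen among transcripts isolated by at least 150 kb from any
other TSS, which is what guarantees the separation invariant exactly.

The *null* design places the same number of peaks uniformly and assigns DE
status independently of peak proximity, making DE and background distances
exchangeable — the calibration case for the KS test.

What passing on these scenarios does **not** show about real data: real
peak sets have width/score distributions tied to read depth, clustered
binding (super-enhancers), and mappability artifacts; real annotations
have gene-dense regions where the 100-kb separation never holds, so real
target calls are necessarily noisier than planted recovery; real DE tables
carry correlated errors the independent-noise generator does not emulate;
and the generator writes no sequence-level features, so the motif stage is
validated on separately generated sequences, not on scenario peaks.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; narrowPeak summit offsets
  of -1 fall back to the floor midpoint so every peak remains usable for
  summit windows; a minus-strand TSS is `tx_end - 1`, the last covered
  base.
* `write_bed` emits 10-column narrowPeak (summit as the field-10 offset)
  so a write/read round trip preserves every coordinate field exactly.
* Exact KS comparisons use a tolerance of 1e-12 on `D` when counting
  permutation exceedances, so floating-point noise cannot flip a split
  across the observed statistic.
* Hierarchical-clustering tie-breaks are those of `stats::hclust`
  (deterministic); Ward heights are monotone for both supported linkages.
* The replicate generator keeps each peak with probability equal to the
  requested concordance: under the min denominator the expected measured
  concordance is then the requested value (shared/min ~ p^2 N / p N = p).
* All generators run under an isolated RNG scope (`with_seed`), so
  identical (parameters, seed) give bit-identical outputs and library
  calls never perturb the caller's stream; the pipeline funnels every
  random choice through named stage seeds derived from one master seed.

## Problem sizes used in the test suite

The suite validates statistics against independent oracles (hand-rolled
rank-then-Pearson for Spearman, `psmirnov` for the exact KS tail,
`choose()`-enumeration for the hypergeometric, regex expansion for IUPAC
matching, all-pairs scans for distances and pairings) at sizes chosen to
finish in minutes on one core: 1,000 Spearman vectors of length up to 50;
100 exact KS enumerations at `n1 = n2 = 10`; 200 seeded null-scenario runs
for KS calibration at ~50 DE vs ~900 background transcripts using the
asymptotic p (exact or Monte-Carlo p-values at that size across 200 runs
would dominate the suite's budget for no extra information — the
asymptotic form is accurate there); 500 uniform-query simulations of 20
gene sets for FDR calibration; and concordance calibration on 10,000-peak
replicate pairs across 20 seeds. Planted-set recovery is asserted exactly
on the noise-free separated scenario (`concordance = 1`, `jitter_sd = 0`,
`noise_sd = 0`) — the configuration in which exactness is a theorem rather
than a probability — while the realistic defaults are exercised end to end
in the pipeline tests and the acceptance script.

## Known limitations

The distance rule is symmetric and promoter-centric: it cannot separate a
target regulated through a 45-kb enhancer from a bystander gene that
merely sits near one, and it ignores chromatin contact maps entirely. The
KS background includes the DE transcripts themselves (negligible at a few
percent DE, but a bias at extreme DE fractions). Direction labels inherit
whatever the upstream DE contrast measured — secondary effects of a 96-h
knockdown are indistinguishable from direct ones except through the
distance argument. The hypergeometric enrichment treats genes as
exchangeable, with none of the expression-level or gene-length matching
that region-based tools apply.
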