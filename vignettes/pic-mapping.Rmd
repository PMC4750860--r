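---
title: "Mapping pre-initiation complexes at base-pair resolution with exopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pre-initiation complexes at base-pair resolution with exopair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopair)
```

## The measurement model

ChIP-exo maps protein–DNA crosslinks at near base-pair resolution. After
immunoprecipitation, lambda exonuclease digests each fragment 5'→3' until it
is blocked a few bp from the crosslink, so sequenced 5' ends pile up at two
strand-specific "borders": forward-strand (W) reads at the left border of
the protected footprint, reverse-strand (C) reads at the right border. A
bound location therefore appears as a W peak and a C peak a short, roughly
constant distance apart, and the midpoint of the two summits estimates the
crosslink point itself. For the general transcription machinery this
geometry is stereotyped: TBP and TFIIB crosslink ~20 bp upstream of the
mRNA TSS (TFIIB contacting DNA just downstream of TATA-bound TBP), paused
Pol II sits ~50 bp downstream, and at Pol III-transcribed tRNA genes TBP
(within TFIIIB) crosslinks ~21 bp upstream of the TSS.

`exopair` implements the complete analysis around this model: peak calling
per strand, peak pairing, filtering, TSS/CpG-island/segment annotation,
composite profiling, inter-complex statistics, and cross-sample
clustering, plus a synthetic-data generator that plants all of the above
with known ground truth.

## Peak calling

Each tag contributes an un-normalized Gaussian kernel
$\exp(-(p-t)^2/2\sigma^2)$ with $\sigma = 20$ bp, truncated at $4\sigma$;
the per-bp sum over tags is the smoothed density. Candidate summits are
strict local maxima; plateaus resolve to their leftmost position so calls
are deterministic. Candidates are retained greedily in descending height
(ties leftmost), discarding any candidate whose summit lies within
less than the 40-bp exclusion zone (center-to-center, applied per strand)
of an already retained summit. Two consequences matter downstream:

* **Resolution bound.** Two binding locations closer than ~40 bp cannot be
  reported separately — below $2\sigma$ the kernel sum is already unimodal,
  and between $2\sigma$ and the exclusion zone the greedy rule suppresses
  the smaller maximum. The test suite asserts both regimes explicitly.
* **Exactness.** Because the kernel is truncated by definition, evaluating
  the density only within $4\sigma$ of some tag is exact, not an
  approximation; the greedy caller is verified equal to an exhaustive
  brute-force implementation on hundreds of random instances.

Each retained peak's `tag_count` is the number of raw tags within half the
exclusion zone (±20 bp) of the summit. The exclusion zone makes that
window unambiguous; it is the quantity thresholded later.

The kernel is deliberately not normalized into a KDE: only the argmax
structure matters for calling, and un-normalized heights remain comparable
within a dataset.

## Pairing, filtering, annotation

A W peak at $w$ pairs with a C peak at $c$ iff $0 \le c - w \le 80$ bp
(the C border must lie in the 3' direction on the forward strand — exo
borders flank the footprint). Each peak joins at most one pair; conflicts
resolve by smallest span, then larger combined tag count, then leftmost W
summit. Smallest-span-first favors tight footprints; the alternatives
differ only on pathological overlaps, and the pairing is tested against an
iterative assignment oracle. The pair's midpoint is the floor of the
summit mean; its occupancy is the sum of the two peak tag counts (a
convention — the source analyses never define pair occupancy).

Pairs with a midpoint inside a blacklist interval are removed (half-open
membership), then the low-occupancy threshold keeps pairs with
occupancy strictly greater than 4. Surviving locations are assigned to the
nearest TSS within 500 bp (unsigned distance; ties to the smaller
coordinate); the nearest TSS of a multi-TSS gene is that location's
primary TSS. Signed offsets are strand-oriented — negative means upstream
in the gene's direction — so a TFIIB location 20 bp upstream reads as −20
for genes on either strand, and mirroring the whole genome leaves offsets
invariant (tested).

## Composite profiles and Input normalization

Signal (tags or pair midpoints) is accumulated gene-by-gene in
non-overlapping 10-bp bins over ±500 bp of the TSS (±200 bp for tRNA
genes), strand-oriented, with tag strand re-expressed relative to the gene
(sense/antisense). ChIP and Input bins are converted to RPKM
(count / (bin kb × total mapped tags in millions); the denominator is the
dataset's total over both strands) and divided bin-wise; Input-empty bins
are marked missing rather than infinite and excluded from composites.
Composites are per-bin means over genes scaled to sum to 100 (percent of
total), the scaling applied after averaging. Row orders for heatmap-style
matrices are stable permutations by a per-gene key (inter-complex
distance, island length, occupancy) that can be applied "linked" across
factors.

## Statistics

Adjacent complexes within a group (e.g. a CpG island) yield inter-location
distances with flanking occupancies. Variability along the distance axis
uses a centered sliding window of 30 consecutive records (sample SD,
n−1), plotted against the window's median distance; coordinately occupied
close-spaced complexes show up as a low-SD short-distance regime, with
per-stratum Pearson correlations reported alongside rather than a
hard-coded regime boundary (the boundary is an empirical observation, not
a parameter). Gene-level comparisons (occupancy vs mRNA) use a
log2(v+1) pseudocount transform median-centered over the genes entering
the analysis, a 100-gene moving average after sorting by the x series, and
pairwise Pearson correlations excluding genes with zero in either series
(zero means "not measured/detected", not low).

## Multi-sample clustering

The gene × sample occupancy matrix sums assigned pair occupancies per gene
(zero = not detected). Normalization is per column: log2(v+1) over
detected entries, centered on their mean; zeros stay NA so "absent" never
masquerades as "low". Genes detected in every sample form Group 1; the
remainder is partitioned by k-means (k = 3, giving Groups 2–4) on the
normalized rows with not-detected cells imputed one log2 unit below the
column minimum — keeping absence ordinally below any observation without
dropping genes. This imputation is the analysis's main free choice (the
source procedure is not stated) and is isolated in one function.
Initialization is k-means++ with 100 restarts under a fixed seed; labels
are renumbered by descending cluster mean and rows ordered by cross-sample
mean within groups. Samples are clustered hierarchically with
1 − Pearson r distance over co-detected genes and average linkage
(serialized as Newick); distance and linkage are conventions — the
reference analysis does not state its choices — and are confined to
`cluster_samples()`.

## The synthetic genome

`sim_config()` defines the study conditions; the defaults are fixed once
and the tests run against them:

| parameter | default | rationale |
|---|---|---|
| factor offsets | TFIIB −20, TBP −20, Pol II +50, TBP at tRNA −21 bp | canonical PIC geometry above |
| divergent offset | 250 ± 40 bp upstream, opposite strand | divergent TSS spacing at mammalian promoters |
| divergent fraction | 0.5 | divergent initiation is common but not universal |
| border half-width | 15 ± 3 bp (truncated ≥ 5), one draw per site | exo footprints ~30 bp; shared by both borders so spans stay symmetric |
| tags per site | NB(mean 50, size 3) per strand | overdispersed occupancy with realistic dynamic range |
| tag jitter | SD 1 bp, rounded | the source analyses do not describe tag noise; small symmetric jitter is this package's choice |
| background | 1 tag/kb/strand (Input 2) | sparse uniform noise floor |
| CpG islands | half-width 400 bp, center +100 bp downstream of the TSS | islands should contain the 1–3 complexes of a promoter, including the divergent one ~230 bp upstream |
| secondary RNA share | 0.24 | divergent transcripts' share of total TSS RNA signal; implemented as a scale of f/(1−f) on divergent RNA so the *share of the total* equals f in expectation |
| gene spacing | ≥ 2 kb | makes TSS assignment unambiguous by construction |

TSSs are placed uniformly under the spacing constraint (a configuration
that cannot satisfy it is rejected); all coordinates are 0-based; a fixed
seed makes every generator bit-identical across calls. The generator also
plants a blacklist (decoys plus one interval deliberately covering a
planted site, so filtering is exercised), a
promoter/transcription/heterochromatin segmentation, per-sample
occupancies (a configurable fraction of genes detected only in a random
proper subset of samples), and mRNA levels with Gaussian log2 noise.

What the generator does *not* emulate — and what green tests therefore do
not certify about real data: PCR duplicates and amplification artifacts,
sequence-dependent exonuclease stalling, mappability gaps, copy-number
variation, overlapping or nested genes, multi-TSS genes, and any
correlation structure between background and open chromatin. Results on
real libraries depend on those factors; results here certify the
*algorithms*, not the biology.

## Numerical conventions and degenerate inputs

* Coordinates 0-based, intervals half-open `[start, end)` everywhere; SAM's
  1-based positions converted on ingest; the 5' end of a minus-strand read
  is its rightmost aligned base.
* Plateau summits and all sort-based tie-breaks resolve leftmost/smallest
  so every stage is deterministic; modal offsets break ties to the
  smallest absolute offset.
* Empty strands, empty interval sets, missing islands and sub-3-element
  correlation strata return empty/NA results, never 0-for-undefined.
* Overlapping annotation intervals resolve first-in-file-order.
* Problem sizes in the test suite (up to ~1,200 planted sites on a few Mb,
  200-instance oracle sweeps) were chosen so the full suite exercises every
  stage genome-wide in a few minutes on one core.

## Known limitations

* The exclusion-zone semantics (center-to-center < 40 bp excludes) is the
  standard reading of the GeneTrack procedure; its exact unpublished tie
  rules may differ in corner cases, which the oracle tests pin to this
  package's documented convention rather than to GeneTrack's binary.
* Location matching between datasets compares midpoints, not feature
  overlap.
* The multi-sample stage consumes per-sample assignments; it does not
  build consensus locations across samples beyond window matching.
* RPKM normalization uses total dataset tags as the "million mapped"
  denominator; with very small synthetic datasets, Input-normalized traces
  are noisier than percent-of-total traces and composite bins with no
  Input coverage are dropped.
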