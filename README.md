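# exopair

Base-pair-resolution mapping of transcription pre-initiation complexes
(PICs) from ChIP-exo data, as an R package plus a worked analysis.

## The problem

ChIP-exo trims immunoprecipitated DNA with lambda exonuclease to within a
few bp of the protein–DNA crosslink, leaving strand-specific 5' "borders":
forward-strand (W) read starts accumulate at the left edge of the protected
footprint, reverse-strand (C) starts at the right edge. A bound location is
therefore a *peak-pair* — a W summit and a C summit a short distance apart —
whose midpoint estimates the crosslink point. At this resolution the
architecture of the general transcription machinery becomes measurable:
TBP/TFIIB crosslink ~20 bp upstream of the mRNA TSS, paused Pol II ~50 bp
downstream, divergent antisense initiation arises from physically distinct
complexes ~250 bp upstream on the opposite strand, promoter CpG islands
hold 1–3 complexes each, and at Pol III tRNA genes TBP sits ~21 bp upstream
of the TSS.

`exopair` is for genomicists who want this entire analysis as tested,
reusable functions: strand-separated peak calling (Gaussian smoothing,
σ = 20 bp, truncated at 4σ; greedy local-maximum selection under a 40-bp
exclusion zone), pairing under the 0–80 bp 3'-direction rule, blacklist and
occupancy (> 4 tags) filtering, nearest-TSS assignment within 500 bp with
strand-oriented offsets, CpG-island and genome-segment annotation,
TSS-aligned composites with per-bin RPKM Input normalization, inter-complex
distance/occupancy statistics, and cross-sample occupancy clustering
(detection Group 1, k-means++ Groups 2–4, sample dendrogram). A synthetic
ChIP-exo generator with planted ground truth makes every stage verifiable
end-to-end without external sequencing data.

The smoothed density on one strand is

    D(p) = Σ_tags exp(−(p − t)² / 2σ²),   |p − t| ≤ 4σ

peaks are its strict local maxima retained greedily under the exclusion
zone, and W@w pairs with C@c iff 0 ≤ c − w ≤ 80, midpoint ⌊(w+c)/2⌋,
occupancy = summed border tag counts.

## Worked example

```r
library(exopair)

cfg <- sim_config(seed = 1)            # 60 mRNA + 20 tRNA genes, 2 x 1 Mb
ex  <- simulate_experiment(cfg)
ann <- ex$annotations

peaks <- call_peaks(ex$tags$TFIIB, sigma = 20, exclusion = 40)
pairs <- pair_peaks_genome(peaks, max_span = 80, sample = "TFIIB")$pairs
pairs <- filter_occupancy(filter_blacklist(pairs, ann$blacklist), 4)
asg   <- assign_to_tss(pairs, ann$tss_set, max_dist = 500)

table(asg$status)
#> assigned
#>       97
peak_pair_mode_offset(pairs, ann$tss_set)$mode
#> [1] -20
```

97 locations survive filtering and all lie within 500 bp of a planted TSS;
the modal strand-oriented offset −20 bp is the planted TFIIB crosslink
point just downstream of the TATA box. The numbered scripts under
`analysis/` run the same pipeline stage by stage on a written-to-disk
simulated study (`results/sim/`) and report, among others: the composite
peak-pair density argmax in bin [−20,−10) for TFIIB/TBP and [50,60) for
Pol II; TBP's modal offset −21 bp at tRNA genes; mean 1.45 complexes per
occupied CpG island with 100% of detected promoters in an island; and
Groups 1–4 of 31/6/9/14 genes across four pseudo-cell-lines:

```sh
Rscript analysis/01_simulate.R   # synthetic genome, tags, truth -> results/sim/
Rscript analysis/02_call_peaks.R
Rscript analysis/03_pair_and_annotate.R
Rscript analysis/04_profiles.R
Rscript analysis/05_stats.R
Rscript analysis/06_multisample.R
```

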