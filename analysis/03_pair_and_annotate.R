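#!/usr/bin/env Rscript
# Stage 3: peak pairing, filtering, and annotation.
#
# W/C peaks are paired under the 0-80 bp 3'-direction rule; pair midpoints
# estimate crosslink points. Pairs in blacklisted intervals are removed and
# the low-occupancy threshold (>4 tags) applied. Surviving locations are
# assigned to the nearest TSS within 500 bp (primary TSS per location),
# intersected with CpG islands, and classified by genome segment; per-gene
# detection sets give the TBP/TFIIB/RNA Venn decomposition.

suppressPackageStartupMessages(library(exopair))
suppressPackageStartupMessages(library(jsonlite))

sim <- "results/sim"
out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tss <- read_tss_table(file.path(sim, "tss.bed"))
islands <- read_intervals_bed(file.path(sim, "cpg_islands.bed"), "CpG")
blacklist <- read_intervals_bed(file.path(sim, "blacklist.bed"), "blacklist")
segments <- read_intervals_bed(file.path(sim, "segments.bed"))

assignments <- list()
for (f in c("TFIIB", "TBP", "PolII")) {
  peaks <- read.table(file.path("results/peaks",
                                paste0("peaks_", f, ".tsv")),
                      header = TRUE, sep = "\t")
  pp <- pair_peaks_genome(peaks, max_span = 80, sample = f)
  n0 <- nrow(pp$pairs)
  pairs <- filter_occupancy(filter_blacklist(pp$pairs, blacklist),
                            min_tags = 4)
  write_peak_pairs(pairs, file.path(out, paste0("pairs_", f, ".tsv")))
  asg <- assign_to_tss(pairs, tss, max_dist = 500)
  write.table(asg, file.path(out, paste0("assignments_", f, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  assignments[[f]] <- asg
  message(sprintf(
    "%s: %d raw pairs -> %d after blacklist+occupancy; %d TSS-assigned (%d genes), %d distal",
    f, n0, nrow(pairs), sum(asg$status == "assigned"),
    length(detected_genes(asg)), sum(asg$status == "distal")))
}

rna <- read.table(file.path(sim, "rna_levels.tsv"), header = TRUE,
                  sep = "\t")
venn <- detection_overlap(list(
  TFIIB = detected_genes(assignments$TFIIB),
  TBP = detected_genes(assignments$TBP),
  RNA = unique(rna$gene_id[rna$class == "primary" & rna$rna > 0])))
write_json(as.list(venn), file.path(out, "venn_counts.json"),
           auto_unbox = TRUE)
message("Venn (TFIIB/TBP/RNA): ",
        paste(names(venn), venn, sep = "=", collapse = ", "))

asg <- assignments$TFIIB
ov <- cpg_overlap(asg, islands, asg)
message(sprintf(
  "CpG islands: %d locations in %d occupied islands (mean %.2f/island); %.0f%% of detected promoters in an island",
  ov$n_locations_in_islands, ov$n_islands_occupied,
  ov$mean_per_occupied_island, 100 * ov$frac_genes_tss_in_island))

seg <- classify_segments(asg, segments)
write_json(list(cpg = ov[c("n_islands_occupied", "n_locations_in_islands",
                           "mean_per_occupied_island",
                           "frac_genes_tss_in_island",
                           "frac_genes_location_in_island")],
                segments = as.list(seg$fractions)),
           file.path(out, "overlap_summary.json"), auto_unbox = TRUE)
message("segment fractions: ",
        paste(names(seg$fractions), round(seg$fractions, 2),
              sep = "=", collapse = ", "))
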