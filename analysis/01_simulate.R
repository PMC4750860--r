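#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A miniature two-chromosome genome with 60 mRNA genes and 20 tRNA genes,
# pre-initiation complexes planted with the canonical geometry (TFIIB/TBP
# -20 bp, paused Pol II +50 bp, TBP -21 bp at tRNA genes; half the genes
# carry a divergent partner complex ~250 bp upstream on the opposite
# strand), ChIP-exo tag datasets per factor, an Input control, mRNA levels
# and per-sample occupancies. Everything is written under results/sim/ in
# plain text so later stages can run from files alone.

suppressPackageStartupMessages(library(exopair))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20160301)
write_sim_config(cfg, file.path(out, "config.yaml"))
ex <- simulate_experiment(cfg)
ann <- ex$annotations

for (f in names(ex$tags)) {
  write_tags_bed(ex$tags[[f]], file.path(out, paste0("tags_", f, ".bed")))
}
write_tags_bed(ex$input, file.path(out, "tags_Input.bed"))

write_bed6 <- function(df, tss, path) {
  bed <- data.frame(df$chrom, tss, tss + 1L, df$gene_id, 0L, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
write_bed6(ann$tss_set, ann$tss_set$tss, file.path(out, "tss.bed"))
write_bed6(ann$trna_set, ann$trna_set$tss, file.path(out, "trna_tss.bed"))
for (trk in c("cpg_islands", "blacklist", "segments")) {
  iv <- ann[[trk]]
  write.table(data.frame(iv$chrom, iv$start, iv$end, iv$label, 0L, "+"),
              file.path(out, paste0(trk, ".bed")), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
}
write.table(ann$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ex$rna, file.path(out, "rna_levels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = rownames(ex$sample_occupancy),
                       ex$sample_occupancy),
            file.path(out, "sample_occupancy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d mRNA + %d tRNA genes; %d planted sites; tags: %s",
  nrow(ann$tss_set), nrow(ann$trna_set), nrow(ann$truth),
  paste(sprintf("%s=%d", names(ex$tags),
                vapply(ex$tags, n_tags, integer(1))), collapse = ", ")))
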