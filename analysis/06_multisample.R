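#!/usr/bin/env Rscript
# Stage 6: cross-sample occupancy clustering.
#
# The per-sample gene occupancies (pseudo-cell-lines sharing a common
# occupancy program plus sample-specific detection) are normalized by
# column, split into Group 1 (detected in every sample) and a remainder
# partitioned into Groups 2-4 by seeded k-means++ (best of 100 restarts),
# and the samples themselves are clustered by 1 - Pearson distance with
# average linkage.

suppressPackageStartupMessages(library(exopair))

sim <- "results/sim"
out <- "results/multisample"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

occ_tab <- read.table(file.path(sim, "sample_occupancy.tsv"),
                      header = TRUE, sep = "\t")
m <- as.matrix(occ_tab[, -1])
rownames(m) <- occ_tab$gene_id
m <- m[rowSums(m > 0) > 0, , drop = FALSE]

norm <- normalize_columns(m)
write.table(data.frame(gene_id = rownames(norm), round(norm, 4)),
            file.path(out, "normalized_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

g <- group_by_detection(m)
km <- kmeans_groups(m[g$remainder, , drop = FALSE], k = 3,
                    seed = 20160301, restarts = 100)
groups <- data.frame(
  gene_id = c(g$group1, names(km$labels)),
  group = c(rep(1L, length(g$group1)), unname(km$labels)))
groups <- groups[order(groups$group, groups$gene_id), ]
write.table(groups, file.path(out, "gene_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("groups: %s",
                paste(sprintf("Group %s = %d genes",
                              names(table(groups$group)),
                              table(groups$group)), collapse = ", ")))

cs <- cluster_samples(m)
writeLines(cs$newick, file.path(out, "sample_dendrogram.nwk"))
message("sample dendrogram (Newick): ", cs$newick)
message("leaf order: ", paste(cs$leaf_order, collapse = ", "))
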