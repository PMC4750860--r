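test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 10, n_trna = 4, seed = 1)
  a <- generate_annotations(cfg)
  b <- generate_annotations(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$tss_set), 10)
  expect_equal(nrow(a$cpg_islands), 10)
  t1 <- simulate_exo_tags(a$truth, cfg)
  t2 <- simulate_exo_tags(a$truth, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(as.data.frame(simulate_input_tags(cfg)),
                   as.data.frame(simulate_input_tags(cfg)))
  # a different seed moves the genes
  c2 <- generate_annotations(sim_config(n_genes = 10, n_trna = 4, seed = 2))
  expect_false(identical(a$tss_set$tss, c2$tss_set$tss))
})

test_that("planted TSSs keep their minimum spacing or the config is rejected", {
  cfg <- sim_config(n_genes = 200, n_trna = 50, n_chroms = 1,
                    chrom_length = 1e6, seed = 5)
  ann <- generate_annotations(cfg)
  all_tss <- sort(c(ann$tss_set$tss, ann$trna_set$tss))
  expect_true(all(diff(all_tss) >= cfg$min_gene_gap))
  expect_error(generate_annotations(
    sim_config(n_genes = 600, n_chroms = 1, chrom_length = 1e6)),
    "overlapping genes")
})

test_that("divergent partners obey the configured fraction and offset", {
  cfg <- sim_config(n_genes = 1000, n_trna = 0, n_chroms = 2,
                    chrom_length = 2e6, divergent_fraction = 1,
                    divergent_offset_mean = 250, divergent_offset_sd = 40,
                    seed = 9)
  ann <- generate_annotations(cfg)
  tf <- ann$truth[ann$truth$factor == "TFIIB", ]
  expect_equal(sum(tf$class == "divergent"), 1000)
  # divergent complexes sit on the opposite strand of their gene's TSS
  prim <- tf[tf$class == "primary", ]
  div <- tf[tf$class == "divergent", ]
  div <- div[match(prim$gene_id, div$gene_id), ]
  expect_true(all(prim$strand != div$strand))
  # signed primary-TSS -> divergent-TSS distance recovers the planted mean
  tss_dist <- abs(prim$pos - div$pos) + 2 * abs(cfg$factor_offsets[["TFIIB"]])
  sem <- sd(tss_dist) / sqrt(length(tss_dist))
  expect_lt(abs(mean(tss_dist) - 250), 2 * sem + 1)
  # divergent_fraction = 0 plants none
  none <- generate_annotations(sim_config(n_genes = 50,
                                          divergent_fraction = 0))
  expect_false(any(none$truth$class == "divergent"))
})

test_that("factor sites are planted at their configured offsets", {
  cfg <- sim_config(n_genes = 50, n_trna = 20, divergent_fraction = 0,
                    seed = 3)
  ann <- generate_annotations(cfg)
  t <- ann$truth
  tss_of <- setNames(ann$tss_set$tss, ann$tss_set$gene_id)
  str_of <- setNames(ann$tss_set$strand, ann$tss_set$gene_id)
  for (f in c("TFIIB", "TBP", "PolII")) {
    rows <- t[t$factor == f & t$class == "primary", ]
    off <- ifelse(str_of[rows$gene_id] == "+",
                  rows$pos - tss_of[rows$gene_id],
                  tss_of[rows$gene_id] - rows$pos)
    expect_true(all(off == cfg$factor_offsets[[f]]), info = f)
  }
  trna_of <- setNames(ann$trna_set$tss, ann$trna_set$gene_id)
  trna_str <- setNames(ann$trna_set$strand, ann$trna_set$gene_id)
  rows <- t[t$class == "tRNA", ]
  off <- ifelse(trna_str[rows$gene_id] == "+",
                rows$pos - trna_of[rows$gene_id],
                trna_of[rows$gene_id] - rows$pos)
  expect_true(all(off == -21))
  # CpG island centers are ~100 bp downstream of the primary TSS
  centers <- (ann$cpg_islands$start + ann$cpg_islands$end) / 2
  tssv <- ann$tss_set$tss
  downstream <- ifelse(ann$tss_set$strand == "+", centers - tssv,
                       tssv - centers)
  expect_true(all(downstream == 100))
})

test_that("noise-free sites emit tags exactly at the planted borders", {
  cfg <- sim_config(n_genes = 1, n_trna = 0, tag_jitter_sd = 0,
                    background_rate = 0, divergent_fraction = 0)
  truth <- data.frame(factor = "TFIIB", chrom = "chr1", pos = 5000L,
                      strand = "+", gene_id = "g1", class = "primary",
                      occupancy = 10L, halfwidth = 15L)
  tags <- simulate_exo_tags(truth, cfg)
  expect_equal(unique(tags$pos[tags$strand == "W"]), 4985)
  expect_equal(unique(tags$pos[tags$strand == "C"]), 5015)
  expect_equal(n_tags(tags, "W"), 10)
  expect_equal(n_tags(tags, "C"), 10)
  # tag-count conservation: site tags + background tags
  cfg_bg <- sim_config(n_genes = 1, background_rate = 1, tag_jitter_sd = 0)
  tags_bg <- simulate_exo_tags(truth, cfg_bg, seed = 42)
  expect_gte(n_tags(tags_bg), 20)
  # W and C modes bracket the midpoint symmetrically
  wmode <- as.integer(names(which.max(tapply(
    tags_bg$count[tags_bg$strand == "W"],
    tags_bg$pos[tags_bg$strand == "W"], sum))))
  cmode <- as.integer(names(which.max(tapply(
    tags_bg$count[tags_bg$strand == "C"],
    tags_bg$pos[tags_bg$strand == "C"], sum))))
  expect_equal((wmode + cmode) / 2, 5000)
})

test_that("background and Input rates follow their Poisson means", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e6, n_genes = 1,
                    background_rate = 1, input_rate = 2)
  truth <- data.frame(factor = "TFIIB", chrom = "chr1", pos = 5e5L,
                      strand = "+", gene_id = "g", class = "primary",
                      occupancy = 0L, halfwidth = 15L)
  tags <- simulate_exo_tags(truth, cfg, seed = 11)
  for (s in c("W", "C")) {
    expect_lt(abs(n_tags(tags, s) - 1000), 3 * sqrt(1000))
  }
  inp <- simulate_input_tags(cfg, seed = 12)
  for (s in c("W", "C")) {
    expect_lt(abs(n_tags(inp, s) - 2000), 3 * sqrt(2000))
  }
  # zero rate gives an empty dataset
  cfg0 <- sim_config(input_rate = 0)
  expect_equal(n_tags(simulate_input_tags(cfg0)), 0)
})

test_that("divergent RNA contributes the configured share of total signal", {
  cfg <- sim_config(n_genes = 2000, n_trna = 0, n_chroms = 4,
                    chrom_length = 2e6, divergent_fraction = 1,
                    rna_noise_sd = 0, secondary_signal_fraction = 0.24,
                    seed = 6)
  ann <- generate_annotations(cfg)
  rna <- simulate_rna_levels(ann$truth[ann$truth$factor == "TFIIB", ], cfg)
  share <- sum(rna$rna[rna$class == "divergent"]) / sum(rna$rna)
  expect_equal(share, 0.24, tolerance = 0.03)
  # zero noise: RNA is a deterministic function of occupancy
  prim <- rna[rna$class == "primary", ]
  expect_equal(cor(log2(prim$rna), log2(prim$occupancy)), 1)
})

test_that("per-sample occupancies mix shared and sample-specific genes", {
  cfg <- sim_config(n_genes = 500, n_chroms = 2, chrom_length = 1e6,
                    n_samples = 4, sample_specific_fraction = 0.4, seed = 2)
  ann <- generate_annotations(cfg)
  occ <- simulate_sample_occupancies(
    ann$truth[ann$truth$factor == "TFIIB", ], cfg)
  expect_equal(dim(occ), c(500, 4))
  detected_everywhere <- mean(rowSums(occ > 0) == 4)
  # shared fraction ~ 0.6; binomial SE ~ 0.022
  expect_lt(abs(detected_everywhere - 0.6), 0.07)
  # sample-specific genes are detected in a non-empty proper subset
  partial <- occ[rowSums(occ > 0) < 4, , drop = FALSE]
  expect_true(all(rowSums(partial > 0) >= 1))
})
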