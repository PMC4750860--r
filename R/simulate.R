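#' Configuration for the synthetic ChIP-exo genome
#'
#' Defines a miniature genome with well-separated mRNA and tRNA genes and
#' the crosslinking geometry of the pre-initiation complex: TFIIB and TBP
#' crosslink ~20 bp upstream of the mRNA TSS, paused Pol II ~50 bp
#' downstream, and TBP ~21 bp upstream of tRNA TSSs. A configurable
#' fraction of genes carries a divergent partner complex on the opposite
#' strand, centered ~250 bp upstream of the primary TSS; each promoter sits
#' in a CpG island whose center lies ~100 bp downstream of the TSS.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total mRNA genes (spread round-robin over chromosomes).
#' @param n_trna total tRNA genes.
#' @param divergent_fraction probability a gene has a divergent partner
#'   initiation complex.
#' @param divergent_offset_mean,divergent_offset_sd distance (bp) from the
#'   primary TSS to the divergent TSS, upstream on the opposite strand.
#' @param factor_offsets named bp offsets of each factor's crosslink point
#'   relative to the TSS (negative = upstream in the gene's direction).
#' @param border_halfwidth_mean,border_halfwidth_sd exonuclease footprint
#'   half-width in bp, drawn per site (truncated normal, minimum 5), shared
#'   by the two strands of a site so the pair span stays symmetric.
#' @param tags_per_site_mean mean planted tags per site per strand
#'   (negative binomial).
#' @param tags_dispersion negative binomial size parameter (overdispersion
#'   of occupancy across sites).
#' @param tag_jitter_sd SD (bp) of the rounding jitter added to each tag
#'   5' end around its border.
#' @param background_rate uniform background, tags per kb per strand.
#' @param input_rate Input (control) dataset rate, tags per kb per strand.
#' @param cpg_island_halfwidth island half-width in bp.
#' @param n_samples number of pseudo-cell-line samples.
#' @param sample_specific_fraction fraction of genes whose occupancy is
#'   sample-specific (absent from a random subset of samples) rather than
#'   shared across all samples.
#' @param rna_noise_sd SD (log2 units) of the mRNA-level noise around
#'   planted occupancy.
#' @param secondary_signal_fraction fraction of total TSS RNA signal
#'   contributed by divergent (secondary) TSSs.
#' @param min_gene_gap minimum spacing between planted TSSs in bp (keeps
#'   TSS assignment unambiguous by construction).
#' @param seed RNG seed; a fixed seed makes every generator output
#'   bit-identical across calls.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 1e6,
                       n_genes = 60,
                       n_trna = 20,
                       divergent_fraction = 0.5,
                       divergent_offset_mean = 250,
                       divergent_offset_sd = 40,
                       factor_offsets = c(TFIIB = -20, TBP = -20,
                                          PolII = 50, TBP_tRNA = -21),
                       border_halfwidth_mean = 15,
                       border_halfwidth_sd = 3,
                       tags_per_site_mean = 50,
                       tags_dispersion = 3,
                       tag_jitter_sd = 1,
                       background_rate = 1,
                       input_rate = 2,
                       cpg_island_halfwidth = 400,
                       n_samples = 4,
                       sample_specific_fraction = 0.4,
                       rna_noise_sd = 0.5,
                       secondary_signal_fraction = 0.24,
                       min_gene_gap = 2000,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes >= 1,
            cfg$n_trna >= 0,
            cfg$divergent_fraction >= 0, cfg$divergent_fraction <= 1,
            cfg$divergent_offset_mean > 0, cfg$divergent_offset_sd >= 0,
            cfg$border_halfwidth_mean > 0, cfg$tags_per_site_mean > 0,
            cfg$tags_dispersion > 0, cfg$background_rate >= 0,
            cfg$input_rate >= 0, cfg$cpg_island_halfwidth > 0,
            cfg$n_samples >= 1,
            cfg$sample_specific_fraction >= 0,
            cfg$sample_specific_fraction <= 1,
            cfg$rna_noise_sd >= 0,
            cfg$secondary_signal_fraction >= 0,
            cfg$secondary_signal_fraction < 1,
            cfg$min_gene_gap > 0,
            is.numeric(cfg$seed))
  stopifnot(all(c("TFIIB", "TBP", "PolII", "TBP_tRNA") %in%
                  names(cfg$factor_offsets)))
  structure(cfg, class = "sim_config")
}

#' Write / read a simulation config as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file.
#' @return `read_sim_config` returns the round-tripped [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$factor_offsets <- unlist(lst$factor_offsets)
  do.call(sim_config, lst)
}

#' Generate the synthetic genome annotation and planted ground truth
#'
#' Places mRNA and tRNA TSSs at least `min_gene_gap` apart on random
#' strands; plants, for every TSS (primary and divergent), one crosslink
#' site per factor at its configured offset; draws each site's planted
#' occupancy (negative binomial) and exo border half-width (truncated
#' normal, min 5 bp); and builds the companion annotation tracks: CpG
#' islands centered ~100 bp downstream of each primary TSS, a blacklist
#' (intergenic decoys plus one interval deliberately covering the first
#' gene's TFIIB site, for filter tests), and a promoter / transcription /
#' heterochromatin segmentation of each chromosome.
#'
#' @param config a [sim_config()].
#' @return List: `tss_set`, `trna_set` (TSS tables), `cpg_islands`,
#'   `blacklist`, `segments` ([interval_set()]s), and `truth` — one row per
#'   planted site with `factor`, `chrom`, `pos` (true crosslink midpoint),
#'   `strand` (of the associated TSS), `occupancy` (planted tags per strand),
#'   `halfwidth`, `gene_id`, `class` ("primary"/"divergent"/"tRNA").
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per_chrom <- table(rep(seq_len(config$n_chroms),
                           length.out = config$n_genes + config$n_trna))
  margin <- 5000
  gap <- config$min_gene_gap
  placements <- lapply(seq_len(config$n_chroms), function(ci) {
    k <- if (ci <= length(n_per_chrom)) as.integer(n_per_chrom[ci]) else 0L
    if (k == 0) return(integer(0))
    usable <- config$chrom_length - 2 * margin - (k - 1) * gap
    if (usable <= 0) {
      stop("config implies overlapping genes: ", k, " TSSs with gap ", gap,
           " bp do not fit on a ", config$chrom_length, " bp chromosome")
    }
    slack <- sort(runif(k, 0, usable))
    as.integer(round(margin + slack + (seq_len(k) - 1) * gap))
  })
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  all_tss <- data.frame(
    chrom = rep(chrom_names, lengths(placements)),
    tss = unlist(placements))
  all_tss <- all_tss[sample.int(nrow(all_tss)), , drop = FALSE]
  is_trna <- c(rep(FALSE, config$n_genes), rep(TRUE, config$n_trna))
  all_tss$strand <- sample(c("+", "-"), nrow(all_tss), replace = TRUE)
  mrna <- all_tss[!is_trna, , drop = FALSE]
  trna <- all_tss[is_trna, , drop = FALSE]
  mrna$gene_id <- sprintf("gene%03d", seq_len(nrow(mrna)))
  trna$gene_id <- if (nrow(trna) > 0) {
    sprintf("trna%03d", seq_len(nrow(trna)))
  } else character(0)

  tss_set <- mrna[, c("gene_id", "chrom", "strand", "tss")]
  trna_set <- trna[, c("gene_id", "chrom", "strand", "tss")]

  # divergent partner TSSs: opposite strand, upstream of the primary TSS
  has_div <- runif(nrow(mrna)) < config$divergent_fraction
  div_off <- pmax(50, round(rnorm(nrow(mrna), config$divergent_offset_mean,
                                  config$divergent_offset_sd)))
  div_tss <- ifelse(mrna$strand == "+", mrna$tss - div_off,
                    mrna$tss + div_off)
  div_strand <- ifelse(mrna$strand == "+", "-", "+")

  site_rows <- list()
  plant <- function(factor, chrom, tss, strand, gene_id, class, offset) {
    pos <- ifelse(strand == "+", tss + offset, tss - offset)
    data.frame(factor = factor, chrom = chrom, pos = as.integer(pos),
               strand = strand, gene_id = gene_id, class = class)
  }
  offs <- config$factor_offsets
  for (f in c("TFIIB", "TBP", "PolII")) {
    site_rows[[length(site_rows) + 1]] <-
      plant(f, mrna$chrom, mrna$tss, mrna$strand, mrna$gene_id,
            "primary", offs[[f]])
    if (any(has_div)) {
      site_rows[[length(site_rows) + 1]] <-
        plant(f, mrna$chrom[has_div], div_tss[has_div],
              div_strand[has_div], mrna$gene_id[has_div],
              "divergent", offs[[f]])
    }
  }
  if (nrow(trna) > 0) {
    site_rows[[length(site_rows) + 1]] <-
      plant("TBP", trna$chrom, trna$tss, trna$strand, trna$gene_id,
            "tRNA", offs[["TBP_tRNA"]])
  }
  truth <- do.call(rbind, site_rows)
  truth$occupancy <- pmax(1L, stats::rnbinom(nrow(truth),
                                             mu = config$tags_per_site_mean,
                                             size = config$tags_dispersion))
  truth$halfwidth <- pmax(5L, as.integer(round(
    stats::rnorm(nrow(truth), config$border_halfwidth_mean,
                 config$border_halfwidth_sd))))
  # one footprint half-width and occupancy per complex, shared by both
  # borders, so the planted pair span is symmetric around pos
  rownames(truth) <- NULL

  # CpG islands: center ~100 bp downstream of the primary TSS
  center <- ifelse(mrna$strand == "+", mrna$tss + 100, mrna$tss - 100)
  hw <- config$cpg_island_halfwidth
  cpg_islands <- interval_set(mrna$chrom, pmax(0L, center - hw),
                              center + hw, "CpG")

  # blacklist: decoys in gene-free space plus one interval covering the
  # first gene's TFIIB primary site so filtering is exercised
  first <- truth[truth$factor == "TFIIB" & truth$class == "primary", ][1, ]
  bl_chrom <- c(chrom_names, first$chrom)
  bl_start <- c(rep(100L, config$n_chroms), first$pos - 50L)
  bl_end <- c(rep(600L, config$n_chroms), first$pos + 50L)
  blacklist <- interval_set(bl_chrom, bl_start, bl_end, "blacklist")

  segments <- build_segments(mrna, trna, chrom_names, config$chrom_length)

  list(tss_set = tss_set, trna_set = trna_set, cpg_islands = cpg_islands,
       blacklist = blacklist, segments = segments, truth = truth)
}

# promoter = TSS +/- 1 kb; transcription = 1-5 kb downstream (oriented);
# remainder of the chromosome = heterochromatin
build_segments <- function(mrna, trna, chrom_names, chrom_length) {
  tss_all <- rbind(mrna[, c("chrom", "tss", "strand")],
                   trna[, c("chrom", "tss", "strand")])
  prom <- data.frame(chrom = tss_all$chrom,
                     start = pmax(0, tss_all$tss - 1000),
                     end = pmin(chrom_length, tss_all$tss + 1000),
                     label = "promoter")
  tx <- data.frame(
    chrom = tss_all$chrom,
    start = ifelse(tss_all$strand == "+", tss_all$tss + 1000,
                   pmax(0, tss_all$tss - 5000)),
    end = ifelse(tss_all$strand == "+",
                 pmin(chrom_length, tss_all$tss + 5000),
                 tss_all$tss - 1000),
    label = "transcription")
  het <- data.frame(chrom = chrom_names, start = 0, end = chrom_length,
                    label = "heterochromatin")
  # promoter listed first, then transcription, then the whole-chromosome
  # heterochromatin catch-all: interval_lookup's first-wins rule makes this
  # an effective partition
  all <- rbind(prom, tx, het)
  interval_set(all$chrom, all$start, all$end, all$label)
}

#' Simulate ChIP-exo tags for planted sites
#'
#' For each site with crosslink midpoint x and half-width b, `occupancy`
#' forward-strand 5' ends are emitted near x - b and the same number of
#' reverse-strand 5' ends near x + b (the two exonuclease borders), each
#' with rounded Gaussian jitter of SD `tag_jitter_sd`; a uniform Poisson
#' background (`background_rate` per kb per strand) is added over every
#' chromosome carrying at least one site.
#'
#' @param truth ground-truth site table (rows of
#'   `generate_annotations()$truth`, typically one factor's).
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed + 1`); fix it to make the
#'   dataset reproducible, vary it across factors/replicates.
#' @param sample sample label for the dataset.
#' @return A [tag_dataset()].
#' @export
simulate_exo_tags <- function(truth, config, seed = config$seed + 1,
                              sample = NA_character_) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  set.seed(seed)
  per_site <- lapply(seq_len(nrow(truth)), function(i) {
    n <- truth$occupancy[i]
    if (n == 0) return(NULL)
    b <- truth$halfwidth[i]
    jit_w <- as.integer(round(stats::rnorm(n, 0, config$tag_jitter_sd)))
    jit_c <- as.integer(round(stats::rnorm(n, 0, config$tag_jitter_sd)))
    list(chrom = rep(truth$chrom[i], 2 * n),
         strand = c(rep("W", n), rep("C", n)),
         pos = c(truth$pos[i] - b + jit_w, truth$pos[i] + b + jit_c))
  })
  per_site <- per_site[!vapply(per_site, is.null, logical(1))]
  chrom <- unlist(lapply(per_site, `[[`, "chrom"))
  strand <- unlist(lapply(per_site, `[[`, "strand"))
  pos <- unlist(lapply(per_site, `[[`, "pos"))
  chroms <- unique(truth$chrom)
  bg <- uniform_background(chroms, config$chrom_length,
                           config$background_rate)
  tag_dataset(c(chrom, bg$chrom), c(strand, bg$strand),
              pmax(c(pos, bg$pos), 0L), sample = sample)
}

uniform_background <- function(chroms, chrom_length, rate_per_kb) {
  chrom <- character(0); strand <- character(0); pos <- integer(0)
  if (rate_per_kb > 0) {
    lambda <- rate_per_kb * chrom_length / 1000
    for (ch in chroms) {
      for (s in c("W", "C")) {
        n <- stats::rpois(1, lambda)
        if (n == 0) next
        chrom <- c(chrom, rep(ch, n))
        strand <- c(strand, rep(s, n))
        pos <- c(pos, as.integer(floor(stats::runif(n, 0, chrom_length))))
      }
    }
  }
  list(chrom = chrom, strand = strand, pos = pos)
}

#' Simulate an Input (control) tag dataset
#'
#' Uniform background tags on both strands of every chromosome at
#' `config$input_rate` tags per kb per strand.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed + 2`).
#' @param sample sample label.
#' @return A [tag_dataset()].
#' @export
simulate_input_tags <- function(config, seed = config$seed + 2,
                                sample = "Input") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  bg <- uniform_background(chroms, config$chrom_length, config$input_rate)
  tag_dataset(bg$chrom, bg$strand, bg$pos, sample = sample)
}

#' Simulate mRNA levels from planted occupancy
#'
#' For each transcript (primary mRNA, and the divergent antisense partner
#' where present), log2 RNA = log2 planted occupancy + Gaussian noise
#' (`rna_noise_sd`). Divergent transcripts are down-scaled so that, in
#' expectation, they contribute `secondary_signal_fraction` of the total
#' TSS RNA signal (scale factor f/(1-f) relative to primary-occupancy
#' scale, mirroring the low abundance of antisense RNA relative to the
#' occupancy of its initiation complex).
#'
#' @param truth ground-truth table restricted to one factor (occupancy per
#'   TSS is taken from these rows; pass e.g. the TFIIB rows).
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed + 3`).
#' @return Data frame `gene_id`, `class`, `occupancy`, `rna` (linear scale).
#' @export
simulate_rna_levels <- function(truth, config, seed = config$seed + 3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  t <- truth[truth$class %in% c("primary", "divergent"), , drop = FALSE]
  f <- config$secondary_signal_fraction
  scale <- ifelse(t$class == "divergent", f / (1 - f), 1)
  log2rna <- log2(scale * t$occupancy) +
    stats::rnorm(nrow(t), 0, config$rna_noise_sd)
  data.frame(gene_id = t$gene_id, class = t$class,
             occupancy = t$occupancy, rna = 2^log2rna)
}

#' Simulate planted per-sample gene occupancies
#'
#' Gene-level occupancy across `n_samples` pseudo-cell-lines: a
#' `sample_specific_fraction` of genes is detected only in a random
#' non-empty proper subset of samples; the rest are shared across all
#' samples. Detected occupancies are the gene's base occupancy times
#' per-sample lognormal noise (SD 0.25 log2 units).
#'
#' @param truth ground-truth table restricted to one factor's primary
#'   sites (one row per gene).
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed + 4`).
#' @return Numeric gene-by-sample matrix (0 = not detected).
#' @export
simulate_sample_occupancies <- function(truth, config,
                                        seed = config$seed + 4) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  t <- truth[truth$class == "primary", , drop = FALSE]
  t <- t[!duplicated(t$gene_id), , drop = FALSE]
  ns <- config$n_samples
  m <- matrix(0, nrow(t), ns,
              dimnames = list(t$gene_id, paste0("sample", seq_len(ns))))
  specific <- runif(nrow(t)) < config$sample_specific_fraction
  for (i in seq_len(nrow(t))) {
    present <- if (specific[i] && ns > 1) {
      k <- sample.int(ns - 1, 1)
      seq_len(ns) %in% sample.int(ns, k)
    } else rep(TRUE, ns)
    noise <- 2^stats::rnorm(ns, 0, 0.25)
    m[i, present] <- t$occupancy[i] * noise[present]
  }
  m
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: annotations + ground truth, one ChIP-exo tag
#' dataset per factor (TFIIB/TBP/PolII at mRNA promoters, TBP at tRNA
#' genes), an Input dataset, mRNA levels, and per-sample occupancies.
#'
#' @param config a [sim_config()].
#' @return List with `annotations`, `tags` (named list per factor, the TBP
#'   dataset includes its tRNA sites), `input`, `rna`, `sample_occupancy`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  ann <- generate_annotations(config)
  factors <- c("TFIIB", "TBP", "PolII")
  tags <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    simulate_exo_tags(ann$truth[ann$truth$factor == f, , drop = FALSE],
                      config, seed = config$seed + 10 + i, sample = f)
  })
  names(tags) <- factors
  list(annotations = ann,
       tags = tags,
       input = simulate_input_tags(config),
       rna = simulate_rna_levels(
         ann$truth[ann$truth$factor == "TFIIB", , drop = FALSE], config),
       sample_occupancy = simulate_sample_occupancies(
         ann$truth[ann$truth$factor == "TFIIB", , drop = FALSE], config))
}
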