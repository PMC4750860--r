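#' Bin signal relative to TSSs into a gene-by-offset matrix
#'
#' Tags (or peak-pair midpoints) are aligned gene-by-gene to the TSS and
#' accumulated in non-overlapping bins of `bin` bp covering `[-window,
#' window)`. Offsets are strand-oriented: upstream of the TSS in the gene's
#' direction of transcription is negative, so profiles from + and - strand
#' genes superimpose. An offset of exactly 0 falls in bin `[0, bin)`. For a
#' [tag_dataset()] input, tag strand is re-expressed relative to the gene
#' ("same"/"opposite"), giving one matrix per relative strand; peak pairs
#' are strandless and give a single matrix.
#'
#' @param signal a [tag_dataset()] or a peak-pair data frame.
#' @param tss_set TSS table (`gene_id`, `chrom`, `strand`, `tss`); for
#'   multi-TSS genes supply the primary TSS per gene.
#' @param bin bin width in bp (default 10).
#' @param window half-window in bp (default 500); columns span
#'   `[-window, window)` so there are `2 * window / bin` bins.
#' @return A `profile_matrix`: list with `counts` (genes x bins matrix, or a
#'   named list of two such matrices "same"/"opposite" for stranded input),
#'   `bin_start` (left edge of each bin, strand-oriented bp), `gene_id`,
#'   `bin`, `window`.
#' @export
bin_relative_to_tss <- function(signal, tss_set, bin = 10, window = 500) {
  stopifnot(bin >= 1, window %% bin == 0)
  genes <- tss_set[!duplicated(tss_set$gene_id), , drop = FALSE]
  bin_start <- seq.int(-window, window - bin, by = bin)
  nb <- length(bin_start)
  mk <- function() matrix(0, nrow = nrow(genes), ncol = nb,
                          dimnames = list(genes$gene_id, bin_start))
  accumulate <- function(mat, gi, offs) {
    keep <- offs >= -window & offs < window
    gi <- gi[keep]; offs <- offs[keep]
    bi <- floor(offs / bin) + window / bin + 1
    for (k in seq_along(gi)) mat[gi[k], bi[k]] <- mat[gi[k], bi[k]] + 1
    mat
  }
  stranded <- inherits(signal, "tag_dataset")
  if (stranded) {
    mats <- list(same = mk(), opposite = mk())
    for (g in seq_len(nrow(genes))) {
      tg <- signal[signal$chrom == genes$chrom[g], , drop = FALSE]
      if (nrow(tg) == 0) next
      off <- if (genes$strand[g] == "+") tg$pos - genes$tss[g]
             else genes$tss[g] - tg$pos
      rel <- ifelse((tg$strand == "W") == (genes$strand[g] == "+"),
                    "same", "opposite")
      for (side in c("same", "opposite")) {
        sel <- rel == side
        idx <- rep.int(which(sel), tg$count[sel])
        offs <- rep.int(off[sel], tg$count[sel])
        mats[[side]] <- accumulate(mats[[side]], rep(g, length(offs)), offs)
      }
    }
    counts <- mats
  } else {
    mat <- mk()
    for (g in seq_len(nrow(genes))) {
      p <- signal[signal$chrom == genes$chrom[g], , drop = FALSE]
      if (nrow(p) == 0) next
      off <- if (genes$strand[g] == "+") p$midpoint - genes$tss[g]
             else genes$tss[g] - p$midpoint
      mat <- accumulate(mat, rep(g, length(off)), off)
    }
    counts <- mat
  }
  structure(list(counts = counts, bin_start = bin_start,
                 gene_id = genes$gene_id, bin = bin, window = window),
            class = "profile_matrix")
}

profile_total <- function(pm) {
  if (is.list(pm$counts)) sum(vapply(pm$counts, sum, numeric(1)))
  else sum(pm$counts)
}

#' Normalize a ChIP profile matrix by an Input profile matrix
#'
#' Both matrices are converted to per-bin RPKM (reads per kb of bin per
#' million mapped tags: `count / (bin_kb * total_millions)`), then each ChIP
#' bin is divided by the corresponding Input bin. Bins where the Input RPKM
#' is zero carry no usable normalization and are marked missing (NA), not
#' infinite; composites exclude them.
#'
#' @param chip,input `profile_matrix` objects with identical bin structure
#'   (unstranded, or the same single matrix per call).
#' @param chip_total,input_total total mapped tags in the full ChIP / Input
#'   datasets (both strands); defaults to the matrix sums, but the full
#'   dataset totals should be supplied when the window covers only part of
#'   the genome.
#' @return A `profile_matrix` whose `counts` are ChIP RPKM / Input RPKM.
#' @export
normalize_by_input <- function(chip, input,
                               chip_total = profile_total(chip),
                               input_total = profile_total(input)) {
  stopifnot(inherits(chip, "profile_matrix"),
            inherits(input, "profile_matrix"))
  if (chip$bin != input$bin || chip$window != input$window ||
      !identical(dim(as_matrix(chip)), dim(as_matrix(input)))) {
    stop("ChIP and Input profile matrices have mismatched bin structure")
  }
  stopifnot(chip_total > 0, input_total > 0)
  cm <- as_matrix(chip); im <- as_matrix(input)  # stranded input: strands sum
  bin_kb <- chip$bin / 1000
  chip_rpkm <- cm / (bin_kb * chip_total / 1e6)
  input_rpkm <- im / (bin_kb * input_total / 1e6)
  ratio <- chip_rpkm / input_rpkm
  ratio[input_rpkm == 0] <- NA_real_
  out <- chip
  out$counts <- ratio
  out
}

as_matrix <- function(pm, which = NULL) {
  if (is.list(pm$counts)) {
    if (is.null(which)) {
      Reduce(`+`, pm$counts)
    } else {
      pm$counts[[which]]
    }
  } else {
    pm$counts
  }
}

#' Composite (meta-gene) trace from a profile matrix, percent of total
#'
#' Per-bin mean over genes (missing bins excluded), then scaled so the
#' trace sums to 100 — each bin reads as the percent of total TSS-proximal
#' signal falling at that offset.
#'
#' @param pm a `profile_matrix` (for stranded matrices pass `which` =
#'   "same" or "opposite").
#' @param which which stranded sub-matrix to use, if any.
#' @return Data frame `bin_start`, `value`, with `sum(value) == 100`.
#' @export
composite_average <- function(pm, which = NULL) {
  m <- as_matrix(pm, which)
  avg <- colMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  tot <- sum(avg)
  if (tot == 0) stop("composite has no signal in the window")
  data.frame(bin_start = pm$bin_start, value = 100 * avg / tot)
}

#' Row order for heatmap display, by a per-gene key
#'
#' Stable sort: equal keys preserve the original gene order. The returned
#' permutation is applied non-destructively, so one "linked" order can be
#' applied to the matrices of several factors.
#'
#' @param pm a `profile_matrix` (or anything with `gene_id`).
#' @param key numeric vector, one value per gene (e.g. inter-complex
#'   distance, CpG-island length, occupancy).
#' @param decreasing sort direction.
#' @return Integer permutation of the rows.
#' @export
sort_rows <- function(pm, key, decreasing = FALSE) {
  stopifnot(length(key) == length(pm$gene_id))
  order(key, decreasing = decreasing)  # order() is a stable sort
}

#' Modal signed offset of peak-pair midpoints from TSSs
#'
#' Builds a 1-bp histogram of strand-oriented midpoint offsets within
#' `max_dist` of each location's nearest TSS and reports the mode; ties are
#' broken to the smallest absolute offset (then the smaller offset). At
#' tRNA genes this recovers the canonical TBP crosslink ~21 bp upstream of
#' the TSS.
#'
#' @param pairs peak-pair data frame.
#' @param tss_set TSS table.
#' @param max_dist assignment window in bp (default 500).
#' @return List `mode` (signed bp), `histogram` (data frame offset/n).
#' @export
peak_pair_mode_offset <- function(pairs, tss_set, max_dist = 500) {
  asg <- assign_to_tss(pairs, tss_set, max_dist = max_dist)
  off <- asg$offset[asg$status == "assigned"]
  if (length(off) == 0) stop("no locations within max_dist of any TSS")
  tab <- table(off)
  hist <- data.frame(offset = as.integer(names(tab)), n = as.integer(tab))
  top <- hist[hist$n == max(hist$n), , drop = FALSE]
  top <- top[order(abs(top$offset), top$offset), , drop = FALSE]
  list(mode = top$offset[1], histogram = hist)
}
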