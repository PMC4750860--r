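#' Gaussian-kernel smoothing of strand-separated tags
#'
#' Each 5'-end tag contributes an un-normalized Gaussian kernel
#' `exp(-(p - t)^2 / (2 sigma^2))`, truncated at `trunc * sigma` bp; the
#' per-bp density on each (chromosome, strand) is the sum over tags weighted
#' by multiplicity. Only positions within the truncation radius of at least
#' one tag are evaluated — the kernel is exactly zero beyond it, so sparse
#' evaluation is exact. The kernel is deliberately not normalized to a KDE:
#' only the argmax structure matters for peak calling, and heights remain
#' comparable within a dataset.
#'
#' @param tags a [tag_dataset()].
#' @param sigma Gaussian kernel bandwidth in bp (default 20).
#' @param trunc kernel truncation radius in multiples of sigma (default 4).
#' @return Data frame `chrom`, `strand`, `pos`, `density`, sorted by
#'   position within each (chrom, strand); positions are contiguous within
#'   each covered block.
#' @export
smooth_tags <- function(tags, sigma = 20, trunc = 4) {
  stopifnot(inherits(tags, "tag_dataset"), sigma > 0, trunc > 0)
  radius <- as.integer(ceiling(trunc * sigma))
  groups <- split(as.data.frame(tags),
                  list(tags$chrom, tags$strand), drop = TRUE)
  out <- lapply(groups, function(g) {
    pos <- smooth_positions(g$pos, radius)
    dens <- kernel_density_at(pos, g$pos, g$count, sigma, radius)
    data.frame(chrom = g$chrom[1], strand = g$strand[1],
               pos = pos, density = dens)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), strand = character(),
               pos = integer(), density = numeric())
  rownames(res) <- NULL
  res[order(res$chrom, res$strand, res$pos), , drop = FALSE]
}

# Union of [t - radius, t + radius] windows as a sorted integer vector.
smooth_positions <- function(tagpos, radius) {
  r <- IRanges::reduce(IRanges::IRanges(start = pmax(tagpos - radius, 0L),
                                        end = tagpos + radius))
  unlist(lapply(seq_along(r), function(i) {
    seq.int(IRanges::start(r)[i], IRanges::end(r)[i])
  }))
}

kernel_density_at <- function(pos, tagpos, counts, sigma, radius) {
  dens <- numeric(length(pos))
  # positions are sorted; locate each tag's window by binary search
  for (i in seq_along(tagpos)) {
    t <- tagpos[i]
    lo <- findInterval(t - radius - 1L, pos) + 1L
    hi <- findInterval(t + radius, pos)
    if (hi < lo) next
    d <- pos[lo:hi] - t
    dens[lo:hi] <- dens[lo:hi] + counts[i] * exp(-d * d / (2 * sigma^2))
  }
  dens
}

#' Call strand-separated peaks with an exclusion zone
#'
#' GeneTrack-style caller: candidate summits are strict local maxima of the
#' smoothed density (plateaus resolved to the leftmost position); candidates
#' are retained greedily in descending height (ties to the leftmost summit),
#' and a candidate is discarded if its summit lies within
#' `< exclusion` bp (center-to-center) of an already-retained summit on the
#' same strand. This bounds the caller's resolution: two binding locations
#' closer than the exclusion zone cannot be called separately. Each retained
#' peak's `tag_count` is the number of raw tags within
#' `[summit - exclusion/2, summit + exclusion/2]`.
#'
#' @param tags a [tag_dataset()].
#' @param sigma kernel bandwidth in bp (default 20).
#' @param exclusion exclusion zone in bp (default 40).
#' @param trunc kernel truncation radius in sigmas (default 4).
#' @return Data frame `chrom`, `strand`, `summit`, `height`, `tag_count`,
#'   sorted by (chrom, strand, summit).
#' @export
call_peaks <- function(tags, sigma = 20, exclusion = 40, trunc = 4) {
  stopifnot(inherits(tags, "tag_dataset"), exclusion >= 1)
  dens <- smooth_tags(tags, sigma = sigma, trunc = trunc)
  groups <- split(dens, list(dens$chrom, dens$strand), drop = TRUE)
  half <- exclusion / 2
  out <- lapply(groups, function(g) {
    cand <- local_maxima(g$pos, g$density)
    if (nrow(cand) == 0) return(NULL)
    kept <- greedy_exclusion(cand, exclusion)
    tg <- tags[tags$chrom == g$chrom[1] & tags$strand == g$strand[1], ]
    cs <- c(0, cumsum(tg$count))  # tg is sorted by pos
    lo <- findInterval(kept$pos - half - 1e-9, tg$pos)
    hi <- findInterval(kept$pos + half + 1e-9, tg$pos)
    tag_count <- cs[hi + 1] - cs[lo + 1]
    data.frame(chrom = g$chrom[1], strand = g$strand[1],
               summit = kept$pos, height = kept$density,
               tag_count = as.integer(tag_count))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), strand = character(),
               summit = integer(), height = numeric(),
               tag_count = integer())
  rownames(res) <- NULL
  res <- res[res$tag_count >= 1, , drop = FALSE]
  res[order(res$chrom, res$strand, res$summit), , drop = FALSE]
}

# Strict local maxima of a density evaluated on (possibly gapped) sorted
# integer positions. Within each contiguous block, a position is a candidate
# iff its density exceeds the previous density and is not exceeded later in
# any plateau (leftmost plateau position wins). Block edges count as
# boundaries against zero density (any positive density qualifies).
local_maxima <- function(pos, density) {
  n <- length(pos)
  if (n == 0) return(data.frame(pos = integer(), density = numeric()))
  block_start <- c(TRUE, diff(pos) != 1L)
  prev <- c(0, density[-n])
  prev[block_start] <- 0
  # rising edge (strictly above the previous value) whose plateau then
  # falls: plateau resolved to its leftmost position
  cand <- logical(n)
  i <- 1L
  while (i <= n) {
    if (density[i] > prev[i]) {
      j <- i
      while (j < n && !block_start[j + 1L] && density[j + 1L] == density[i]) {
        j <- j + 1L
      }
      after <- if (j < n && !block_start[j + 1L]) density[j + 1L] else 0
      if (after < density[i] && density[i] > 0) cand[i] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(pos = pos[cand], density = density[cand])
}

# Greedy retention in descending height, ties to leftmost summit; a
# candidate within < exclusion bp of a retained summit is discarded.
greedy_exclusion <- function(cand, exclusion) {
  ord <- order(-cand$density, cand$pos)
  kept_pos <- integer(0)
  kept_idx <- integer(0)
  for (i in ord) {
    if (length(kept_pos) == 0 ||
        all(abs(kept_pos - cand$pos[i]) >= exclusion)) {
      kept_pos <- c(kept_pos, cand$pos[i])
      kept_idx <- c(kept_idx, i)
    }
  }
  cand[sort(kept_idx), , drop = FALSE]
}
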