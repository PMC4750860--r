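# Independent brute-force reference implementations used to validate the
# production code. Kept deliberately naive: direct sums, exhaustive scans,
# iterative selection.

# Density at every integer position of [lo, hi]: direct sum of truncated
# Gaussians over all tags.
oracle_density <- function(tagpos, counts, sigma, trunc, lo, hi) {
  pos <- lo:hi
  radius <- ceiling(trunc * sigma)
  dens <- numeric(length(pos))
  for (i in seq_along(tagpos)) {
    d <- pos - tagpos[i]
    w <- ifelse(abs(d) <= radius, exp(-d^2 / (2 * sigma^2)), 0)
    dens <- dens + counts[i] * w
  }
  data.frame(pos = pos, density = dens)
}

# Exhaustive peak calling on one strand: scan every position for a strict
# local maximum (plateaus -> leftmost), then iteratively retain the highest
# remaining candidate (ties -> leftmost) and delete all candidates closer
# than the exclusion zone.
oracle_call_peaks <- function(tagpos, counts, sigma = 20, exclusion = 40,
                              trunc = 4) {
  lo <- min(tagpos) - ceiling(trunc * sigma)
  hi <- max(tagpos) + ceiling(trunc * sigma)
  dd <- oracle_density(tagpos, counts, sigma, trunc, lo, hi)
  cand <- data.frame(pos = integer(), density = numeric())
  i <- 2
  n <- nrow(dd)
  while (i <= n - 1) {
    if (dd$density[i] > dd$density[i - 1]) {
      j <- i
      while (j < n && dd$density[j + 1] == dd$density[i]) j <- j + 1
      after <- if (j < n) dd$density[j + 1] else 0
      if (after < dd$density[i] && dd$density[i] > 0) {
        cand <- rbind(cand, dd[i, ])
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  kept <- data.frame(pos = integer(), density = numeric())
  while (nrow(cand) > 0) {
    best <- order(-cand$density, cand$pos)[1]
    kept <- rbind(kept, cand[best, ])
    cand <- cand[abs(cand$pos - cand$pos[best]) >= exclusion, ]
  }
  kept <- kept[order(kept$pos), ]
  half <- exclusion / 2
  kept$tag_count <- vapply(kept$pos, function(s) {
    sum(counts[tagpos >= s - half & tagpos <= s + half])
  }, numeric(1))
  # an emitted peak must carry at least one raw tag (same post-exclusion
  # filter as the caller)
  kept <- kept[kept$tag_count >= 1, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Iterative-selection pairing oracle: enumerate all admissible (W, C)
# couples and repeatedly take the best by (smallest span, largest combined
# tag count, leftmost W), removing both peaks each time.
oracle_pair_peaks <- function(w_summits, w_counts, c_summits, c_counts,
                              max_span = 80) {
  cand <- data.frame()
  for (i in seq_along(w_summits)) {
    for (j in seq_along(c_summits)) {
      span <- c_summits[j] - w_summits[i]
      if (span >= 0 && span <= max_span) {
        cand <- rbind(cand, data.frame(
          wi = i, ci = j, span = span,
          occ = w_counts[i] + c_counts[j], w = w_summits[i]))
      }
    }
  }
  out <- data.frame()
  while (nrow(cand) > 0) {
    best <- order(cand$span, -cand$occ, cand$w)[1]
    out <- rbind(out, cand[best, ])
    cand <- cand[cand$wi != cand$wi[best] & cand$ci != cand$ci[best], ]
  }
  if (nrow(out) == 0) return(out)
  out[order(out$w), c("wi", "ci", "span", "occ", "w")]
}

# Build a tag_dataset from one strand's coordinate multiset on one chrom.
tags1 <- function(pos, strand = "W", count = NULL, chrom = "chr1") {
  tag_dataset(rep(chrom, length(pos)), rep(strand, length(pos)), pos,
              count = count)
}

# Two-border site helper: n tags per strand at x - b and x + b.
site_tags <- function(x, b, n, chrom = "chr1") {
  tag_dataset(rep(chrom, 2 * n),
              c(rep("W", n), rep("C", n)),
              c(rep(x - b, n), rep(x + b, n)))
}

# Adjusted Rand index between two labelings (independent of the k-means
# code under test).
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
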