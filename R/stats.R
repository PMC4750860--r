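#' Adjacent inter-location distances within groups
#'
#' Within each group (a CpG island, a promoter window), locations are
#' sorted by coordinate and each adjacent pair contributes one record:
#' the distance between the two midpoints and the occupancies of the left
#' and right location. Three locations give two adjacent records, not
#' three pairwise ones; singleton groups contribute nothing.
#'
#' @param locations data frame with `midpoint`, `occupancy` and a grouping
#'   column.
#' @param group name of the grouping column (default "group").
#' @return Data frame `group`, `distance`, `left_occ`, `right_occ`.
#' @export
inter_location_distances <- function(locations, group = "group") {
  stopifnot(all(c("midpoint", "occupancy", group) %in% names(locations)))
  parts <- split(locations, locations[[group]])
  recs <- lapply(parts, function(p) {
    if (nrow(p) < 2) return(NULL)
    p <- p[order(p$midpoint), , drop = FALSE]
    data.frame(group = p[[group]][1],
               distance = diff(p$midpoint),
               left_occ = p$occupancy[-nrow(p)],
               right_occ = p$occupancy[-1])
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(group = character(), distance = integer(),
               left_occ = numeric(), right_occ = numeric())
  rownames(out) <- NULL
  out
}

#' Sliding-window SD of occupancy along the distance axis
#'
#' Records are sorted by distance (stable, so equal distances keep input
#' order); a centered window of `window` consecutive records slides in
#' steps of 1, and for each position the sample SD (n-1 denominator) of the
#' chosen occupancy values is reported against the median distance in the
#' window. Low variability at short distances diagnoses coordinately
#' regulated adjacent complexes.
#'
#' @param records output of [inter_location_distances()].
#' @param window number of consecutive records per window (default 30).
#' @param value which occupancy to use: "left", "right", or "both"
#'   (left and right interleaved per record; window then counts records,
#'   SD is over 2*window values).
#' @return Data frame `distance` (median in window), `sd`.
#' @export
sliding_window_sd <- function(records, window = 30, value = c("left", "right", "both")) {
  value <- match.arg(value)
  n <- nrow(records)
  if (n < window) stop("need at least ", window, " records, got ", n)
  ord <- order(records$distance)  # stable
  r <- records[ord, , drop = FALSE]
  idx <- seq_len(n - window + 1)
  dist_med <- vapply(idx, function(i) {
    stats::median(r$distance[i:(i + window - 1)])
  }, numeric(1))
  sdv <- vapply(idx, function(i) {
    w <- i:(i + window - 1)
    v <- switch(value,
                left = r$left_occ[w],
                right = r$right_occ[w],
                both = c(rbind(r$left_occ[w], r$right_occ[w])))
    stats::sd(v)
  }, numeric(1))
  data.frame(distance = dist_med, sd = sdv)
}

#' Correlation of adjacent-complex occupancies by distance stratum
#'
#' Pearson correlation between left and right occupancies of adjacent
#' location pairs, within strata of inter-location distance. Strata with
#' fewer than 3 records report NA.
#'
#' @param records output of [inter_location_distances()].
#' @param breaks distance breakpoints passed to [cut()] (right-open).
#' @return Data frame `stratum`, `n`, `r`.
#' @export
adjacent_occupancy_correlation <- function(records, breaks) {
  stratum <- cut(records$distance, breaks = breaks, right = FALSE)
  parts <- split(records, stratum, drop = FALSE)
  out <- data.frame(stratum = names(parts),
                    n = vapply(parts, nrow, integer(1)),
                    r = vapply(parts, function(p) {
                      if (nrow(p) < 3) return(NA_real_)
                      stats::cor(p$left_occ, p$right_occ)
                    }, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Median-centered log2 transform
#'
#' `log2(v + 1)` pseudocount transform, then subtraction of the median of
#' the transformed values.
#'
#' @param v non-negative numeric vector.
#' @return Centered log2 vector.
#' @export
log2_median_centered <- function(v) {
  x <- log2(v + 1)
  x - stats::median(x)
}

#' Moving-average trend of one gene-level variable against another
#'
#' Both series are put on a median-centered log2(v+1) scale, genes are
#' sorted by the x series, and windowed means of both series (window
#' `window` genes, step 1) trace the trend — e.g. mRNA level versus
#' initiation-factor occupancy across genes.
#'
#' @param x,y parallel non-negative gene-level vectors.
#' @param window moving-average window in genes (default 100).
#' @return Data frame `x`, `y` of windowed means (length `n - window + 1`).
#' @export
moving_average_trend <- function(x, y, window = 100) {
  stopifnot(length(x) == length(y), length(x) >= window, window >= 1)
  lx <- log2_median_centered(x)
  ly <- log2_median_centered(y)
  ord <- order(lx)
  lx <- lx[ord]; ly <- ly[ord]
  data.frame(x = moving_mean(lx, window), y = moving_mean(ly, window))
}

moving_mean <- function(v, window) {
  cs <- cumsum(c(0, v))
  (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
}

#' Pairwise Pearson correlations of gene-level series
#'
#' All-vs-all Pearson correlation on median-centered log2(v+1) values.
#' Genes with a zero in either series of a pair are excluded from that
#' pair's correlation (unmeasured, not zero signal).
#'
#' @param tables named list or data frame of parallel non-negative
#'   gene-level vectors.
#' @return Symmetric correlation matrix.
#' @export
pairwise_correlations <- function(tables) {
  tables <- as.list(tables)
  k <- length(tables)
  stopifnot(k >= 2, length(unique(lengths(tables))) == 1)
  r <- matrix(NA_real_, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      keep <- tables[[i]] > 0 & tables[[j]] > 0
      r[i, j] <- if (sum(keep) >= 3) {
        stats::cor(log2_median_centered(tables[[i]][keep]),
                   log2_median_centered(tables[[j]][keep]))
      } else NA_real_
    }
  }
  r
}
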