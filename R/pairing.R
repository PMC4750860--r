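#' Pair forward- and reverse-strand border peaks
#'
#' The two exonuclease borders of a protein-DNA crosslink appear as a
#' W-strand peak upstream and a C-strand peak downstream of the protected
#' footprint. Peaks are paired if the C peak lies 0-80 bp in the 3'
#' direction (on the forward strand: at equal or greater coordinate) of the
#' W peak. Each peak joins at most one pair; conflicting candidates are
#' resolved by smallest span first, then larger combined tag count, then
#' leftmost W summit. The pair midpoint (floor of the summit mean) estimates
#' the crosslink point; occupancy is the sum of the two peak tag counts.
#'
#' @param w_peaks,c_peaks peak data frames from [call_peaks()] for the "W"
#'   and "C" strands of one chromosome and sample.
#' @param max_span maximum allowed C - W summit distance in bp (default 80).
#' @param sample sample label attached to the output.
#' @return List with `pairs` (data frame `chrom`, `w_summit`, `c_summit`,
#'   `midpoint`, `span`, `occupancy`, `sample`) and `unpaired` (peaks that
#'   joined no pair).
#' @export
pair_peaks <- function(w_peaks, c_peaks, max_span = 80,
                       sample = NA_character_) {
  chroms <- unique(c(w_peaks$chrom, c_peaks$chrom))
  if (length(chroms) > 1) {
    stop("pair_peaks expects peaks from a single chromosome; got: ",
         paste(chroms, collapse = ", "), " (use pair_peaks_genome)")
  }
  empty_pairs <- data.frame(chrom = character(), w_summit = integer(),
                            c_summit = integer(), midpoint = integer(),
                            span = integer(), occupancy = integer(),
                            sample = character())
  if (nrow(w_peaks) == 0 || nrow(c_peaks) == 0) {
    return(list(pairs = empty_pairs, unpaired = rbind(w_peaks, c_peaks)))
  }
  # all admissible candidates: 0 <= c - w <= max_span
  cand <- expand.grid(wi = seq_len(nrow(w_peaks)), ci = seq_len(nrow(c_peaks)))
  cand$span <- c_peaks$summit[cand$ci] - w_peaks$summit[cand$wi]
  cand <- cand[cand$span >= 0 & cand$span <= max_span, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(pairs = empty_pairs, unpaired = rbind(w_peaks, c_peaks)))
  }
  cand$occ <- w_peaks$tag_count[cand$wi] + c_peaks$tag_count[cand$ci]
  cand <- cand[order(cand$span, -cand$occ, w_peaks$summit[cand$wi]), ,
               drop = FALSE]
  used_w <- logical(nrow(w_peaks)); used_c <- logical(nrow(c_peaks))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_w[cand$wi[i]] && !used_c[cand$ci[i]]) {
      take[i] <- TRUE
      used_w[cand$wi[i]] <- TRUE
      used_c[cand$ci[i]] <- TRUE
    }
  }
  sel <- cand[take, , drop = FALSE]
  pairs <- data.frame(
    chrom = w_peaks$chrom[sel$wi],
    w_summit = w_peaks$summit[sel$wi],
    c_summit = c_peaks$summit[sel$ci],
    midpoint = as.integer(floor((w_peaks$summit[sel$wi] +
                                   c_peaks$summit[sel$ci]) / 2)),
    span = as.integer(sel$span),
    occupancy = as.integer(sel$occ),
    sample = sample)
  pairs <- pairs[order(pairs$midpoint), , drop = FALSE]
  rownames(pairs) <- NULL
  unpaired <- rbind(w_peaks[!used_w, , drop = FALSE],
                    c_peaks[!used_c, , drop = FALSE])
  rownames(unpaired) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Pair peaks across a whole peak table
#'
#' Splits a [call_peaks()] table by chromosome and applies [pair_peaks()]
#' to the W/C peaks of each.
#'
#' @param peaks combined peak table with both strands.
#' @inheritParams pair_peaks
#' @return Same structure as [pair_peaks()].
#' @export
pair_peaks_genome <- function(peaks, max_span = 80, sample = NA_character_) {
  res <- lapply(split(peaks, peaks$chrom), function(p) {
    pair_peaks(p[p$strand == "W", , drop = FALSE],
               p[p$strand == "C", , drop = FALSE],
               max_span = max_span, sample = sample)
  })
  pairs <- do.call(rbind, lapply(res, `[[`, "pairs"))
  unpaired <- do.call(rbind, lapply(res, `[[`, "unpaired"))
  pairs <- pairs[order(pairs$chrom, pairs$midpoint), , drop = FALSE]
  rownames(pairs) <- NULL
  rownames(unpaired) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Remove peak pairs falling in blacklisted intervals
#'
#' A pair is removed iff its midpoint lies inside a blacklist interval
#' (half-open membership).
#'
#' @param pairs peak-pair data frame.
#' @param blacklist an [interval_set()].
#' @return Filtered pairs, order preserved.
#' @export
filter_blacklist <- function(pairs, blacklist) {
  if (nrow(pairs) == 0 || nrow(blacklist) == 0) return(pairs)
  hit <- interval_lookup(blacklist, pairs$chrom, pairs$midpoint)
  out <- pairs[is.na(hit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the low-occupancy threshold to peak pairs
#'
#' Keeps pairs with occupancy strictly greater than `min_tags` (default 4,
#' i.e. at least 5 tags across the two borders).
#'
#' @param pairs peak-pair data frame.
#' @param min_tags strict lower bound on occupancy (default 4).
#' @return Filtered pairs, order preserved.
#' @export
filter_occupancy <- function(pairs, min_tags = 4) {
  out <- pairs[pairs$occupancy > min_tags, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match peak-pair locations between two datasets
#'
#' A location in `pairs_a` is matched iff some midpoint in `pairs_b` on the
#' same chromosome lies within `window` bp (symmetric absolute distance,
#' boundary inclusive).
#'
#' @param pairs_a,pairs_b peak-pair data frames.
#' @param window matching window in bp.
#' @return List with `matched` and `unmatched` subsets of `pairs_a`,
#'   `n_matched`, and per-location nearest distance `dist` column added.
#' @export
match_locations <- function(pairs_a, pairs_b, window) {
  if (nrow(pairs_a) == 0) {
    return(list(matched = pairs_a, unmatched = pairs_a, n_matched = 0L))
  }
  dist <- rep(Inf, nrow(pairs_a))
  for (ch in unique(pairs_a$chrom)) {
    ai <- which(pairs_a$chrom == ch)
    b <- pairs_b$midpoint[pairs_b$chrom == ch]
    if (length(b) == 0) next
    b <- sort(b)
    idx <- findInterval(pairs_a$midpoint[ai], b)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(b))
    dist[ai] <- pmin(abs(pairs_a$midpoint[ai] - b[lo]),
                     abs(pairs_a$midpoint[ai] - b[hi]))
  }
  a <- pairs_a
  a$dist <- dist
  matched <- a[dist <= window, , drop = FALSE]
  unmatched <- a[dist > window, , drop = FALSE]
  rownames(matched) <- NULL
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched,
       n_matched = nrow(matched))
}
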