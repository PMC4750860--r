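#' Assign peak-pair locations to transcription start sites
#'
#' Each bound location (peak-pair midpoint) is assigned to the nearest TSS
#' on the same chromosome if that TSS lies within `max_dist` bp (unsigned
#' distance); the nearest TSS of a multi-TSS gene is its primary TSS for
#' that location, the gene's other TSSs are secondary. The signed offset is
#' oriented by gene strand, negative upstream of the TSS in the gene's
#' direction of transcription (so a TFIIB crosslink 20 bp upstream reads as
#' -20 on either strand). Locations with no TSS within `max_dist` are
#' labeled TSS-distal. Distance ties are broken to the smaller TSS
#' coordinate.
#'
#' @param pairs peak-pair data frame (needs `chrom`, `midpoint`,
#'   `occupancy`).
#' @param tss_set TSS table from [read_tss_table()] (`gene_id`, `chrom`,
#'   `strand`, `tss`).
#' @param max_dist maximum assignment distance in bp (default 500).
#' @return The pairs with added columns `gene_id`, `tss`, `gene_strand`,
#'   `offset` (signed, strand-oriented), `status` ("assigned"/"distal").
#' @export
assign_to_tss <- function(pairs, tss_set, max_dist = 500) {
  n <- nrow(pairs)
  out <- pairs
  out$gene_id <- NA_character_
  out$tss <- NA_integer_
  out$gene_strand <- NA_character_
  out$offset <- NA_integer_
  out$status <- rep("distal", n)
  if (n == 0 || nrow(tss_set) == 0) return(out)
  for (ch in unique(pairs$chrom)) {
    pi <- which(pairs$chrom == ch)
    ts <- tss_set[tss_set$chrom == ch, , drop = FALSE]
    if (nrow(ts) == 0) next
    ts <- ts[order(ts$tss), , drop = FALSE]
    for (i in pi) {
      d <- abs(ts$tss - pairs$midpoint[i])
      dmin <- min(d)
      if (dmin > max_dist) next
      j <- which(d == dmin)[1]  # ts sorted by tss: tie -> smaller coordinate
      out$gene_id[i] <- ts$gene_id[j]
      out$tss[i] <- ts$tss[j]
      out$gene_strand[i] <- ts$strand[j]
      out$offset[i] <- if (ts$strand[j] == "+") {
        pairs$midpoint[i] - ts$tss[j]
      } else {
        ts$tss[j] - pairs$midpoint[i]
      }
      out$status[i] <- "assigned"
    }
  }
  out
}

#' Nonredundant detected genes of an assignment
#'
#' @param assignments output of [assign_to_tss()].
#' @return Character vector of unique gene ids with at least one assigned
#'   location.
#' @export
detected_genes <- function(assignments) {
  unique(assignments$gene_id[assignments$status == "assigned"])
}

#' Venn decomposition of gene detection sets
#'
#' Counts every region of a 2- or 3-set Venn diagram over gene-id sets
#' (e.g. genes with a TBP location, a TFIIB location, measurable mRNA).
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return Named integer vector; region names join set names with "&" for
#'   membership and "only" for exclusive regions, plus per-set totals.
#' @export
detection_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2, 3),
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), ncol = length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  regions <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&", simplify = TRUE)
  }))
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  totals <- vapply(sets, length, integer(1))
  names(totals) <- paste0("total_", names(sets))
  c(counts, totals)
}

#' Complexes per CpG island
#'
#' A location belongs to an island iff its midpoint lies inside the island
#' interval (half-open). Reports islands with at least one location, the
#' total locations inside islands, the mean per occupied island, and two
#' promoter-overlap fractions for TSS-assigned genes: the fraction whose
#' primary TSS lies in an island, and the fraction with a bound location in
#' an island — the two readings of "promoter overlaps a CpG island".
#'
#' @param pairs peak-pair data frame.
#' @param islands an [interval_set()] of CpG islands.
#' @param assignments optional [assign_to_tss()] output for the promoter
#'   fractions (and the TSS coordinates they need).
#' @return List: `per_island` data frame (island row index, n locations),
#'   `n_islands_occupied`, `n_locations_in_islands`,
#'   `mean_per_occupied_island` (NA when no island is occupied),
#'   `frac_genes_tss_in_island`, `frac_genes_location_in_island`.
#' @export
cpg_overlap <- function(pairs, islands, assignments = NULL) {
  if (nrow(islands) == 0) {
    return(list(per_island = data.frame(island = integer(), n = integer()),
                n_islands_occupied = 0L, n_locations_in_islands = 0L,
                mean_per_occupied_island = NA_real_,
                frac_genes_tss_in_island = NA_real_,
                frac_genes_location_in_island = NA_real_))
  }
  hit <- interval_lookup(islands, pairs$chrom, pairs$midpoint)
  occ <- table(hit[!is.na(hit)])
  per_island <- data.frame(island = as.integer(names(occ)),
                           n = as.integer(occ))
  n_in <- sum(!is.na(hit))
  res <- list(per_island = per_island,
              n_islands_occupied = nrow(per_island),
              n_locations_in_islands = n_in,
              mean_per_occupied_island =
                if (nrow(per_island) > 0) n_in / nrow(per_island)
                else NA_real_,
              frac_genes_tss_in_island = NA_real_,
              frac_genes_location_in_island = NA_real_)
  if (!is.null(assignments)) {
    stopifnot(nrow(assignments) == nrow(pairs))  # row-parallel annotation
    asg <- assignments[assignments$status == "assigned", , drop = FALSE]
    if (nrow(asg) > 0) {
      gene_tbl <- asg[!duplicated(asg$gene_id), , drop = FALSE]
      tss_hit <- interval_lookup(islands, gene_tbl$chrom, gene_tbl$tss)
      res$frac_genes_tss_in_island <- mean(!is.na(tss_hit))
      loc_hit <- !is.na(hit) & assignments$status == "assigned"
      genes_with_loc <- unique(assignments$gene_id[loc_hit])
      res$frac_genes_location_in_island <-
        length(genes_with_loc) / nrow(gene_tbl)
    }
  }
  res
}

#' Classify locations by genome-segment annotation
#'
#' Each location takes the class of the segment containing its midpoint
#' (first segment in file order wins where segments overlap). Fractions are
#' over classified locations and sum to 1; unclassified locations are
#' reported separately.
#'
#' @param pairs peak-pair data frame.
#' @param segments an [interval_set()] with class labels.
#' @return List: `fractions` (named numeric, sums to 1 over classified),
#'   `counts` (named integer), `n_unclassified`.
#' @export
classify_segments <- function(pairs, segments) {
  if (nrow(segments) == 0 || nrow(pairs) == 0) {
    return(list(fractions = numeric(0), counts = integer(0),
                n_unclassified = nrow(pairs)))
  }
  hit <- interval_lookup(segments, pairs$chrom, pairs$midpoint)
  cls <- segments$label[hit]
  tab <- table(cls[!is.na(cls)])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  fractions <- if (sum(counts) > 0) counts / sum(counts) else numeric(0)
  list(fractions = fractions, counts = counts,
       n_unclassified = sum(is.na(hit)))
}
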