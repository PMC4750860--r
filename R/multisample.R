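#' Build a gene-by-sample occupancy matrix
#'
#' A gene row exists iff the gene is detected (has at least one TSS-assigned
#' peak pair) in at least one sample; the cell value is the summed pair
#' occupancy of the gene in that sample, 0 where the gene was not detected.
#'
#' @param assignments_by_sample named list of [assign_to_tss()] outputs, one
#'   per sample.
#' @return Numeric matrix, rownames gene ids, colnames sample names.
#' @export
build_occupancy_matrix <- function(assignments_by_sample) {
  stopifnot(is.list(assignments_by_sample),
            !is.null(names(assignments_by_sample)))
  per_sample <- lapply(assignments_by_sample, function(a) {
    a <- a[a$status == "assigned", , drop = FALSE]
    if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
    tapply(a$occupancy, a$gene_id, sum)
  })
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, nrow = length(genes), ncol = length(per_sample),
              dimnames = list(genes, names(assignments_by_sample)))
  for (s in names(per_sample)) {
    v <- per_sample[[s]]
    m[names(v), s] <- as.numeric(v)
  }
  m
}

#' Column-wise normalization of an occupancy matrix
#'
#' Within each sample column, detected (nonzero) occupancies are log2(v+1)
#' transformed and centered on the column mean of those detected entries.
#' Zeros mean "not detected" and are returned as NA so they stay distinct
#' from genuinely low occupancy in display and clustering.
#'
#' @param m occupancy matrix from [build_occupancy_matrix()].
#' @return Matrix of centered log2 values, NA where not detected.
#' @export
normalize_columns <- function(m) {
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    nz <- m[, j] > 0
    if (!any(nz)) next
    v <- log2(m[nz, j] + 1)
    out[nz, j] <- v - mean(v)
  }
  out
}

#' Split genes into the detected-everywhere group and the remainder
#'
#' Group 1 is the set of genes detected (nonzero) in every sample; the
#' remainder is passed on to k-means partitioning.
#'
#' @param m occupancy matrix (raw, zeros = not detected).
#' @return List `group1` and `remainder`, character vectors of gene ids.
#' @export
group_by_detection <- function(m) {
  all_det <- rowSums(m > 0) == ncol(m)
  list(group1 = rownames(m)[all_det], remainder = rownames(m)[!all_det])
}

#' K-means partitioning of the remainder genes
#'
#' Rows are the column-normalized occupancies with not-detected cells
#' imputed one log2 unit below the column minimum of detected values (so
#' absence reads as "lower than any observed occupancy" without dropping
#' the gene). k-means++ seeding, `restarts` independent starts, best
#' within-cluster sum of squares kept. Cluster labels are relabeled
#' 2..(k+1) in order of descending cluster mean, and genes are ordered
#' within each group by their cross-sample mean.
#'
#' @param m raw occupancy matrix restricted to the remainder genes.
#' @param k number of clusters (default 3, giving groups 2-4).
#' @param seed RNG seed for reproducible seeding/restarts.
#' @param restarts independent k-means++ starts (default 100).
#' @return List `labels` (named integer vector, values 2..k+1), `order`
#'   (gene ids sorted by group then descending mean), `centers`,
#'   `tot_withinss`.
#' @export
kmeans_groups <- function(m, k = 3, seed = 1, restarts = 100) {
  norm <- normalize_columns(m)
  for (j in seq_len(ncol(norm))) {
    cmin <- suppressWarnings(min(norm[, j], na.rm = TRUE))
    if (!is.finite(cmin)) cmin <- 0
    norm[is.na(norm[, j]), j] <- cmin - 1
  }
  if (k >= nrow(norm)) {
    labels <- stats::setNames(seq_len(nrow(norm)) + 1L, rownames(norm))
    return(list(labels = labels, order = rownames(norm),
                centers = norm, tot_withinss = 0))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(norm, k)
    fit <- suppressWarnings(
      stats::kmeans(norm, centers = centers, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  # relabel clusters by descending mean occupancy; groups numbered from 2
  means <- tapply(rowMeans(norm), best$cluster, mean)
  rank_of <- stats::setNames(rank(-means, ties.method = "first"),
                             names(means))
  labels <- rank_of[as.character(best$cluster)] + 1L
  labels <- stats::setNames(as.integer(labels), rownames(norm))
  ord <- order(labels, -rowMeans(norm))
  list(labels = labels, order = rownames(norm)[ord],
       centers = best$centers, tot_withinss = best$tot.withinss)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[i + 1] <- sample.int(n, 1)
    } else {
      idx[i + 1] <- sample.int(n, 1, prob = d2)
    }
    nd <- rowSums((x - matrix(x[idx[i + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[idx, , drop = FALSE]
}

#' Hierarchical clustering of samples by occupancy profile
#'
#' Sample-sample distance is 1 - Pearson r over genes detected in both
#' samples; average-linkage hierarchical clustering; the dendrogram is
#' also serialized as a Newick string.
#'
#' @param m occupancy matrix (raw; correlation computed on column-
#'   normalized values over co-detected genes).
#' @return List `hclust`, `newick`, `leaf_order` (sample names), `dist`
#'   (the distance matrix).
#' @export
cluster_samples <- function(m) {
  stopifnot(ncol(m) >= 2)
  norm <- normalize_columns(m)
  k <- ncol(m)
  d <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      keep <- !is.na(norm[, i]) & !is.na(norm[, j])
      r <- if (sum(keep) >= 3) stats::cor(norm[keep, i], norm[keep, j])
           else 0
      d[i, j] <- 1 - r
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = newick,
       leaf_order = colnames(m)[hc$order], dist = d)
}
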