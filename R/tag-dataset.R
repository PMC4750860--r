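#' Strand-separated 5' tag dataset
#'
#' The raw signal of the pipeline: a multiset of 5'-end tag coordinates per
#' chromosome and strand. ChIP-exo trims each immunoprecipitated fragment to
#' within a few bp of the protein-DNA crosslink, so the 5' ends of forward
#' ("W", Watson) and reverse ("C", Crick) reads accumulate at the left and
#' right exonuclease borders of the protected footprint.
#'
#' Stored as a data frame with columns `chrom`, `strand` ("W"/"C"), `pos`
#' (0-based bp) and `count` (multiplicity), sorted by (chrom, strand, pos),
#' with a `sample` attribute. All coordinates in the package are 0-based.
#'
#' @param chrom character vector of chromosome names.
#' @param strand character vector, "W"/"+" for forward, "C"/"-" for reverse.
#' @param pos integer vector of 0-based 5'-end coordinates.
#' @param count integer multiplicities (default 1 per record); records at the
#'   same (chrom, strand, pos) are aggregated.
#' @param sample sample label carried through the pipeline.
#' @return A `tag_dataset` object.
#' @export
tag_dataset <- function(chrom = character(), strand = character(),
                        pos = integer(), count = NULL, sample = NA_character_) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  if (is.null(count)) count <- rep.int(1L, n)
  stopifnot(length(count) == n)
  strand <- normalize_strand(strand)
  if (n > 0 && any(pos < 0)) stop("tag coordinates must be non-negative")
  df <- data.frame(chrom = as.character(chrom), strand = strand,
                   pos = as.integer(pos), count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    agg <- stats::aggregate(count ~ chrom + strand + pos, data = df, FUN = sum)
    agg <- agg[order(agg$chrom, agg$strand, agg$pos), , drop = FALSE]
    df <- agg[, c("chrom", "strand", "pos", "count")]
    rownames(df) <- NULL
  }
  structure(df, sample = sample, class = c("tag_dataset", "data.frame"))
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("+", "W", "w")] <- "W"
  s[s %in% c("-", "C", "c")] <- "C"
  bad <- !(s %in% c("W", "C")) & !is.na(s)
  if (any(bad)) stop("unknown strand value(s): ",
                     paste(unique(s[bad]), collapse = ", "))
  s
}

#' Total number of tags in a dataset
#'
#' @param tags a [tag_dataset()].
#' @param strand optional "W" or "C" to count one strand only.
#' @return Integer tag count (sum of multiplicities).
#' @export
n_tags <- function(tags, strand = NULL) {
  stopifnot(inherits(tags, "tag_dataset"))
  if (!is.null(strand)) tags <- tags[tags$strand == normalize_strand(strand), ]
  sum(tags$count)
}

#' @export
print.tag_dataset <- function(x, ...) {
  cat(sprintf("tag_dataset: %d tags at %d positions, %d chromosome(s), sample=%s\n",
              sum(x$count), nrow(x), length(unique(x$chrom)),
              as.character(attr(x, "sample"))))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Merge biological replicate tag datasets
#'
#' Final peak-pair calls are made on the coordinate-wise multiset union of
#' all replicate tags, so per-position multiplicities add.
#'
#' @param tagsets a list of [tag_dataset()] objects for the same factor.
#' @param sample sample label for the merged dataset (default: label of the
#'   first non-empty input).
#' @return A merged `tag_dataset`.
#' @export
merge_replicates <- function(tagsets, sample = NULL) {
  stopifnot(is.list(tagsets), length(tagsets) >= 1,
            all(vapply(tagsets, inherits, logical(1), "tag_dataset")))
  if (is.null(sample)) {
    labs <- vapply(tagsets, function(t) as.character(attr(t, "sample")),
                   character(1))
    sample <- if (any(!is.na(labs))) labs[!is.na(labs)][1] else NA_character_
  }
  all <- do.call(rbind, lapply(tagsets, as.data.frame))
  tag_dataset(all$chrom, all$strand, all$pos, all$count, sample = sample)
}
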