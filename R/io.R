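#' Read tags from a BED6 file
#'
#' Each BED record contributes one tag at the record's 5' position: `start`
#' for "+" records, `end - 1` for "-" records (the 5' end of a minus-strand
#' read is its rightmost base). BED is 0-based half-open, matching the
#' package's internal convention.
#'
#' @param path BED6 file, columns chrom/start/end/name/score/strand.
#' @param sample sample label to attach.
#' @return A [tag_dataset()].
#' @export
read_tags_bed <- function(path, sample = NA_character_) {
  bed <- read_bed6(path)
  if (nrow(bed) == 0) return(tag_dataset(sample = sample))
  pos <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
  tag_dataset(bed$chrom, bed$strand, pos, sample = sample)
}

#' Write a tag dataset as BED6
#'
#' One record per 5' end (multiplicities expanded), score 1, 1-bp intervals.
#'
#' @param tags a [tag_dataset()].
#' @param path output file.
#' @export
write_tags_bed <- function(tags, path) {
  stopifnot(inherits(tags, "tag_dataset"))
  idx <- rep.int(seq_len(nrow(tags)), tags$count)
  pos <- tags$pos[idx]
  strand <- ifelse(tags$strand[idx] == "W", "+", "-")
  df <- data.frame(chrom = tags$chrom[idx], start = pos, end = pos + 1L,
                   name = "tag", score = 1L, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed6 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 fields")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": non-numeric coordinates")
  }
  strand <- get(6, "+")
  ok <- strand %in% c("+", "-")
  if (any(!ok)) {
    stop("unknown strand on BED line ", which(!ok)[1], " in ", path)
  }
  data.frame(chrom = get(1, NA), start = start, end = end,
             name = get(4, "."),
             score = suppressWarnings(as.numeric(get(5, "0"))),
             strand = strand)
}

#' Extract 5'-end tags from aligned reads (SAM/BAM)
#'
#' Converts mapped alignments to the same strand-separated 5'-end
#' representation as [read_tags_bed()]: forward reads yield a W tag at the
#' alignment start, reverse reads a C tag at the alignment end (both
#' converted from SAM's 1-based coordinates to 0-based). Unmapped and
#' secondary records are skipped. Requires the Rsamtools and
#' GenomicAlignments packages.
#'
#' @param path a SAM or BAM file.
#' @param sample sample label to attach.
#' @return A [tag_dataset()].
#' @export
tags_from_alignments <- function(path, sample = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("tags_from_alignments requires Rsamtools and GenomicAlignments")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
  if (length(aln) == 0) {
    warning("no mapped reads in ", path)
    return(tag_dataset(sample = sample))
  }
  str <- as.character(BiocGenerics::strand(aln))
  # SAM POS is 1-based; start(aln)-1 is the 0-based leftmost base and
  # end(aln)-1 the 0-based rightmost base of the alignment.
  pos <- ifelse(str == "+",
                BiocGenerics::start(aln) - 1L,
                BiocGenerics::end(aln) - 1L)
  tag_dataset(as.character(GenomeInfoDb::seqnames(aln)), str, pos,
              sample = sample)
}

#' Read a TSS annotation table
#'
#' Accepts BED6 (TSS = start for "+" genes, end-1 for "-" genes; gene id in
#' the name column) or a headered TSV with columns `gene_id`, `chrom`,
#' `strand`, `tss`. A gene may have several TSS rows; all are kept under one
#' gene id and collapse to a nonredundant gene set downstream.
#'
#' @param path annotation file.
#' @return Data frame with columns `gene_id`, `chrom`, `strand` (+/-), `tss`
#'   (0-based bp).
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 1 && grepl("gene_id", first)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(df)))
    out <- df[, c("gene_id", "chrom", "strand", "tss")]
  } else {
    bed <- read_bed6(path)
    tss <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
    out <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                      strand = bed$strand, tss = as.integer(tss))
  }
  out$tss <- as.integer(out$tss)
  stopifnot(all(out$strand %in% c("+", "-")))
  out[order(out$chrom, out$tss), , drop = FALSE]
}

#' Read labeled genomic intervals (BED)
#'
#' Intervals are 0-based half-open `[start, end)`. The class label is taken
#' from the BED name column unless `label` overrides it for the whole file
#' (as for CpG islands or a blacklist).
#'
#' @param path BED file.
#' @param label optional single label applied to every interval.
#' @return An interval set: data frame `chrom`, `start`, `end`, `label`.
#' @export
read_intervals_bed <- function(path, label = NULL) {
  bed <- read_bed6(path)
  lab <- if (is.null(label)) bed$name else rep(label, nrow(bed))
  interval_set(bed$chrom, bed$start, bed$end, lab)
}

#' Construct an interval set
#'
#' @param chrom,start,end,label parallel vectors; `[start, end)` half-open,
#'   `start < end`.
#' @return Data frame with class `interval_set`; file order is preserved
#'   (relevant where overlapping intervals are resolved first-wins).
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = character()) {
  n <- length(start)
  if (length(label) %in% c(0, 1) && n > 0) {
    label <- rep(if (length(label)) label else ".", n)
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$start >= df$end)) {
    stop("interval_set requires start < end (half-open intervals)")
  }
  structure(df, class = c("interval_set", "data.frame"))
}

#' Locate points within an interval set
#'
#' Half-open membership: a point p is inside `[start, end)` iff
#' `start <= p < end`. Where intervals overlap, the first interval in file
#' order wins.
#'
#' @param intervals an [interval_set()].
#' @param chrom,pos parallel vectors of query points (0-based).
#' @return Integer vector: row index of the containing interval, NA if none.
#' @export
interval_lookup <- function(intervals, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  hit <- rep(NA_integer_, length(pos))
  if (nrow(intervals) == 0 || length(pos) == 0) return(hit)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ii <- which(intervals$chrom == ch)
    if (length(ii) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[qi], width = 1L),
      IRanges::IRanges(start = intervals$start[ii],
                       end = intervals$end[ii] - 1L),
      select = "first")
    hit[qi] <- ii[ov]
  }
  hit
}

#' Write peak pairs as TSV
#'
#' Columns: chrom, w_summit, c_summit, midpoint, span, occupancy, sample.
#'
#' @param pairs a peak-pair data frame (see [pair_peaks()]).
#' @param path output file.
#' @export
write_peak_pairs <- function(pairs, path) {
  cols <- c("chrom", "w_summit", "c_summit", "midpoint", "span",
            "occupancy", "sample")
  stopifnot(all(cols %in% names(pairs)))
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read peak pairs written by [write_peak_pairs()]
#'
#' @param path TSV file.
#' @return Peak-pair data frame.
#' @export
read_peak_pairs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
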