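mktss <- function(gene_id, tss, strand = "+", chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = as.integer(tss))
}

test_that("binning relative to the TSS is strand-oriented with floor bins", {
  tss <- mktss(c("plus", "minus"), c(1000, 1000), strand = c("+", "-"),
               chrom = c("chr1", "chr2"))
  tags <- tag_dataset(c("chr1", "chr2", "chr1"), c("W", "C", "W"),
                      c(1055, 945, 1000))
  pm <- bin_relative_to_tss(tags, tss, bin = 10, window = 500)
  m <- pm$counts$same
  # + gene, tag at TSS+55 -> bin [50,60)
  expect_equal(unname(m["plus", "50"]), 1)
  # - gene, tag at TSS-55 -> oriented offset +55 -> same bin
  expect_equal(unname(m["minus", "50"]), 1)
  # offset exactly 0 -> bin [0,10)
  expect_equal(unname(m["plus", "0"]), 1)
  expect_equal(ncol(m), 2 * 500 / 10)
})

test_that("tag strand is re-expressed relative to the gene", {
  tss <- mktss("minus", 1000, strand = "-")
  # on a minus-strand gene a C tag is sense ("same"), a W tag antisense
  tags <- tag_dataset(c("chr1", "chr1"), c("C", "W"), c(980, 1020))
  pm <- bin_relative_to_tss(tags, tss, bin = 10, window = 100)
  expect_equal(sum(pm$counts$same), 1)
  expect_equal(unname(pm$counts$same["minus", "20"]), 1)   # offset +20
  expect_equal(sum(pm$counts$opposite), 1)
  expect_equal(unname(pm$counts$opposite["minus", "-20"]), 1)
})

test_that("binning conserves tags within the window", {
  set.seed(17)
  tss <- mktss(sprintf("g%d", 1:10), seq(5000, 50000, by = 5000),
               strand = sample(c("+", "-"), 10, TRUE))
  pos <- sample.int(55000, 2000, replace = TRUE)
  tags <- tag_dataset(rep("chr1", 2000),
                      sample(c("W", "C"), 2000, TRUE), pos)
  pm <- bin_relative_to_tss(tags, tss, bin = 10, window = 500)
  # oracle: count tags within [-500, 500) of each TSS, orientation-aware
  expanded <- rep(tags$pos, tags$count)
  total <- 0
  for (i in 1:10) {
    off <- if (tss$strand[i] == "+") expanded - tss$tss[i]
           else tss$tss[i] - expanded
    total <- total + sum(off >= -500 & off < 500)
  }
  expect_equal(profile_total(pm), total)
})

test_that("peak-pair matrices are unstranded and conserve locations", {
  tss <- mktss(c("g1", "g2"), c(1000, 3000))
  pairs <- data.frame(chrom = "chr1", midpoint = c(980, 1050, 2960),
                      occupancy = 5L)
  pm <- bin_relative_to_tss(pairs, tss, bin = 10, window = 500)
  expect_false(is.list(pm$counts))
  expect_equal(sum(pm$counts), 3)
  expect_equal(unname(pm$counts["g1", "-20"]), 1)
})

test_that("input normalization is an RPKM ratio with missing-not-infinite bins", {
  tss <- mktss("g1", 1000)
  chip <- bin_relative_to_tss(
    data.frame(chrom = "chr1", midpoint = c(995, 996, 1005)), tss,
    bin = 10, window = 20)
  input <- bin_relative_to_tss(
    data.frame(chrom = "chr1", midpoint = c(991, 1003)), tss,
    bin = 10, window = 20)
  norm <- normalize_by_input(chip, input, chip_total = 3, input_total = 2)
  # bin [-10,0): chip 2 of 3 tags, input 1 of 2 -> RPKM ratio (2/3)/(1/2)
  expect_equal(unname(norm$counts["g1", "-10"]), (2 / 3) / (1 / 2))
  # input-empty bin is NA, not Inf
  expect_true(is.na(norm$counts["g1", "-20"]))
  expect_false(any(is.infinite(norm$counts)))
  # flat chip over flat input is identically 1
  flat_tags <- data.frame(chrom = "chr1", midpoint = 981:1020)
  flat <- bin_relative_to_tss(flat_tags, tss, bin = 10, window = 20)
  ones <- normalize_by_input(flat, flat, chip_total = 40, input_total = 40)
  expect_true(all(ones$counts == 1))
  # mismatched bin structure is an error
  other <- bin_relative_to_tss(flat_tags, tss, bin = 20, window = 40)
  expect_error(normalize_by_input(chip, other), "mismatched")
})

test_that("composite averages are percent-of-total and mirror under reversal", {
  set.seed(23)
  L <- 200000L
  tss <- mktss(sprintf("g%d", 1:8), seq(20000, 160000, by = 20000),
               strand = sample(c("+", "-"), 8, TRUE))
  tags <- tag_dataset(rep("chr1", 500), sample(c("W", "C"), 500, TRUE),
                      sample.int(L, 500))
  pm <- bin_relative_to_tss(tags, tss, bin = 10, window = 500)
  tr <- composite_average(pm, "same")
  expect_equal(sum(tr$value), 100, tolerance = 1e-9)
  # single gene, single occupied bin -> that bin carries all 100%
  one <- bin_relative_to_tss(data.frame(chrom = "chr1", midpoint = 985),
                             mktss("g", 1000), bin = 10, window = 500)
  tr1 <- composite_average(one)
  expect_equal(tr1$value[tr1$bin_start == -20], 100)

  # coordinate reversal: reflecting all coordinates negates every offset,
  # so the composite at offset o must equal the mirrored composite at -o
  pm1 <- bin_relative_to_tss(tags, tss, bin = 1, window = 100)
  tr1 <- composite_average(pm1, "same")
  tss_m <- tss
  tss_m$tss <- L - tss$tss
  tags_m <- tag_dataset(tags$chrom, tags$strand, L - tags$pos,
                        count = tags$count)
  pm_m <- bin_relative_to_tss(tags_m, tss_m, bin = 1, window = 100)
  tr_m <- composite_average(pm_m, "same")
  common <- intersect(tr1$bin_start, -tr_m$bin_start)
  expect_gt(length(common), 150)
  orig <- tr1$value[match(common, tr1$bin_start)]
  mirr <- tr_m$value[match(-common, tr_m$bin_start)]
  expect_equal(orig / sum(orig), mirr / sum(mirr), tolerance = 1e-9)
})

test_that("row sorting is stable and returns a reusable permutation", {
  pm <- list(gene_id = c("a", "b", "c"))
  expect_equal(sort_rows(pm, c(30, 10, 20)), c(2, 3, 1))
  expect_equal(sort_rows(pm, c(1, 1, 0)), c(3, 1, 2))  # stable on ties
  # one linked permutation applies identically to several matrices
  perm <- sort_rows(pm, c(3, 1, 2))
  m1 <- matrix(1:6, 3, dimnames = list(c("a", "b", "c"), NULL))
  m2 <- matrix(7:12, 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(rownames(m1[perm, ]), rownames(m2[perm, ]))
})

test_that("modal offsets report ties to the smallest absolute offset", {
  tss <- mktss("g", 1000)
  pairs <- data.frame(chrom = "chr1",
                      midpoint = c(rep(979, 10), rep(981, 2)))
  mo <- peak_pair_mode_offset(pairs, tss)
  expect_equal(mo$mode, -21)
  expect_equal(mo$histogram$n[mo$histogram$offset == -21], 10)
  tie <- peak_pair_mode_offset(
    data.frame(chrom = "chr1", midpoint = c(970, 1020)), tss)
  expect_equal(tie$mode, 20)  # |-30| vs |20|: smallest magnitude wins
  expect_error(peak_pair_mode_offset(
    data.frame(chrom = "chr1", midpoint = 99999), tss), "no locations")
})
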