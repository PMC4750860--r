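test_that("adjacent distances are within-group and adjacency-only", {
  loc <- data.frame(group = c("i1", "i1", "i2", "i2", "i2", "i3"),
                    midpoint = c(160, 100, 300, 100, 200, 50),
                    occupancy = c(6, 5, 30, 10, 20, 99))
  d <- inter_location_distances(loc)
  expect_equal(d$distance[d$group == "i1"], 60)
  expect_equal(d$left_occ[d$group == "i1"], 5)  # sorted by coordinate
  # three locations give two adjacent records, not three pairwise
  expect_equal(sum(d$group == "i2"), 2)
  expect_equal(d$distance[d$group == "i2"], c(100, 100))
  # singleton groups contribute nothing
  expect_false("i3" %in% d$group)
})

test_that("sliding-window SD matches a direct loop and handles edge cases", {
  set.seed(3)
  recs <- data.frame(group = "g", distance = sample.int(300, 100, TRUE),
                     left_occ = rexp(100, 1 / 50), right_occ = rexp(100, 1 / 50))
  sw <- sliding_window_sd(recs, window = 30)
  expect_equal(nrow(sw), 100 - 30 + 1)
  # brute-force oracle
  ord <- order(recs$distance)
  r <- recs[ord, ]
  for (i in c(1, 35, 71)) {
    w <- i:(i + 29)
    expect_equal(sw$sd[i], sd(r$left_occ[w]))
    expect_equal(sw$distance[i], median(r$distance[w]))
  }
  # constant occupancies give an identically zero trace
  const <- recs
  const$left_occ <- 7
  expect_true(all(sliding_window_sd(const, window = 30)$sd == 0))
  expect_error(sliding_window_sd(recs[1:10, ], window = 30), "at least 30")
})

test_that("correlated short-range and independent long-range occupancies separate in the SD trace", {
  # planted regimes: adjacent complexes < 70 bp apart share occupancy
  # (correlated), those further apart are independent
  set.seed(41)
  n <- 300
  dist <- c(sample(40:69, n / 2, TRUE), sample(90:250, n / 2, TRUE))
  base <- rexp(n, 1 / 50)
  left <- ifelse(dist < 70, base, rexp(n, 1 / 50))
  right <- ifelse(dist < 70, base * 2^rnorm(n, 0, 0.1), rexp(n, 1 / 50))
  recs <- data.frame(group = "g", distance = dist,
                     left_occ = left, right_occ = right)
  # correlation contrast
  ac <- adjacent_occupancy_correlation(recs, breaks = c(0, 70, 300))
  expect_gt(ac$r[1], 0.8)
  expect_lt(abs(ac$r[2]), 0.25)
  # SD of the left-right difference is lower in the correlated regime
  diff_sd_short <- sd(left[dist < 70] - right[dist < 70])
  diff_sd_long <- sd(left[dist >= 70] - right[dist >= 70])
  expect_lt(diff_sd_short, diff_sd_long / 2)
})

test_that("stratified correlations handle exact, null and tiny strata", {
  recs <- data.frame(group = "g", distance = rep(c(10, 110), each = 50),
                     left_occ = 1:100, right_occ = 1:100)
  ac <- adjacent_occupancy_correlation(recs, breaks = c(0, 100, 200))
  expect_equal(ac$r, c(1, 1))
  expect_equal(ac$n, c(50L, 50L))
  # independent occupancies: |r| small at n = 500
  set.seed(8)
  null <- data.frame(group = "g", distance = sample.int(200, 500, TRUE),
                     left_occ = rexp(500), right_occ = rexp(500))
  acn <- adjacent_occupancy_correlation(null, breaks = c(0, 300))
  expect_lt(abs(acn$r), 0.1)
  tiny <- adjacent_occupancy_correlation(recs[1:2, ], breaks = c(0, 100))
  expect_true(is.na(tiny$r))
})

test_that("moving-average trend is median-centered and collapses to the diagonal", {
  set.seed(5)
  x <- rexp(300, 1 / 40)
  tr <- moving_average_trend(x, x, window = 100)
  expect_equal(tr$x, tr$y)  # y = x exactly lies on the diagonal
  expect_equal(nrow(tr), 201)
  # window = n collapses to the single point (mean, mean)
  one <- moving_average_trend(x, x, window = 300)
  lx <- log2(x + 1)
  expect_equal(one$x, mean(lx - median(lx)))
  # the pre-windowed series are median-centered by construction
  expect_equal(median(log2_median_centered(x)), 0)
  # brute-force windowed mean oracle
  y <- rexp(300, 1 / 40)
  tr2 <- moving_average_trend(x, y, window = 50)
  lx <- log2_median_centered(x); ly <- log2_median_centered(y)
  ord <- order(lx)
  expect_equal(tr2$x[1], mean(lx[ord][1:50]))
  expect_equal(tr2$y[113], mean(ly[ord][113:162]))
})

test_that("pairwise correlations are 1 on self, -1 on anti-sorted, zero-excluding", {
  v <- c(0, 1, 2, 4, 8, 16, 32)
  r <- pairwise_correlations(list(a = v, b = v))
  expect_equal(unname(r["a", "b"]), 1)
  # anti-sorted series: -1 up to the +1 pseudocount curvature
  anti <- pairwise_correlations(list(a = 2^(1:20), b = 2^(20:1)))
  expect_equal(unname(anti["a", "b"]), -1, tolerance = 1e-3)
  # genes with a zero in either series are dropped from that pair
  with_zero <- pairwise_correlations(list(a = c(0, 2, 4, 8, 16),
                                          b = c(1000, 2, 4, 8, 16)))
  expect_equal(unname(with_zero["a", "b"]), 1)
})

test_that("noisy RNA attenuates correlation according to the closed form", {
  # log2 rna = log2 occupancy + N(0, sd): with signal variance s2,
  # rho = s / sqrt(s2 + sd^2)
  sdn <- 0.5
  rs <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_genes = 400, n_trna = 0, n_chroms = 2,
                      chrom_length = 1e6, divergent_fraction = 0,
                      rna_noise_sd = sdn, seed = 1000 + seed)
    ann <- generate_annotations(cfg)
    truth <- ann$truth[ann$truth$factor == "TFIIB", ]
    rna <- simulate_rna_levels(truth, cfg)
    cor(log2(rna$occupancy), log2(rna$rna))
  }, numeric(1))
  s2 <- local({
    set.seed(99)
    cfg <- sim_config(n_genes = 400, seed = 1)
    # variance of log2 occupancy under the generator's negative binomial
    occ <- pmax(1, rnbinom(20000, mu = cfg$tags_per_site_mean,
                           size = cfg$tags_dispersion))
    var(log2(occ))
  })
  rho <- sqrt(s2) / sqrt(s2 + sdn^2)
  expect_equal(mean(rs), rho, tolerance = 0.05)
  # monotone attenuation over an sd grid
  r_by_sd <- vapply(c(0, 0.5, 1, 2, 4), function(sdv) {
    cfg <- sim_config(n_genes = 300, n_trna = 0, divergent_fraction = 0,
                      rna_noise_sd = sdv, seed = 77)
    ann <- generate_annotations(cfg)
    rna <- simulate_rna_levels(ann$truth[ann$truth$factor == "TFIIB", ], cfg)
    cor(log2(rna$occupancy), log2(rna$rna))
  }, numeric(1))
  expect_equal(r_by_sd[1], 1)
  expect_true(all(diff(r_by_sd) < 0))
})
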