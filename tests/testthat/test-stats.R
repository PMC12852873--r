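test_that("Welch t matches the closed form and its symmetries", {
  r <- welch_t(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$statistic, 9 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-9)
  same <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(welch_t(a, b)$statistic, -welch_t(b, a)$statistic)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  expect_equal(welch_t(a + 7, b + 7)$p_value, welch_t(a, b)$p_value)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Kruskal-Wallis gives H = 7.2 on the hand-ranked 3x3 example", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  ident <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Kruskal-Wallis p agrees with the exhaustive permutation null", {
  groups <- list(c(1.2, 3.4, 0.5), c(2.1, 4.8, 3.9), c(0.1, 1.1))
  p_perm <- kw_perm_p(groups)       # exact enumeration over 560 labelings
  p_chisq <- kruskal_wallis(groups)$p_value
  expect_lt(abs(p_chisq - p_perm), 0.02)
})

test_that("Dunn post hoc: z signs, Bonferroni bound, and separation power", {
  two_same <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(two_same$z, 0)
  expect_equal(two_same$adjusted_p, 1)
  set.seed(8)
  g <- list(a = rnorm(12), b = rnorm(12, 1), c = rnorm(12, 3))
  d <- dunn_posthoc(g)
  expect_equal(nrow(d), 3)
  expect_true(all(d$adjusted_p >= d$p_value))
  expect_true(all(d$adjusted_p <= 1))
  ## for two groups, |z| equals sqrt(H) from Kruskal-Wallis
  g2 <- list(x = c(3, 1, 4, 1, 5), y = c(9, 2, 6, 5, 3.5))
  expect_equal(abs(dunn_posthoc(g2)$z),
               sqrt(kruskal_wallis(g2)$statistic), tolerance = 1e-12)
  ## three well-separated groups: all pairwise adjusted p < 0.01
  set.seed(10)
  far <- list(rnorm(20, 0), rnorm(20, 5), rnorm(20, 10))
  expect_true(all(dunn_posthoc(far)$adjusted_p < 0.01))
})

test_that("Wilcoxon rank-sum: exact enumeration and branch agreement", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)   # 2/C(4,2)
  expect_match(r$method, "exact")
  expect_equal(wilcoxon_rank_sum(5, 5)$p_value, 1)
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6) + 0.5
  pe <- wilcoxon_rank_sum(x, y)$p_value               # exact branch (n = 12)
  pa <- wilcoxon_rank_sum(c(x, 100), c(y, -100))$p_value
  ## branches agree within 0.02 at the switch size on tie-free data
  pa12 <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value)
  expect_lt(abs(pe - pa12), 0.02)
  ## adding a constant changes nothing
  expect_equal(wilcoxon_rank_sum(x + 3, y + 3)$p_value, pe)
})

test_that("binned track correlation matches the closed-form Pearson", {
  runs <- function(v) signal_track(data.frame(
    chrom = "chr1", start = seq(0, 4000, 1000)[1:5],
    end = seq(1000, 5000, 1000), value = v))
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 7)
  r <- binned_pearson(runs(a), runs(b), bin_size = 1000,
                      chrom_sizes = c(chr1 = 5000))
  av <- a * 1000; bv <- b * 1000
  closed <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(r$r, closed, tolerance = 1e-12)
  expect_equal(r$n_bins, 5)
  expect_equal(binned_pearson(runs(a), runs(a), 1000,
                              c(chr1 = 5000))$r, 1)
  expect_equal(binned_pearson(runs(a), runs(-a), 1000,
                              c(chr1 = 5000))$r, -1)
  expect_error(binned_pearson(runs(a), runs(b), 5000, c(chr1 = 5000)),
               "fewer than 2 bins")
  ## restriction to sites drops non-overlapping bins
  rr <- binned_pearson(runs(a), runs(b), 1000, c(chr1 = 5000),
                       restrict = genomic_intervals("chr1", c(100, 3100),
                                                    c(200, 3200)))
  expect_equal(rr$n_bins, 2)
})

test_that("tumor volume and its scaling law follow D*d^2/2", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(10, 10), 500)
  expect_equal(tumor_volume(8, 6), 4 * tumor_volume(8, 3))
  expect_error(tumor_volume(5, 10), "exceeds")
  expect_error(tumor_volume(5, 0), "positive")
})

test_that("nuclear shape index is the region-fraction-weighted mean ratio", {
  one <- data.frame(region = "r1", fraction = 1,
                    long_axis = c(2.0, 2.2, 1.8) * 5, orth_axis = 5)
  expect_equal(nuclear_shape_index(one), 2.0)
  two <- rbind(
    data.frame(region = "r1", fraction = 0.5, long_axis = 10, orth_axis = 5),
    data.frame(region = "r1", fraction = 0.5, long_axis = 10, orth_axis = 5),
    data.frame(region = "r1", fraction = 0.5, long_axis = 10, orth_axis = 5),
    data.frame(region = "r2", fraction = 0.5, long_axis = 6, orth_axis = 6),
    data.frame(region = "r2", fraction = 0.5, long_axis = 6, orth_axis = 6),
    data.frame(region = "r2", fraction = 0.5, long_axis = 6, orth_axis = 6))
  expect_equal(nuclear_shape_index(two), 1.5)
  round_all <- one; round_all$long_axis <- round_all$orth_axis
  expect_equal(nuclear_shape_index(round_all), 1.0)
  bad <- one; bad$fraction <- 0.7
  expect_error(nuclear_shape_index(bad), "sum to 1")
})

test_that("nuclear density converts between the 500-um2 square and mm2", {
  expect_equal(nuclear_density(0)$per_500um2, 0)
  d <- nuclear_density(25)
  expect_equal(d$per_500um2, 25)
  expect_equal(d$per_mm2, 50000)
  expect_equal(nuclear_density(50)$per_mm2, 2 * d$per_mm2)
})

test_that("stats_report assembles comparisons with Bonferroni adjustment", {
  set.seed(3)
  rep <- stats_report(list(
    shift = list(groups = list(rnorm(10), rnorm(10, 3)), test = "welch_t"),
    ranks = list(groups = list(1:5, 6:10, 11:15), test = "kruskal_wallis"),
    mw = list(groups = list(rnorm(8), rnorm(8)), test = "wilcoxon")))
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$adjusted_p >= rep$p_value))
  expect_true(all(rep$adjusted_p <= 1))
})
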