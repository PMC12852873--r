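## Statistical tests and quantitative phenotype formulas used across the
## pipeline, each returning a uniform test-result record.

.test_result <- function(method, statistic, df = NA_real_, p_value,
                         adjusted_p = NA_real_, adjust_method = "none") {
  list(method = method, statistic = unname(statistic), df = unname(df),
       p_value = unname(p_value), adjusted_p = unname(adjusted_p),
       adjust_method = adjust_method)
}

#' Welch (heteroscedastic) two-sample t test
#'
#' Two-tailed t test with unequal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric samples, each of size >= 2
#' @return test-result list with `statistic`, `df`, `p_value`
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(.test_result("Welch t", 0, NA_real_, 1))
    stop("both samples have zero variance with different means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  .test_result("Welch t", ht$statistic, ht$parameter, ht$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of two or more independent groups, with the
#' standard ties correction; p from the chi-square approximation on
#' k - 1 degrees of freedom.
#'
#' @param groups list of numeric samples
#' @return test-result list
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, sum(lengths(groups)) >= 3)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1)
    return(.test_result("Kruskal-Wallis", 0, length(groups) - 1, 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  .test_result("Kruskal-Wallis", kt$statistic, kt$parameter, kt$p.value)
}

#' Dunn's post-hoc test with Bonferroni adjustment
#'
#' After a Kruskal-Wallis test, compares every pair of groups using the
#' pooled-rank z statistic
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))`
#' where `Ri` are mean ranks and `T = sum(t^3 - t) / (12 (N - 1))` corrects
#' for ties. Two-tailed p-values are Bonferroni-adjusted over the
#' `k(k-1)/2` pairs.
#'
#' @param groups named or unnamed list of numeric samples
#' @return data.frame, one row per pair: `group1, group2, z, p_value,
#'   adjusted_p`
#' @export
dunn_posthoc <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(vals)
  r <- rank(vals)
  mean_rank <- tapply(r, g, mean)
  n <- lengths(groups)
  tie_tab <- table(vals)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    c(z = unname(z), p = unname(p))
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = res["z", ], p_value = res["p", ],
             adjusted_p = pmin(1, res["p", ] * n_pairs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is <= 12 and there are
#' no ties; otherwise the normal approximation with midranks, ties
#' variance correction and continuity correction.
#'
#' @param x,y numeric samples
#' @return test-result list; `statistic` is the Mann-Whitney U (W in R)
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1)
    return(.test_result("Wilcoxon rank-sum", length(x) * length(y) / 2,
                        NA_real_, 1))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .test_result(if (exact) "Wilcoxon rank-sum (exact)"
               else "Wilcoxon rank-sum (normal approx.)",
               wt$statistic, NA_real_, wt$p.value)
}

#' Pearson correlation of two tracks over genomic bins
#'
#' Partitions each chromosome into fixed-size bins (optionally restricted
#' to bins overlapping a given set of sites, e.g. binding sites of a
#' reference factor), sums each track's signal per bin, and returns the
#' Pearson correlation of the two bin vectors.
#'
#' @param track_a,track_b `signal_track`s on the same genome
#' @param bin_size bin width in bp
#' @param chrom_sizes named vector of chromosome lengths; defaults to the
#'   maximum run end per chromosome across both tracks
#' @param restrict optional interval data.frame; only bins overlapping
#'   these sites are used
#' @return list with `r`, `n_bins`, and the per-bin sums
#' @export
binned_pearson <- function(track_a, track_b, bin_size,
                           chrom_sizes = NULL, restrict = NULL) {
  stopifnot(bin_size > 0)
  if (is.null(chrom_sizes)) {
    ends <- c(tapply(track_a$end, track_a$chrom, max),
              tapply(track_b$end, track_b$chrom, max))
    chrom_sizes <- tapply(ends, names(ends), max)
  }
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    genomic_intervals(ch, starts, pmin(starts + bin_size, chrom_sizes[[ch]]))
  }))
  if (!is.null(restrict) && nrow(restrict) > 0) {
    hits <- GenomicRanges::findOverlaps(.as_granges(bins), .as_granges(restrict))
    bins <- bins[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
  }
  if (nrow(bins) < 2) stop("fewer than 2 bins; enlarge the genome or shrink bins")
  a <- window_signal(track_a, bins)
  b <- window_signal(track_b, bins)
  list(r = stats::cor(a, b), n_bins = nrow(bins), bins_a = a, bins_b = b)
}

#' Tumor volume from caliper diameters
#'
#' `volume = D * d^2 / 2` (mm^3) with D the long and d the short diameter.
#'
#' @param D long diameter (mm)
#' @param d short diameter (mm)
#' @return volume in mm^3
#' @export
tumor_volume <- function(D, d) {
  if (any(d <= 0)) stop("diameters must be positive")
  if (any(d > D)) stop("short diameter exceeds long diameter")
  D * d^2 / 2
}

#' Region-weighted nuclear shape index for a tumor
#'
#' Within each histomorphologically distinct region, the long/orthogonal
#' axis ratio is averaged over the three measured nuclei; region means are
#' then weighted by the fractional area contribution of each region.
#'
#' @param regions data.frame, one row per (region, nucleus) with columns
#'   `region`, `fraction` (region area fraction, constant within region),
#'   `long_axis`, `orth_axis` (um)
#' @return weighted mean axis ratio (>= 1)
#' @export
nuclear_shape_index <- function(regions) {
  stopifnot(all(c("region", "fraction", "long_axis", "orth_axis") %in%
                names(regions)))
  if (any(regions$long_axis < regions$orth_axis))
    stop("long axis shorter than orthogonal axis")
  per_region <- do.call(rbind, lapply(split(regions, regions$region), function(rr) {
    if (nrow(rr) != 3) stop("each region needs exactly 3 nucleus measurements")
    data.frame(fraction = rr$fraction[1],
               mean_ratio = mean(rr$long_axis / rr$orth_axis))
  }))
  if (abs(sum(per_region$fraction) - 1) > 1e-6)
    stop("region fractions must sum to 1")
  sum(per_region$fraction * per_region$mean_ratio)
}

#' Nuclear density
#'
#' Reported as nuclei per 500 um^2 square (the measurement unit);
#' `per_mm2` gives the equivalent count per mm^2 (1 mm^2 = 2000 squares).
#'
#' @param count nuclei counted in one 500 um^2 square
#' @return list with `per_500um2` and `per_mm2`
#' @export
nuclear_density <- function(count) {
  stopifnot(all(count >= 0))
  list(per_500um2 = count, per_mm2 = count * 1e6 / 500)
}

#' Assemble a group-comparison report
#'
#' Runs the named test on each comparison and collects a tidy table.
#'
#' @param comparisons named list; each element is a list with `groups`
#'   (list of numeric vectors) and `test` (one of `"welch_t"`,
#'   `"kruskal_wallis"`, `"wilcoxon"`)
#' @return data.frame: comparison, test, statistic, df, p_value,
#'   adjusted_p (Bonferroni over the report's rows)
#' @export
stats_report <- function(comparisons) {
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    res <- switch(cmp$test,
      welch_t = welch_t(cmp$groups[[1]], cmp$groups[[2]]),
      kruskal_wallis = kruskal_wallis(cmp$groups),
      wilcoxon = wilcoxon_rank_sum(cmp$groups[[1]], cmp$groups[[2]]),
      stop("unknown test: ", cmp$test))
    data.frame(comparison = nm, test = res$method, statistic = res$statistic,
               df = res$df, p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- pmin(1, out$p_value * nrow(out))
  out
}
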