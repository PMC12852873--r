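mk_peakset <- function(chrom, center, qvalue, width = 1000) {
  data.frame(chrom = chrom, start = center - width / 2,
             end = center + width / 2, name = "pk", enrichment = 1,
             qvalue = qvalue)
}

test_that("mark presence requires a passing peak overlapping the window", {
  win <- genomic_intervals("chr1", 8000, 12000)
  ps <- list(H3K4me3 = mk_peakset("chr1", 10000, 0.0009))
  sig <- signature_at(win, ps)
  expect_true(sig[1, "H3K4me3"])
  expect_true(is.na(sig[1, "H3K27me3"]))          # missing peakset -> unknown
  ## boundary: q-value exactly at the threshold fails the strict filter
  sig2 <- signature_at(win, list(H3K4me3 = mk_peakset("chr1", 10000, 0.001)))
  expect_false(sig2[1, "H3K4me3"])
  sig3 <- signature_at(win, list(H3K4me3 = mk_peakset("chr1", 50000, 1e-6)))
  expect_false(sig3[1, "H3K4me3"])                # no overlap
})

test_that("promoter rule set maps signatures to the expected classes", {
  flags <- function(ub = FALSE, k4 = FALSE, ac = FALSE, me3 = FALSE,
                    me1 = FALSE)
    c(H2AK119ub = ub, H3K4me3 = k4, H3K27ac = ac, H3K27me3 = me3,
      H3K4me1 = me1)
  expect_equal(classify_promoter(flags(ub = TRUE, k4 = TRUE, ac = TRUE)),
               "SAT_PATTERN")
  expect_equal(classify_promoter(flags(k4 = TRUE, me3 = TRUE)), "BIVALENT")
  expect_equal(classify_promoter(flags(me3 = TRUE)), "REPRESSED")
  expect_equal(classify_promoter(flags(k4 = TRUE, ac = TRUE)), "ACTIVE")
  expect_equal(classify_promoter(flags()), "UNCLASSIFIED")
  ## SAT and BIVALENT are disjoint: H3K27me3 always separates them
  for (code in 0:31) {
    f <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L, 16L)))
    names(f) <- c("H2AK119ub", "H3K4me3", "H3K27ac", "H3K27me3", "H3K4me1")
    cls <- classify_promoter(f)
    if (cls == "SAT_PATTERN") expect_false(f[["H3K27me3"]])
    if (cls == "BIVALENT") expect_true(f[["H3K27me3"]])
  }
  ## unknown flag among the defining marks -> UNCLASSIFIED
  f <- flags(k4 = TRUE, ac = TRUE); f["H2AK119ub"] <- NA
  expect_equal(classify_promoter(f), "UNCLASSIFIED")
})

test_that("enhancer rule requires H3K4me1 + H3K27ac and splits on H2AK119ub", {
  flags <- function(me1, ac, ub)
    c(H2AK119ub = ub, H3K4me3 = FALSE, H3K27ac = ac, H3K27me3 = FALSE,
      H3K4me1 = me1)
  expect_equal(classify_enhancer(flags(TRUE, TRUE, TRUE)), "ENHANCER_UB_POS")
  expect_equal(classify_enhancer(flags(TRUE, TRUE, FALSE)), "ENHANCER_UB_NEG")
  expect_equal(classify_enhancer(flags(TRUE, FALSE, TRUE)), "NOT_ENHANCER")
  expect_error(
    classify_enhancer(matrix(flags(TRUE, TRUE, TRUE), nrow = 1,
                             dimnames = list(NULL, names(flags(T, T, T)))),
                      windows = genomic_intervals("chr1", 9000, 9500),
                      promoter_windows = genomic_intervals("chr1", 8000, 12000)),
    "not distal")
})

test_that("classification is invariant to peak order and matches truth at zero noise", {
  r <- measured_recovery(small_cfg(seed = 5))
  expect_equal(r$promoter, 1)
  expect_equal(r$enhancer, 1)
  g <- r$genome
  m <- simulate_marks_and_peaks(g)
  ann <- g$promoters[, c("gene_id", "chrom", "tss", "strand", "gene_label")]
  shuffled <- lapply(m$peaksets, function(pk) {
    set.seed(1); pk[sample(nrow(pk)), , drop = FALSE]
  })
  expect_equal(classify_promoters(ann, shuffled)$class,
               classify_promoters(ann, m$peaksets)$class)
})

test_that("TSS peak profiling retains exactly the peaks near a TSS", {
  prom <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     tss = c(10000, 60000), strand = "+",
                     gene_label = c("SAT", "MAT"))
  pk <- data.frame(chrom = "chr1",
                   start = c(7000, 8500, 59000, 30000),
                   end = c(7500, 9000, 59400, 30500),
                   name = paste0("p", 1:4), enrichment = 2, qvalue = 1e-4)
  prof <- profile_tss_peaks(pk, prom)
  expect_setequal(prof$name, c("p2", "p3"))   # p1 gap > 2 kb, p4 far away
  expect_equal(prof$gene_label[prof$name == "p3"], "MAT")
  ## count agrees with the all-pairs oracle on a random 200-peak fixture
  peaks <- random_intervals(200, seed = 21, chroms = "chr1",
                            max_pos = 3e5, max_width = 4000)
  peaks$name <- paste0("pk", seq_len(nrow(peaks)))
  peaks$enrichment <- 1; peaks$qvalue <- 1e-4
  prom2 <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      tss = seq(20000, 290000, length.out = 10),
                      strand = "+", gene_label = "none")
  win <- make_tss_window(prom2, 2000)
  oracle_n <- sum(apply(oracle_overlap_pairs(peaks, win), 1, any))
  prof2 <- profile_tss_peaks(peaks, prom2)
  expect_equal(nrow(prof2), oracle_n)
  expect_equal(anyDuplicated(prof2$name), 0)
})

test_that("peak shape boundary is strict and the default cut separates modes", {
  expect_equal(classify_peak_shape(8000), "BROAD")
  expect_equal(classify_peak_shape(400), "NARROW")
  expect_equal(classify_peak_shape(2000), "NARROW")   # boundary: strict >
  expect_equal(classify_peak_shape(2001), "BROAD")
  set.seed(2)
  widths <- c(rlnorm(100, log(400), 0.3), rlnorm(100, log(6000), 0.25))
  auto <- classify_peak_shape(widths, "auto")
  expect_equal(auto, rep(c("NARROW", "BROAD"), each = 100))
})

test_that("random promoter control is seeded, uniform, and bounded", {
  prom <- data.frame(gene_id = paste0("g", 1:20), chrom = "chr1",
                     tss = (1:20) * 50000, strand = "+", gene_label = "none")
  a <- select_random_promoters(prom, 5, seed = 42)
  b <- select_random_promoters(prom, 5, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(select_random_promoters(prom, 20, seed = 1)), 20)
  expect_error(select_random_promoters(prom, 21, seed = 1), "exceeds")
  ## selection frequency per promoter within 3 SD of the binomial expectation
  hits <- integer(20)
  for (s in 1:1000) {
    sel <- select_random_promoters(prom, 5, seed = s)
    hits[match(sel$gene_id, prom$gene_id)] <-
      hits[match(sel$gene_id, prom$gene_id)] + 1L
  }
  p <- 5 / 20
  sd3 <- 3 * sqrt(1000 * p * (1 - p))
  expect_true(all(abs(hits - 1000 * p) <= sd3))
})
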