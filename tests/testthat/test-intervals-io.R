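test_that("interval validation and TSS windows follow the half-open convention", {
  expect_error(genomic_intervals("chr1", 10, 10), "end")
  expect_error(genomic_intervals("chr1", -1, 10), "start")
  p <- data.frame(gene_id = c("a", "b"), chrom = "chr1", tss = c(10000, 1000))
  w <- make_tss_window(p, 2000)
  expect_equal(w$start, c(8000, 0))      # second window clipped at zero
  expect_equal(w$end, c(12000, 3000))
  expect_equal(w$end[1] - w$start[1], 4000)
})

test_that("pairwise overlap matches the definition and an all-pairs oracle", {
  a <- genomic_intervals("chr1", 0, 10)
  expect_false(interval_overlaps(a, genomic_intervals("chr1", 10, 20)))
  expect_true(interval_overlaps(a, genomic_intervals("chr1", 9, 20)))
  expect_false(interval_overlaps(a, genomic_intervals("chr2", 0, 10)))
  x <- random_intervals(40, seed = 11)
  y <- random_intervals(40, seed = 12)
  oracle <- oracle_overlap_pairs(x, y)
  for (i in seq_len(nrow(x)))
    expect_equal(as.vector(interval_overlaps(x[i, ], y)), oracle[i, ])
})

test_that("blacklist filtering removes any-overlap peaks, matching the oracle", {
  pk <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                   end = c(50, 200, 400), name = c("p1", "p2", "p3"),
                   enrichment = 1, qvalue = 1e-4)
  empty_bl <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
  expect_identical(filter_blacklist(pk, empty_bl), pk)
  bl <- genomic_intervals("chr1", c(110, 399), c(120, 500))  # inside; 1-bp overlap
  kept <- filter_blacklist(pk, bl)
  expect_equal(kept$name, "p1")
  x <- random_intervals(200, seed = 3)
  x$name <- paste0("p", seq_len(nrow(x)))
  x$qvalue <- 0; x$enrichment <- 0
  bl2 <- random_intervals(30, seed = 4)
  oracle_keep <- !apply(oracle_overlap_pairs(x, bl2), 1, any)
  expect_equal(filter_blacklist(x, bl2)$name, x$name[oracle_keep])
})

test_that("window_signal sums per-base signal and is additive over partitions", {
  tr <- signal_track(data.frame(chrom = "chr1", start = c(0, 100),
                                end = c(100, 200), value = c(1, 2)))
  w4k <- signal_track(data.frame(chrom = "chr1", start = 0, end = 4000,
                                 value = 1))
  expect_equal(window_signal(w4k, genomic_intervals("chr1", 0, 4000)), 4000)
  expect_equal(window_signal(tr, genomic_intervals("chr1", 150, 250)), 100)
  empty <- signal_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric()))
  expect_warning(v <- window_signal(empty, genomic_intervals("chr1", 0, 10)))
  expect_equal(v, 0)
  ## additivity over a random partition
  set.seed(9)
  cuts <- sort(sample(1:3999, 5))
  parts <- genomic_intervals("chr1", c(0, cuts), c(cuts, 4000))
  whole <- genomic_intervals("chr1", 0, 4000)
  tr2 <- signal_track(data.frame(chrom = "chr1",
                                 start = seq(0, 3900, 100),
                                 end = seq(100, 4000, 100),
                                 value = runif(40)))
  expect_equal(sum(window_signal(tr2, parts)), window_signal(tr2, whole))
})

test_that("merge_tracks depth-normalizes then averages per base", {
  t1 <- signal_track(data.frame(chrom = "chr1", start = 0, end = 100, value = 2))
  t2 <- signal_track(data.frame(chrom = "chr1", start = 0, end = 100, value = 4))
  m <- merge_tracks(list(t1, t2))
  ## equal depths would give 3, but depth normalization first rescales
  ## each to the mean total (300): t1 -> 3, t2 -> 3, mean = 3
  expect_equal(window_signal(m, genomic_intervals("chr1", 0, 100)), 300)
  expect_equal(unname(as.data.frame(m)$value), 3)
  single <- merge_tracks(list(t1))
  expect_equal(window_signal(single, genomic_intervals("chr1", 0, 100)),
               window_signal(t1, genomic_intervals("chr1", 0, 100)))
  same <- merge_tracks(list(t2, t2))
  expect_equal(window_signal(same, genomic_intervals("chr1", 0, 100)),
               window_signal(t2, genomic_intervals("chr1", 0, 100)))
  zero <- signal_track(data.frame(chrom = "chr1", start = 0, end = 10, value = 0))
  expect_error(merge_tracks(list(t1, zero)), "depth-normalize")
})

test_that("narrowPeak decode/round-trip and BED defaults are dialect-exact", {
  tmp <- withr::local_tempfile(fileext = ".narrowPeak")
  pk <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2", "chr10"),
                   start = c(100, 5000, 30, 700, 42),
                   end = c(600, 5400, 130, 1500, 90),
                   name = paste0("pk", 1:5), score = c(10, 20, 30, 40, 50),
                   strand = ".", enrichment = c(5.5, 2.25, 8, 1.5, 3),
                   pvalue_mlog = c(5, 6, 7, 8, 9),
                   qvalue_mlog = c(3, 4.5, 2, 6, 3.25),
                   peak_offset = c(250, 200, 50, 400, 24),
                   qvalue = 10^(-c(3, 4.5, 2, 6, 3.25)))
  write_peaks(pk, tmp)
  back <- read_peaks(tmp)
  expect_equal(back$qvalue[back$name == "pk1"], 0.001)  # -log10 decoding
  tmp2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  ## minimal BED3 dialect
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  b <- read_peaks(bed)
  expect_equal(b$enrichment, 0)
  expect_equal(b$qvalue, 0)
  ## malformed lines name the line number
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), bad)
  expect_error(read_peaks(bad), "line 2")
  rev <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t30\t20", rev)
  expect_error(read_peaks(rev), "end <= start")
})

test_that("bedGraph and BEDPE round-trip byte-identically", {
  tr <- signal_track(data.frame(chrom = c("chr1", "chr1", "chr2"),
                                start = c(0, 500, 100),
                                end = c(100, 900, 200),
                                value = c(1.5, 2, 0.25)))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(read_bedgraph(f), f2)
  expect_identical(readLines(f), readLines(f2))

  lp <- data.frame(chrom1 = "chr1", start1 = c(100, 9000), end1 = c(600, 9500),
                   chrom2 = "chr1", start2 = c(50000, 52000),
                   end2 = c(50500, 52500), name = c("l1", "l2"),
                   loop_score = c(2.5, 1), fdr = c(0.01, 0.2))
  g <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(lp, g)
  g2 <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(read_loops(g), g2)
  expect_identical(readLines(g), readLines(g2))
  expect_equal(read_loops(g)$fdr, c(0.01, 0.2))
})

test_that("TSS tables round-trip with validation", {
  p <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(1000, 2000), strand = c("+", "-"),
                  gene_label = c("SAT", "none"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tss(p, f)
  expect_equal(read_tss(f), p)
  bad <- p; bad$strand <- c("+", "*")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tss(f2), "strand")
})
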