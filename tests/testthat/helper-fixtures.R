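## Shared fixtures and independent oracles, built in code.

## small, fast simulation: one 2-Mb chromosome, 30 genes
small_cfg <- function(...) {
  sim_config(chrom_lengths = c(chrA = 2e6), n_genes = 30, ...)
}

## brute-force all-pairs overlap oracle (half-open intervals)
oracle_overlap_pairs <- function(a, b) {
  hits <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      hits[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
    }
  }
  hits
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, max_width = 500) {
  set.seed(seed)
  start <- floor(runif(n, 0, max_pos))
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + ceiling(runif(n, 1, max_width)))
}

## exhaustive permutation null for the Kruskal-Wallis statistic (3 groups)
kw_perm_p <- function(groups) {
  vals <- unlist(groups)
  n <- lengths(groups)
  N <- sum(n)
  h_of <- function(lab) suppressWarnings(
    stats::kruskal.test(vals, factor(lab))$statistic)
  obs <- h_of(rep(seq_along(groups), n))
  idx <- seq_len(N)
  combs1 <- utils::combn(N, n[1])
  tot <- 0; ge <- 0
  for (i in seq_len(ncol(combs1))) {
    rest1 <- setdiff(idx, combs1[, i])
    combs2 <- utils::combn(length(rest1), n[2])
    for (j in seq_len(ncol(combs2))) {
      g2 <- rest1[combs2[, j]]
      g3 <- setdiff(rest1, g2)
      lab <- integer(N)
      lab[combs1[, i]] <- 1; lab[g2] <- 2; lab[g3] <- 3
      tot <- tot + 1
      if (h_of(lab) >= obs - 1e-12) ge <- ge + 1
    }
  }
  ge / tot
}

## exact per-class recovery probability of the promoter rule under
## independent flag flips at rate eps (enumeration over the 4 relevant marks)
expected_promoter_recovery <- function(class, eps) {
  planted <- switch(class,
    SAT_PATTERN = c(TRUE, TRUE, TRUE, FALSE),
    BIVALENT = c(FALSE, TRUE, FALSE, TRUE),
    REPRESSED = c(FALSE, FALSE, FALSE, TRUE),
    ACTIVE = c(FALSE, TRUE, TRUE, FALSE))  # (ub, k4, ac, me3)
  acc <- 0
  for (code in 0:15) {
    flips <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)))
    flags <- xor(planted, flips)
    prob <- prod(ifelse(flips, eps, 1 - eps))
    sig <- c(H2AK119ub = flags[1], H3K4me3 = flags[2], H3K27ac = flags[3],
             H3K27me3 = flags[4], H3K4me1 = FALSE)
    if (classify_promoter(sig) == class) acc <- acc + prob
  }
  acc
}

## same, for the enhancer rule over (me1, ac, ub)
expected_enhancer_recovery <- function(ub_pos, eps) {
  planted <- c(TRUE, TRUE, ub_pos)  # (me1, ac, ub)
  truth <- if (ub_pos) "ENHANCER_UB_POS" else "ENHANCER_UB_NEG"
  acc <- 0
  for (code in 0:7) {
    flips <- as.logical(bitwAnd(code, c(1L, 2L, 4L)))
    flags <- xor(planted, flips)
    prob <- prod(ifelse(flips, eps, 1 - eps))
    sig <- c(H2AK119ub = flags[3], H3K4me3 = FALSE, H3K27ac = flags[2],
             H3K27me3 = FALSE, H3K4me1 = flags[1])
    if (classify_enhancer(sig) == truth) acc <- acc + prob
  }
  acc
}

## measured classification accuracy for one simulation seed
measured_recovery <- function(cfg) {
  g <- simulate_genome(cfg)
  m <- simulate_marks_and_peaks(g)
  ann <- g$promoters[, c("gene_id", "chrom", "tss", "strand", "gene_label")]
  cls <- classify_promoters(ann, m$peaksets)
  ewin <- make_tss_window(
    data.frame(chrom = g$enhancers$chrom, tss = g$enhancers$pos), 2000)
  esig <- signature_at(ewin, m$peaksets)
  ecls <- classify_enhancer(esig)
  list(promoter = mean(cls$class == g$promoters$class),
       enhancer = mean(ecls == unname(g$truth$enhancer_class)),
       genome = g)
}

## forward-construct a noise-free SMARCC1 row from fitted components
mixture_profile <- function(components, pct, scale = 1000) {
  fr <- 1:24
  phi_full <- vapply(components, function(cp) {
    d <- stats::dnorm(fr, cp$mean, cp$sd)
    d / sum(stats::dnorm(12:24, cp$mean, cp$sd))
  }, numeric(24))
  scale * as.numeric(phi_full %*% (pct / 100))
}

default_components <- function(means = c(14, 17, 20), sds = rep(1.2, 3)) {
  Map(function(m, s, lab) list(subtype = lab, mean = m, sd = s,
                               amplitude = 1, converged = TRUE),
      means, sds, c("GBAF", "CBAF", "PBAF"))
}

## random integer triple summing to 100
random_triple <- function() {
  cuts <- sort(sample(0:100, 2, replace = TRUE))
  c(cuts[1], cuts[2] - cuts[1], 100 - cuts[2])
}
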