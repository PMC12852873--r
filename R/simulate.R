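## Seeded synthetic-data generator. Plants promoters of known class, mark
## peaks, fusion/BAF signal tracks, enhancer loops, CpG-island-like GC
## elevation, knockout dips, gradient densitometry, and morphometry tables,
## together with a truth table, so every pipeline stage can be checked
## against known ground truth without sequencing data.

#' Simulation configuration
#'
#' Returns the default study conditions; any field can be overridden by
#' name. Key defaults: 2 chromosomes x 10 Mb, 300 genes with class mix
#' 0.2/0.2/0.2/0.4 (SAT_PATTERN/BIVALENT/REPRESSED/ACTIVE), flag flip rate
#' 0, broad fusion peaks with log-normal widths (median 6 kb), narrow
#' peaks (median 400 bp), 2 loops per SAT promoter with 30% decoys,
#' gradient components at fraction means 14/17/20 (sd 1.2) with true
#' mixture (55, 15, 30), CpG-island GC 0.65 over 600 bp on a 0.40
#' baseline, knockout dip depth 0.1.
#'
#' @param ... overrides for any default field
#' @return a `sim_config` list
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1,
    chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
    n_genes = 300,
    class_mix = c(SAT_PATTERN = 0.2, BIVALENT = 0.2, REPRESSED = 0.2,
                  ACTIVE = 0.4),
    flank = 2000,
    flip_rate = 0,
    ## peak geometry
    mark_width_range = c(800, 1500),
    broad_meanlog = log(6000), broad_sdlog = 0.25,
    narrow_meanlog = log(400), narrow_sdlog = 0.3,
    broad_enrich_shape = 4, broad_enrich_scale = 3,
    narrow_enrich_shape = 4, narrow_enrich_scale = 12,
    narrow_active_frac = 0.5,
    qmlog_range = c(3.5, 8),
    ## tracks
    bin_size = 50,
    track_noise_sd = 0,
    promoter_amp = 6, promoter_shape_sd = 800,
    enhancer_amp = 4, enhancer_width = 1000,
    smarca4_amp = 5,
    dip_depth = 0.1,
    ## loops
    loops_per_sat = 2,
    enhancer_offset_range = c(10000, 25000),
    loop_score_shape = 2, loop_score_scale = 1.5,
    decoy_fraction = 0.3,
    enhancer_ub_frac = 0.7,
    ## sequence / GC
    baseline_gc = 0.40, island_gc = 0.65, island_width = 600,
    ## gradient
    gradient_means = c(GBAF = 14, CBAF = 17, PBAF = 20),
    gradient_sds = c(GBAF = 1.2, CBAF = 1.2, PBAF = 1.2),
    gradient_amps = c(GBAF = 900, CBAF = 1100, PBAF = 1000),
    true_pct = c(GBAF = 55, CBAF = 15, PBAF = 30),
    gradient_noise = 0.05,
    ## morphometry
    n_tumors_per_group = 6,
    shape_ratio_means = c(control = 1.2, treated = 2.0),
    shape_ratio_sd = 0.15,
    density_lambda = c(control = 18, treated = 34),
    n_days = 6)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$class_mix) - 1) < 1e-9,
            sum(cfg$true_pct) == 100)
  structure(cfg, class = c("sim_config", "list"))
}

## largest-remainder apportionment of n into proportions p
.apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  base
}

#' Simulate the genome layout: promoters, classes, enhancers
#'
#' Places TSSs with wide, collision-free spacing, assigns planted promoter
#' classes by largest-remainder apportionment of the class mix, derives
#' gene labels (SAT_PATTERN -> SAT, ACTIVE -> MAT, BIVALENT -> SST,
#' REPRESSED -> none), plants CpG-island and knockout-dip flags on
#' SAT_PATTERN promoters, and positions distal enhancers for each SAT
#' promoter. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()]
#' @return list with `promoters`, `enhancers`, `truth`, `cfg`
#' @export
simulate_genome <- function(cfg = sim_config()) {
  n <- cfg$n_genes
  counts <- .apportion(n, cfg$class_mix)
  max_broad <- exp(cfg$broad_meanlog + 4 * cfg$broad_sdlog)
  min_space <- max(2 * (cfg$flank + max_broad),
                   max(cfg$enhancer_offset_range) + 2 * cfg$flank + 2000)
  total <- sum(cfg$chrom_lengths)
  per_chrom <- .apportion(n, cfg$chrom_lengths / total)
  if (any(cfg$chrom_lengths / pmax(per_chrom, 1) < min_space))
    stop("genes too dense for collision-free spacing; enlarge chromosomes")
  .with_seed(cfg$seed + 101, {
    classes <- sample(rep(names(cfg$class_mix), counts))
    rows <- list()
    gi <- 0
    for (ci in seq_along(cfg$chrom_lengths)) {
      ch <- names(cfg$chrom_lengths)[ci]
      k <- per_chrom[ci]
      if (k == 0) next
      spacing <- floor(cfg$chrom_lengths[ci] / (k + 1))
      tss <- spacing * seq_len(k) + round(runif(k, -1000, 1000))
      rows[[ch]] <- data.frame(
        gene_id = sprintf("gene%03d", gi + seq_len(k)),
        chrom = ch, tss = tss,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
      gi <- gi + k
    }
    promoters <- do.call(rbind, rows)
    rownames(promoters) <- NULL
    promoters$class <- classes
    promoters$gene_label <- c(SAT_PATTERN = "SAT", ACTIVE = "MAT",
                              BIVALENT = "SST", REPRESSED = "none")[classes]
    is_sat <- promoters$class == "SAT_PATTERN"
    promoters$island <- is_sat
    promoters$dip <- is_sat
    narrow_pool <- which(promoters$class == "ACTIVE")
    narrow_sel <- sort(sample(narrow_pool,
                              round(cfg$narrow_active_frac * length(narrow_pool))))
    promoters$narrow_fusion <- seq_len(n) %in% narrow_sel
    ## enhancers for each SAT promoter
    sat_idx <- which(is_sat)
    enh <- do.call(rbind, lapply(sat_idx, function(i) {
      k <- cfg$loops_per_sat
      ## slotted magnitudes with alternating sign keep enhancer signal
      ## rectangles of one gene disjoint
      slot <- diff(cfg$enhancer_offset_range) / k
      mag <- cfg$enhancer_offset_range[1] + (seq_len(k) - 1) * slot +
        round(runif(k, 0, max(slot - 1500, 0)))
      off <- mag * rep_len(c(-1, 1), k)
      data.frame(gene_id = promoters$gene_id[i],
                 chrom = promoters$chrom[i],
                 pos = promoters$tss[i] + off,
                 ub_pos = runif(k) < cfg$enhancer_ub_frac,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(enh)) enh <- data.frame(gene_id = character(),
                                        chrom = character(), pos = numeric(),
                                        ub_pos = logical())
    enh$enh_id <- sprintf("enh%03d", seq_len(nrow(enh)))
    truth <- list(
      class_counts = as.list(table(promoters$class)),
      classes = stats::setNames(promoters$class, promoters$gene_id),
      island = stats::setNames(promoters$island, promoters$gene_id),
      dip = stats::setNames(promoters$dip, promoters$gene_id),
      enhancer_class = stats::setNames(
        ifelse(enh$ub_pos, "ENHANCER_UB_POS", "ENHANCER_UB_NEG"), enh$enh_id))
    list(promoters = promoters, enhancers = enh, truth = truth, cfg = cfg)
  })
}

## planted mark flags per promoter class
.planted_flags <- function(class) {
  switch(class,
    SAT_PATTERN = c(H2AK119ub = TRUE, H3K4me3 = TRUE, H3K27ac = TRUE,
                    H3K27me3 = FALSE, H3K4me1 = FALSE),
    BIVALENT = c(H2AK119ub = FALSE, H3K4me3 = TRUE, H3K27ac = FALSE,
                 H3K27me3 = TRUE, H3K4me1 = FALSE),
    REPRESSED = c(H2AK119ub = FALSE, H3K4me3 = FALSE, H3K27ac = FALSE,
                  H3K27me3 = TRUE, H3K4me1 = FALSE),
    ACTIVE = c(H2AK119ub = FALSE, H3K4me3 = TRUE, H3K27ac = TRUE,
               H3K27me3 = FALSE, H3K4me1 = FALSE),
    stop("unknown class ", class))
}

.mk_peak <- function(chrom, start, end, name, enrichment, qmlog) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = round(enrichment * 10), strand = ".",
             enrichment = enrichment, pvalue_mlog = qmlog + 1,
             qvalue_mlog = qmlog, peak_offset = floor((end - start) / 2),
             qvalue = 10^(-qmlog), stringsAsFactors = FALSE)
}

#' Simulate mark peak sets and fusion peaks
#'
#' Each promoter's planted class emits its defining mark peaks (q-values
#' drawn below 0.001); each of the five flags is then flipped
#' independently with probability `flip_rate` (a present mark loses its
#' peak; an absent one gains a passing peak). SAT promoters receive broad
#' fusion peaks; a configured subset of ACTIVE promoters receives narrow,
#' high-enrichment fusion peaks. Enhancers emit H3K4me1 + H3K27ac peaks
#' (plus H2AK119ub when ub-positive), with the same flip noise on those
#' three flags.
#'
#' @param genome output of [simulate_genome()]
#' @param cfg optional config override (defaults to `genome$cfg`)
#' @return list with `peaksets` (named list of per-mark peak
#'   data.frames), `fusion_peaks`, and `realized` flag matrices for
#'   promoters and enhancers
#' @export
simulate_marks_and_peaks <- function(genome, cfg = genome$cfg) {
  pr <- genome$promoters
  enh <- genome$enhancers
  .with_seed(cfg$seed + 202, {
    planted <- t(vapply(pr$class, .planted_flags, logical(5)))
    flips <- matrix(runif(length(planted)) < cfg$flip_rate, nrow = nrow(planted))
    realized <- xor(planted, flips)
    colnames(realized) <- MARKS
    enh_planted <- cbind(H2AK119ub = enh$ub_pos,
                         H3K4me3 = rep(FALSE, nrow(enh)),
                         H3K27ac = rep(TRUE, nrow(enh)),
                         H3K27me3 = rep(FALSE, nrow(enh)),
                         H3K4me1 = rep(TRUE, nrow(enh)))
    enh_flip_marks <- c("H2AK119ub", "H3K27ac", "H3K4me1")
    enh_realized <- enh_planted
    if (nrow(enh) > 0) {
      fl <- matrix(runif(nrow(enh) * 3) < cfg$flip_rate, ncol = 3)
      enh_realized[, enh_flip_marks] <- xor(enh_planted[, enh_flip_marks], fl)
    }
    peaksets <- lapply(MARKS, function(mark) {
      rows <- list()
      on <- which(realized[, mark])
      if (length(on) > 0) {
        w <- round(runif(length(on), cfg$mark_width_range[1],
                         cfg$mark_width_range[2]))
        qm <- runif(length(on), cfg$qmlog_range[1], cfg$qmlog_range[2])
        rows$prom <- .mk_peak(pr$chrom[on], pr$tss[on] - floor(w / 2),
                              pr$tss[on] + ceiling(w / 2),
                              paste0(mark, "_", pr$gene_id[on]),
                              rgamma(length(on), 3, scale = 2), qm)
      }
      eon <- which(enh_realized[, mark])
      if (length(eon) > 0) {
        w <- round(runif(length(eon), cfg$mark_width_range[1],
                         cfg$mark_width_range[2]))
        qm <- runif(length(eon), cfg$qmlog_range[1], cfg$qmlog_range[2])
        rows$enh <- .mk_peak(enh$chrom[eon], enh$pos[eon] - floor(w / 2),
                             enh$pos[eon] + ceiling(w / 2),
                             paste0(mark, "_", enh$enh_id[eon]),
                             rgamma(length(eon), 3, scale = 2), qm)
      }
      pk <- if (length(rows) > 0) do.call(rbind, rows) else .empty_peaks()
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      rownames(pk) <- NULL
      pk
    })
    names(peaksets) <- MARKS
    ## fusion peaks: broad at SAT, narrow at the chosen ACTIVE subset
    sat <- which(pr$class == "SAT_PATTERN")
    nar <- which(pr$narrow_fusion)
    wb <- round(rlnorm(length(sat), cfg$broad_meanlog, cfg$broad_sdlog))
    wn <- round(rlnorm(length(nar), cfg$narrow_meanlog, cfg$narrow_sdlog))
    we <- if (nrow(enh) > 0)
      round(runif(nrow(enh), cfg$mark_width_range[1],
                  cfg$mark_width_range[2])) else integer(0)
    fusion <- rbind(
      if (nrow(enh) > 0)
        .mk_peak(enh$chrom, enh$pos - floor(we / 2),
                 enh$pos + ceiling(we / 2),
                 paste0("fusion_", enh$enh_id),
                 rgamma(nrow(enh), 3, scale = 2),
                 runif(nrow(enh), cfg$qmlog_range[1], cfg$qmlog_range[2])),
      .mk_peak(pr$chrom[sat], pmax(0, pr$tss[sat] - floor(wb / 2)),
               pr$tss[sat] + ceiling(wb / 2),
               paste0("fusion_", pr$gene_id[sat]),
               rgamma(length(sat), cfg$broad_enrich_shape,
                      scale = cfg$broad_enrich_scale),
               runif(length(sat), cfg$qmlog_range[1], cfg$qmlog_range[2])),
      .mk_peak(pr$chrom[nar], pmax(0, pr$tss[nar] - floor(wn / 2)),
               pr$tss[nar] + ceiling(wn / 2),
               paste0("fusion_", pr$gene_id[nar]),
               rgamma(length(nar), cfg$narrow_enrich_shape,
                      scale = cfg$narrow_enrich_scale),
               runif(length(nar), cfg$qmlog_range[1], cfg$qmlog_range[2])))
    fusion <- fusion[order(fusion$chrom, fusion$start), , drop = FALSE]
    rownames(fusion) <- NULL
    list(peaksets = peaksets, fusion_peaks = fusion,
         realized = realized, enh_realized = enh_realized)
  })
}

## Gaussian-profile bin values over [tss - flank, tss + flank)
.promoter_bins <- function(chrom, tss, flank, bin, amp, shape_sd) {
  starts <- seq(tss - flank, tss + flank - bin, by = bin)
  centers <- starts + bin / 2
  data.frame(chrom = chrom, start = starts, end = starts + bin,
             value = amp * exp(-(centers - tss)^2 / (2 * shape_sd^2)),
             stringsAsFactors = FALSE)
}

#' Simulate the signal track set
#'
#' Emits piecewise-constant tracks (50-bp bins): broad Gaussian-profile
#' fusion and GBAF signal over SAT promoter windows plus rectangular
#' fusion signal at enhancers; narrow CBAF/PBAF peaks at ACTIVE and SAT
#' TSSs; H2AK119ub signal at SAT promoters and ub-positive enhancers; and
#' a SMARCA4 pair where the knockout condition carries planted central
#' dips (depth `dip_depth`) at dip-flagged promoters. Optional truncated
#' additive Gaussian noise; all values nonnegative.
#'
#' @param genome output of [simulate_genome()]
#' @param cfg optional config override
#' @return named list of `signal_track`s: `fusion, H2AK119ub, GBAF, CBAF,
#'   PBAF, SMARCA4_wt, SMARCA4_ko`
#' @export
simulate_tracks <- function(genome, cfg = genome$cfg) {
  pr <- genome$promoters
  enh <- genome$enhancers
  b <- cfg$bin_size
  .with_seed(cfg$seed + 303, {
    sat <- pr[pr$class == "SAT_PATTERN", , drop = FALSE]
    act_sat <- pr[pr$class %in% c("ACTIVE", "SAT_PATTERN"), , drop = FALSE]
    prom_gauss <- function(rows, amp) {
      if (nrow(rows) == 0) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
        .promoter_bins(rows$chrom[i], rows$tss[i], cfg$flank, b, amp,
                       cfg$promoter_shape_sd)))
    }
    enh_rect <- function(rows, amp) {
      if (nrow(rows) == 0) return(NULL)
      half <- cfg$enhancer_width / 2
      data.frame(chrom = rows$chrom, start = rows$pos - half,
                 end = rows$pos + half, value = amp, stringsAsFactors = FALSE)
    }
    narrow_rect <- function(rows, amp) {
      if (nrow(rows) == 0) return(NULL)
      data.frame(chrom = rows$chrom, start = rows$tss - 200,
                 end = rows$tss + 200, value = amp, stringsAsFactors = FALSE)
    }
    flat_prom <- function(rows, amp) {
      if (nrow(rows) == 0) return(NULL)
      data.frame(chrom = rows$chrom, start = rows$tss - cfg$flank,
                 end = rows$tss + cfg$flank, value = amp,
                 stringsAsFactors = FALSE)
    }
    fusion <- rbind(prom_gauss(sat, cfg$promoter_amp),
                    enh_rect(enh, cfg$enhancer_amp))
    ub <- rbind(prom_gauss(sat, cfg$promoter_amp * 0.8),
                enh_rect(enh[enh$ub_pos, , drop = FALSE],
                         cfg$enhancer_amp * 0.8))
    gbaf <- prom_gauss(sat, cfg$promoter_amp * 0.9)
    cbaf <- narrow_rect(act_sat, cfg$promoter_amp)
    pbaf <- narrow_rect(act_sat, cfg$promoter_amp * 0.7)
    wt <- flat_prom(act_sat, cfg$smarca4_amp)
    ## knockout: same coverage, central dip at dip-flagged promoters
    dipped <- pr[pr$dip, , drop = FALSE]
    ko_rows <- lapply(seq_len(nrow(act_sat)), function(i) {
      r <- act_sat[i, ]
      if (!r$dip) {
        return(data.frame(chrom = r$chrom, start = r$tss - cfg$flank,
                          end = r$tss + cfg$flank, value = cfg$smarca4_amp))
      }
      data.frame(chrom = r$chrom,
                 start = c(r$tss - cfg$flank, r$tss - 250, r$tss + 250),
                 end = c(r$tss - 250, r$tss + 250, r$tss + cfg$flank),
                 value = cfg$smarca4_amp * c(1, cfg$dip_depth, 1))
    })
    ko <- do.call(rbind, ko_rows)
    finish <- function(runs) {
      if (is.null(runs)) runs <- data.frame(chrom = character(),
                                            start = numeric(), end = numeric(),
                                            value = numeric())
      if (cfg$track_noise_sd > 0 && nrow(runs) > 0)
        runs$value <- pmax(0, runs$value +
                             rnorm(nrow(runs), 0, cfg$track_noise_sd))
      signal_track(runs)
    }
    list(fusion = finish(fusion), H2AK119ub = finish(ub), GBAF = finish(gbaf),
         CBAF = finish(cbaf), PBAF = finish(pbaf), SMARCA4_wt = finish(wt),
         SMARCA4_ko = finish(ko))
  })
}

#' Simulate HiChIP loops with decoys and analytic truth
#'
#' Each SAT promoter is looped to its planted enhancers (anchors 500 bp,
#' FDR drawn below 0.05); decoy loops between intergenic anchor pairs
#' carry FDR at or above 0.05. The truth table records, per gene, the
#' analytic expectation of every target-score component at zero track
#' noise (enhancer rectangles lie wholly inside their 4-kb anchor
#' windows; promoter Gaussian bins tile the TSS window exactly).
#'
#' @param genome output of [simulate_genome()]
#' @param cfg optional config override
#' @return list with `loops` (data.frame as from [read_loops()]) and
#'   `truth` (per-gene expected components data.frame)
#' @export
simulate_loops <- function(genome, cfg = genome$cfg) {
  pr <- genome$promoters
  enh <- genome$enhancers
  b <- cfg$bin_size
  .with_seed(cfg$seed + 404, {
    real <- NULL
    if (nrow(enh) > 0) {
      pr_ix <- match(enh$gene_id, pr$gene_id)
      real <- data.frame(
        chrom1 = pr$chrom[pr_ix], start1 = pr$tss[pr_ix] - 250,
        end1 = pr$tss[pr_ix] + 250,
        chrom2 = enh$chrom, start2 = enh$pos - 250, end2 = enh$pos + 250,
        name = paste0("loop_", enh$enh_id),
        loop_score = round(rgamma(nrow(enh), cfg$loop_score_shape,
                                  scale = cfg$loop_score_scale), 3),
        fdr = round(runif(nrow(enh), 0.0005, 0.045), 4),
        stringsAsFactors = FALSE)
    }
    n_decoy <- round(cfg$decoy_fraction * max(1, nrow(enh)))
    chs <- sample(names(cfg$chrom_lengths), n_decoy, replace = TRUE)
    p1 <- round(runif(n_decoy, 1e5, cfg$chrom_lengths[chs] - 2e5))
    decoys <- data.frame(
      chrom1 = chs, start1 = p1, end1 = p1 + 500,
      chrom2 = chs, start2 = p1 + 50000, end2 = p1 + 50500,
      name = sprintf("decoy%03d", seq_len(n_decoy)),
      loop_score = round(rgamma(n_decoy, cfg$loop_score_shape,
                                scale = cfg$loop_score_scale), 3),
      fdr = round(runif(n_decoy, 0.05, 0.9), 4),
      stringsAsFactors = FALSE)
    loops <- rbind(real, decoys)
    ## analytic expected components per gene at zero track noise
    gauss_sum <- function(tss, amp) {
      starts <- seq(tss - cfg$flank, tss + cfg$flank - b, by = b)
      centers <- starts + b / 2
      sum(amp * exp(-(centers - tss)^2 / (2 * cfg$promoter_shape_sd^2)) * b)
    }
    truth <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
      g <- pr$gene_id[i]
      is_sat <- pr$class[i] == "SAT_PATTERN"
      fp <- if (is_sat) gauss_sum(pr$tss[i], cfg$promoter_amp) else 0
      up <- if (is_sat) gauss_sum(pr$tss[i], cfg$promoter_amp * 0.8) else 0
      fd <- ud <- 0
      nl <- 0
      if (is_sat && !is.null(real)) {
        mine <- real[enh$gene_id == g, , drop = FALSE]
        my_enh <- enh[enh$gene_id == g, , drop = FALSE]
        nl <- nrow(mine)
        fd <- sum(cfg$enhancer_amp * cfg$enhancer_width * mine$loop_score)
        ud <- sum(cfg$enhancer_amp * 0.8 * cfg$enhancer_width *
                    mine$loop_score * my_enh$ub_pos)
      }
      data.frame(gene_id = g, fusion_promoter = fp, fusion_distal = fd,
                 ub_promoter = up, ub_distal = ud, n_loops = nl,
                 total = fp + fd + up + ud, stringsAsFactors = FALSE)
    }))
    list(loops = loops, truth = truth)
  })
}

#' Simulate genome sequence with CpG-island-like promoters
#'
#' Random sequence at the baseline GC fraction, with island-flagged
#' promoters carrying an elevated-GC segment of `island_width` bp
#' centered on the TSS.
#'
#' @param genome output of [simulate_genome()]
#' @param cfg optional config override
#' @return a [Biostrings::DNAStringSet], one sequence per chromosome
#' @export
simulate_sequences <- function(genome, cfg = genome$cfg) {
  pr <- genome$promoters
  .with_seed(cfg$seed + 505, {
    base_p <- c(A = (1 - cfg$baseline_gc) / 2, C = cfg$baseline_gc / 2,
                G = cfg$baseline_gc / 2, T = (1 - cfg$baseline_gc) / 2)
    isl_p <- c(A = (1 - cfg$island_gc) / 2, C = cfg$island_gc / 2,
               G = cfg$island_gc / 2, T = (1 - cfg$island_gc) / 2)
    half <- floor(cfg$island_width / 2)
    seqs <- lapply(names(cfg$chrom_lengths), function(ch) {
      len <- cfg$chrom_lengths[[ch]]
      idx <- sample.int(4, len, replace = TRUE, prob = base_p)
      here <- pr[pr$chrom == ch & pr$island, , drop = FALSE]
      for (tss in here$tss) {
        s <- max(1, tss - half + 1); e <- min(len, tss + half)
        idx[s:e] <- sample.int(4, e - s + 1, replace = TRUE, prob = isl_p)
      }
      paste(c("A", "C", "G", "T")[idx], collapse = "")
    })
    out <- Biostrings::DNAStringSet(unlist(seqs))
    names(out) <- names(cfg$chrom_lengths)
    out
  })
}

#' Simulate a glycerol-gradient densitometry table
#'
#' Marker rows (BRD9, DPF2, PBRM1) are amplitude-scaled Gaussians over
#' fractions 1-24; the SMARCC1 row is the true-percentage mixture of the
#' three component densities (unit-normalized over fractions 12-24), with
#' optional multiplicative log-normal noise.
#'
#' @param cfg a [sim_config()]
#' @return list with `profiles` (densitometry data.frame) and `true_pct`
#' @export
simulate_gradient <- function(cfg = sim_config()) {
  .with_seed(cfg$seed + 606, {
    fr <- 1:24
    markers <- c(GBAF = "BRD9", CBAF = "DPF2", PBAF = "PBRM1")
    rows <- lapply(names(markers), function(s) {
      cfg$gradient_amps[[s]] * stats::dnorm(fr, cfg$gradient_means[[s]],
                                            cfg$gradient_sds[[s]])
    })
    names(rows) <- markers
    phi <- vapply(names(markers), function(s) {
      d <- stats::dnorm(GRADIENT_RANGE, cfg$gradient_means[[s]],
                        cfg$gradient_sds[[s]])
      full <- stats::dnorm(fr, cfg$gradient_means[[s]], cfg$gradient_sds[[s]])
      full / sum(d)
    }, numeric(24))
    smarcc1 <- 1000 * as.numeric(phi %*% (cfg$true_pct / 100))
    mat <- rbind(do.call(rbind, rows), SMARCC1 = smarcc1)
    if (cfg$gradient_noise > 0)
      mat <- mat * exp(matrix(rnorm(length(mat), 0, cfg$gradient_noise),
                              nrow = nrow(mat)))
    profiles <- data.frame(marker = c(markers, "SMARCC1"), mat,
                           stringsAsFactors = FALSE, row.names = NULL)
    names(profiles) <- c("marker", paste0("f", fr))
    list(profiles = profiles, true_pct = cfg$true_pct)
  })
}

#' Simulate morphometry and tumor-growth tables
#'
#' Two groups of tumors: per tumor, 1-3 histomorphologically distinct
#' regions with Dirichlet area fractions; per region, three nucleus
#' (long, orthogonal) axis pairs with long >= orthogonal enforced, and a
#' nucleus count per 500 um^2 square; plus a caliper (D, d) diameter
#' series with the derived volume column.
#'
#' @param cfg a [sim_config()]
#' @return list with `morphometry`, `counts`, `growth` data.frames
#' @export
simulate_morphometry <- function(cfg = sim_config()) {
  .with_seed(cfg$seed + 707, {
    groups <- names(cfg$shape_ratio_means)
    morpho <- list(); counts <- list(); growth <- list()
    for (g in groups) {
      for (t in seq_len(cfg$n_tumors_per_group)) {
        id <- paste0(g, "_tumor", t)
        k <- sample(1:3, 1)
        fr <- rgamma(k, 2); fr <- fr / sum(fr)
        for (r in seq_len(k)) {
          orth <- rlnorm(3, log(6), 0.15)
          ratio <- pmax(1, rnorm(3, cfg$shape_ratio_means[[g]],
                                 cfg$shape_ratio_sd))
          morpho[[length(morpho) + 1]] <- data.frame(
            tumor = id, group = g, region = paste0("region", r),
            fraction = fr[r], long_axis = orth * ratio, orth_axis = orth,
            stringsAsFactors = FALSE)
          counts[[length(counts) + 1]] <- data.frame(
            tumor = id, group = g, region = paste0("region", r),
            nuclei_per_500um2 = rpois(1, cfg$density_lambda[[g]]),
            stringsAsFactors = FALSE)
        }
        D <- cumsum(abs(rnorm(cfg$n_days, 1.5, 0.4))) + 4
        d <- D * runif(cfg$n_days, 0.6, 0.95)
        growth[[length(growth) + 1]] <- data.frame(
          tumor = id, group = g, day = seq(0, by = 3,
                                           length.out = cfg$n_days),
          D = round(D, 2), d = round(d, 2),
          stringsAsFactors = FALSE)
      }
    }
    growth <- do.call(rbind, growth)
    growth$volume <- tumor_volume(growth$D, growth$d)
    list(morphometry = do.call(rbind, morpho),
         counts = do.call(rbind, counts),
         growth = growth)
  })
}

#' Run the full generator and write every output file
#'
#' Emits FASTA, TSS table, per-mark narrowPeak files, fusion narrowPeak,
#' bedGraph tracks, BEDPE loops, densitometry and morphometry TSVs, a
#' truth-table JSON, and a manifest with the seed and config hash.
#' Byte-identical across runs for a fixed config.
#'
#' @param cfg a [sim_config()]
#' @param outdir output directory (created if absent)
#' @param sequences write the FASTA (the slowest step); set `FALSE` to
#'   skip when sequence is not needed
#' @return invisibly, the genome object plus file paths
#' @export
simulate_all <- function(cfg = sim_config(), outdir, sequences = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  marks <- simulate_marks_and_peaks(genome)
  tracks <- simulate_tracks(genome)
  loops <- simulate_loops(genome)
  grad <- simulate_gradient(cfg)
  morpho <- simulate_morphometry(cfg)
  paths <- list()
  pr <- genome$promoters
  paths$tss <- file.path(outdir, "tss.tsv")
  write_tss(pr, paths$tss)
  for (mark in MARKS) {
    p <- file.path(outdir, paste0(mark, ".narrowPeak"))
    write_peaks(marks$peaksets[[mark]], p)
    paths[[mark]] <- p
  }
  paths$fusion_peaks <- file.path(outdir, "fusion.narrowPeak")
  write_peaks(marks$fusion_peaks, paths$fusion_peaks)
  for (tr in names(tracks)) {
    p <- file.path(outdir, paste0(tr, ".bedGraph"))
    write_bedgraph(tracks[[tr]], p)
    paths[[tr]] <- p
  }
  paths$loops <- file.path(outdir, "loops.bedpe")
  write_loops(loops$loops, paths$loops)
  paths$gradient <- file.path(outdir, "gradient.tsv")
  write_gradient_profiles(grad$profiles, paths$gradient)
  paths$morphometry <- file.path(outdir, "morphometry.tsv")
  write.table(morpho$morphometry, paths$morphometry, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$nuclear_counts <- file.path(outdir, "nuclear_counts.tsv")
  write.table(morpho$counts, paths$nuclear_counts, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$growth <- file.path(outdir, "tumor_growth.tsv")
  write.table(morpho$growth, paths$growth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (sequences) {
    paths$fasta <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(simulate_sequences(genome), paths$fasta)
  }
  truth <- list(
    classes = genome$truth$classes,
    class_counts = genome$truth$class_counts,
    island = genome$truth$island,
    dip = genome$truth$dip,
    enhancer_class = genome$truth$enhancer_class,
    target_scores = loops$truth,
    true_pct = as.list(grad$true_pct))
  paths$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, marks = marks, tracks = tracks,
                 loops = loops, gradient = grad, morphometry = morpho,
                 paths = paths))
}
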