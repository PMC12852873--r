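## Combinatorial histone-mark signatures and promoter/enhancer classes.
## A mark is "present" in a window iff some called peak of that mark with
## q-value < q_max overlaps the window (strict inequality, default 0.001).

MARKS <- c("H2AK119ub", "H3K4me3", "H3K27ac", "H3K27me3", "H3K4me1")

PROMOTER_CLASSES <- c("SAT_PATTERN", "BIVALENT", "REPRESSED", "ACTIVE",
                      "UNCLASSIFIED", "RANDOM_CONTROL")

#' Mark signatures over query windows
#'
#' For each window and each histone mark, tests whether any called peak of
#' that mark passing the q-value filter overlaps the window.
#'
#' @param windows interval data.frame (typically TSS windows)
#' @param peaksets named list of peak data.frames, names among
#'   `H2AK119ub, H3K4me3, H3K27ac, H3K27me3, H3K4me1`; a missing mark
#'   yields `NA` flags (downstream class `UNCLASSIFIED`)
#' @param q_max q-value threshold; a peak counts iff `qvalue < q_max`
#' @return logical matrix, one row per window, one column per mark
#' @export
signature_at <- function(windows, peaksets, q_max = 0.001) {
  stopifnot(q_max > 0, q_max <= 1)
  sig <- matrix(NA, nrow = nrow(windows), ncol = length(MARKS),
                dimnames = list(NULL, MARKS))
  for (mark in MARKS) {
    pk <- peaksets[[mark]]
    if (is.null(pk)) next
    pk <- pk[pk$qvalue < q_max, , drop = FALSE]
    present <- logical(nrow(windows))
    if (nrow(pk) > 0 && nrow(windows) > 0) {
      hits <- GenomicRanges::findOverlaps(.as_granges(windows), .as_granges(pk))
      present[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    sig[, mark] <- present
  }
  sig
}

#' Classify promoters from mark signatures
#'
#' Applies the combinatorial rule set, in precedence order:
#' * `SAT_PATTERN`: H2AK119ub+, H3K4me3+, H3K27ac+, H3K27me3-
#' * `BIVALENT`: H3K4me3+, H3K27me3+
#' * `REPRESSED`: H3K27me3+ with H3K4me3-
#' * `ACTIVE`: H3K4me3+, H3K27ac+ (the maintained-active, H2AK119ub-negative
#'   promoter state)
#' * otherwise `UNCLASSIFIED`
#'
#' Any `NA` flag among the four promoter-defining marks yields
#' `UNCLASSIFIED`. The classification is a pure function of the flags.
#'
#' @param sig logical matrix from [signature_at()] (or a single named
#'   logical vector)
#' @return character vector of promoter classes
#' @export
classify_promoter <- function(sig) {
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1,
                                       dimnames = list(NULL, names(sig)))
  ub <- sig[, "H2AK119ub"]; k4 <- sig[, "H3K4me3"]
  ac <- sig[, "H3K27ac"]; me3 <- sig[, "H3K27me3"]
  out <- rep("UNCLASSIFIED", nrow(sig))
  known <- !(is.na(ub) | is.na(k4) | is.na(ac) | is.na(me3))
  cls <- ifelse(ub & k4 & ac & !me3, "SAT_PATTERN",
         ifelse(k4 & me3, "BIVALENT",
         ifelse(me3 & !k4, "REPRESSED",
         ifelse(k4 & ac, "ACTIVE", "UNCLASSIFIED"))))
  out[known] <- cls[known]
  out
}

#' Classify distal elements from mark signatures
#'
#' Distal active enhancers are called by the intersection of H3K4me1 and
#' H3K27ac peaks, then split by H2AK119ub status:
#' `ENHANCER_UB_POS` (H3K4me1+, H3K27ac+, H2AK119ub+),
#' `ENHANCER_UB_NEG` (H3K4me1+, H3K27ac+, H2AK119ub-), else `NOT_ENHANCER`.
#'
#' @param sig logical matrix from [signature_at()]
#' @param windows optional interval data.frame of the candidate elements;
#'   when given together with `promoter_windows`, any candidate overlapping
#'   a promoter window raises an error (enhancers must be distal)
#' @param promoter_windows optional interval data.frame of TSS windows
#' @return character vector of enhancer classes
#' @export
classify_enhancer <- function(sig, windows = NULL, promoter_windows = NULL) {
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1,
                                       dimnames = list(NULL, names(sig)))
  if (!is.null(windows) && !is.null(promoter_windows) &&
      nrow(windows) > 0 && nrow(promoter_windows) > 0) {
    hits <- GenomicRanges::findOverlaps(.as_granges(windows),
                                        .as_granges(promoter_windows))
    if (length(hits) > 0)
      stop("candidate enhancer window overlaps a promoter window (not distal)")
  }
  me1 <- sig[, "H3K4me1"]; ac <- sig[, "H3K27ac"]; ub <- sig[, "H2AK119ub"]
  out <- rep("NOT_ENHANCER", nrow(sig))
  enh <- !is.na(me1) & !is.na(ac) & me1 & ac
  out[enh & !is.na(ub) & ub] <- "ENHANCER_UB_POS"
  out[enh & !(!is.na(ub) & ub)] <- "ENHANCER_UB_NEG"
  out[enh & is.na(ub)] <- "NOT_ENHANCER"  # unresolved ubiquitin flag
  out
}

#' Profile fusion peaks near transcription start sites
#'
#' Retains peaks whose span overlaps any TSS +/- `flank` window and records
#' width, enrichment, shape class, and the gene label of the nearest TSS.
#' Each peak appears at most once.
#'
#' @param peaks fusion peak data.frame, pre-filtered at the q-value
#'   threshold (use `peaks[peaks$qvalue < 0.001, ]`)
#' @param promoters promoter annotation data.frame
#' @param flank TSS window half-width in bp
#' @param broad_min_width width above which a peak is BROAD (see
#'   [classify_peak_shape()])
#' @return data.frame: `name,chrom,start,end,width,enrichment,shape,
#'   nearest_gene,gene_label`
#' @export
profile_tss_peaks <- function(peaks, promoters, flank = 2000,
                              broad_min_width = 2000) {
  win <- make_tss_window(promoters, flank)
  if (nrow(peaks) == 0) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(), width = numeric(),
                      enrichment = numeric(), shape = character(),
                      nearest_gene = character(), gene_label = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(peaks), .as_granges(win))
  keep <- unique(S4Vectors::queryHits(hits))
  keep <- keep[order(keep)]
  pk <- peaks[keep, , drop = FALSE]
  ## nearest TSS by distance from peak midpoint
  mid <- (pk$start + pk$end) / 2
  nearest <- vapply(seq_len(nrow(pk)), function(i) {
    same <- which(promoters$chrom == pk$chrom[i])
    same[which.min(abs(promoters$tss[same] - mid[i]))]
  }, integer(1))
  width <- pk$end - pk$start
  data.frame(name = pk$name, chrom = pk$chrom, start = pk$start, end = pk$end,
             width = width, enrichment = pk$enrichment,
             shape = classify_peak_shape(width, broad_min_width),
             nearest_gene = promoters$gene_id[nearest],
             gene_label = promoters$gene_label[nearest],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Broad/narrow peak shape call
#'
#' `BROAD` iff `width > broad_min_width` (strict; a peak of exactly the
#' boundary width is NARROW). The default boundary of 2 kb separates the
#' two width modes seen among promoter-associated fusion peaks; pass
#' `broad_min_width = "auto"` to place the boundary by 1-D two-means on
#' log widths instead.
#'
#' @param width peak widths in bp
#' @param broad_min_width boundary in bp, or `"auto"`
#' @return character vector of `"BROAD"`/`"NARROW"`
#' @export
classify_peak_shape <- function(width, broad_min_width = 2000) {
  stopifnot(all(width > 0))
  if (identical(broad_min_width, "auto")) {
    lw <- log(width)
    km <- stats::kmeans(lw, centers = range(lw), iter.max = 50)
    hi <- which.max(km$centers)
    broad_min_width <- exp((max(lw[km$cluster != hi]) +
                            min(lw[km$cluster == hi])) / 2)
  }
  ifelse(width > broad_min_width, "BROAD", "NARROW")
}

#' Uniform random control promoters
#'
#' Samples `n` promoters uniformly without replacement; reproducible for a
#' fixed seed.
#'
#' @param promoters promoter annotation data.frame
#' @param n subset size
#' @param seed integer seed
#' @return data.frame subset with `gene_label` set to `"none"` and marked
#'   `RANDOM_CONTROL` in a `class` column
#' @export
select_random_promoters <- function(promoters, n, seed) {
  if (n > nrow(promoters)) stop("n exceeds the number of promoters")
  idx <- .with_seed(seed, sample.int(nrow(promoters), n))
  out <- promoters[idx, , drop = FALSE]
  out$class <- "RANDOM_CONTROL"
  rownames(out) <- NULL
  out
}

## Run code under a local RNG seed without disturbing the global stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Classify all promoters against mark peak sets
#'
#' Convenience wrapper: builds TSS windows, computes signatures, and
#' returns the annotation with per-mark flags and the promoter class.
#'
#' @inheritParams signature_at
#' @param promoters promoter annotation data.frame
#' @param flank TSS window half-width
#' @return promoter data.frame with per-mark logical columns and `class`
#' @export
classify_promoters <- function(promoters, peaksets, q_max = 0.001,
                               flank = 2000) {
  win <- make_tss_window(promoters, flank)
  sig <- signature_at(win, peaksets, q_max)
  out <- cbind(promoters, as.data.frame(sig))
  out$class <- classify_promoter(sig)
  out
}
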