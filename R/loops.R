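## HiChIP loop filtering and loop-weighted cumulative target scores.

#' Retain high-confidence loops
#'
#' Keeps loops with `fdr < fdr_max` (strict inequality; a loop at exactly
#' the threshold is dropped).
#'
#' @param loops loop data.frame (see [read_loops()])
#' @param fdr_max FDR threshold, default 0.05
#' @return filtered loop data.frame
#' @export
filter_loops <- function(loops, fdr_max = 0.05) {
  stopifnot(fdr_max > 0, fdr_max <= 1)
  loops[loops$fdr < fdr_max, , drop = FALSE]
}

#' 4-kb target window centered on an anchor midpoint
#'
#' Loop anchors are standardized to target intervals of `2 * half_width`
#' bp centered on the anchor midpoint (integer midpoint, rounded down),
#' clipped at zero.
#'
#' @param anchors interval data.frame
#' @param half_width half-width in bp (default 2000, giving 4-kb windows)
#' @return interval data.frame
#' @export
anchor_window <- function(anchors, half_width = 2000) {
  stopifnot(half_width > 0)
  mid <- floor((anchors$start + anchors$end) / 2)
  genomic_intervals(anchors$chrom, pmax(0, mid - half_width), mid + half_width)
}

#' Assign loops to a promoter and identify distal anchors
#'
#' A loop is assigned to a promoter iff exactly one of its anchors
#' overlaps the TSS +/- `flank` window; the other anchor is the distal
#' one. Loops with both anchors inside the promoter window are degenerate
#' (no distal element) and excluded.
#'
#' @param promoter single-row promoter annotation
#' @param loops loop data.frame, already filtered with [filter_loops()]
#' @param flank TSS window half-width
#' @return data.frame of assigned loops with distal anchor columns
#'   `chrom,start,end` and `loop_score`
#' @export
assign_loops_to_promoter <- function(promoter, loops, flank = 2000) {
  win <- make_tss_window(promoter, flank)
  if (nrow(loops) == 0) return(.empty_assignment())
  a1 <- genomic_intervals(loops$chrom1, loops$start1, loops$end1)
  a2 <- genomic_intervals(loops$chrom2, loops$start2, loops$end2)
  h1 <- interval_overlaps(a1, win)
  h2 <- interval_overlaps(a2, win)
  keep <- xor(h1, h2)
  if (!any(keep)) return(.empty_assignment())
  distal_is_2 <- h1[keep]
  lp <- loops[keep, , drop = FALSE]
  data.frame(
    name = lp$name,
    chrom = ifelse(distal_is_2, lp$chrom2, lp$chrom1),
    start = ifelse(distal_is_2, lp$start2, lp$start1),
    end = ifelse(distal_is_2, lp$end2, lp$end1),
    loop_score = lp$loop_score,
    fdr = lp$fdr,
    stringsAsFactors = FALSE, row.names = NULL)
}

.empty_assignment <- function() {
  data.frame(name = character(), chrom = character(), start = numeric(),
             end = numeric(), loop_score = numeric(), fdr = numeric(),
             stringsAsFactors = FALSE)
}

#' Loop-weighted distal enrichment for one promoter
#'
#' Sums, over assigned loops, the track signal in the 4-kb distal anchor
#' window multiplied by the loop score.
#'
#' @param assigned assignment data.frame from [assign_loops_to_promoter()]
#' @param track a `signal_track`
#' @param half_width anchor window half-width
#' @return numeric scalar
#' @export
distal_score <- function(assigned, track, half_width = 2000) {
  if (nrow(assigned) == 0) return(0)
  win <- anchor_window(assigned, half_width)
  sum(window_signal(track, win) * assigned$loop_score)
}

#' Cumulative loop-weighted target scores
#'
#' For each promoter and each track (fusion and H2AK119ub), computes the
#' promoter component (summed signal over TSS +/- `flank`) and the distal
#' component (loop-score-weighted summed signal over 4-kb distal anchor
#' windows of assigned high-confidence loops). The cumulative score is the
#' sum over both tracks of promoter + distal components.
#'
#' @param promoters promoter annotation data.frame
#' @param loops loop data.frame (filtered internally at `fdr_max`)
#' @param tracks named list of `signal_track`s; must contain `fusion`
#'   and `H2AK119ub`
#' @param flank TSS window half-width
#' @param fdr_max loop FDR threshold
#' @param half_width distal anchor window half-width
#' @return data.frame, one row per promoter: per-track promoter/distal
#'   components, `promoter_component`, `distal_component`, `total`,
#'   `n_loops`
#' @export
cumulative_target_score <- function(promoters, loops, tracks, flank = 2000,
                                    fdr_max = 0.05, half_width = 2000) {
  need <- c("fusion", "H2AK119ub")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0) stop("missing track(s): ", paste(miss, collapse = ", "))
  hi <- filter_loops(loops, fdr_max)
  tss_win <- make_tss_window(promoters, flank)
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    assigned <- assign_loops_to_promoter(promoters[i, , drop = FALSE], hi, flank)
    comp <- lapply(need, function(tr) {
      prom <- window_signal(tracks[[tr]], tss_win[i, , drop = FALSE])
      dist <- distal_score(assigned, tracks[[tr]], half_width)
      c(prom = prom, distal = dist)
    })
    names(comp) <- need
    c(fusion_promoter = comp$fusion[["prom"]],
      fusion_distal = comp$fusion[["distal"]],
      ub_promoter = comp$H2AK119ub[["prom"]],
      ub_distal = comp$H2AK119ub[["distal"]],
      n_loops = nrow(assigned))
  })
  m <- do.call(rbind, res)
  out <- data.frame(gene_id = promoters$gene_id, m,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$promoter_component <- out$fusion_promoter + out$ub_promoter
  out$distal_component <- out$fusion_distal + out$ub_distal
  out$total <- out$promoter_component + out$distal_component
  out
}
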