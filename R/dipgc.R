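## Focal-loss ("dip") detection of BAF ChIP signal at TSSs, and promoter
## GC content over the 200 bp surrounding the TSS.

#' Central-to-flank signal ratio at promoters
#'
#' For each promoter: `central_mean` is mean signal/bp over
#' `[tss - central, tss + central)`; `flank_mean` is mean signal/bp over
#' the two flanking bands `[tss - flank_outer, tss - central)` and
#' `[tss + central, tss + flank_outer)` pooled. The dip ratio is
#' `central_mean / flank_mean`, undefined (NA, `degenerate = TRUE`) when
#' the flank mean falls at or below the noise floor (default 10% of the
#' track's mean per covered base). The ratio is invariant to uniform
#' rescaling of the track.
#'
#' @param track a `signal_track`
#' @param promoters promoter annotation data.frame
#' @param central central half-width in bp (default 250)
#' @param flank_outer outer flank half-width in bp (default 2000)
#' @param noise_floor_frac noise floor as a fraction of the track's mean
#'   per-base signal over covered bases
#' @return data.frame: `gene_id, central_mean, flank_mean, dip_ratio,
#'   degenerate`
#' @export
dip_ratio <- function(track, promoters, central = 250, flank_outer = 2000,
                      noise_floor_frac = 0.1) {
  stopifnot(flank_outer > central, central > 0)
  cen <- genomic_intervals(promoters$chrom,
                           pmax(0, promoters$tss - central),
                           promoters$tss + central)
  left <- genomic_intervals(promoters$chrom,
                            pmax(0, promoters$tss - flank_outer),
                            pmax(1, promoters$tss - central))
  right <- genomic_intervals(promoters$chrom,
                             promoters$tss + central,
                             promoters$tss + flank_outer)
  cen_sum <- window_signal(track, cen)
  fl_sum <- window_signal(track, left) + window_signal(track, right)
  cen_bp <- cen$end - cen$start
  fl_bp <- (left$end - left$start) + (right$end - right$start)
  central_mean <- cen_sum / cen_bp
  flank_mean <- fl_sum / fl_bp
  floor_val <- noise_floor_frac * track_total(track) / track_covered_bases(track)
  degenerate <- flank_mean <= floor_val
  data.frame(gene_id = promoters$gene_id,
             central_mean = central_mean,
             flank_mean = flank_mean,
             dip_ratio = ifelse(degenerate, NA_real_, central_mean / flank_mean),
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Call dip promoters
#'
#' A promoter is a dip iff its ratio is defined and `dip_ratio < ratio_max`
#' (strict; a ratio of exactly the threshold is not a dip).
#'
#' @inheritParams dip_ratio
#' @param ratio_max dip threshold in (0, 1), default 0.5
#' @return the [dip_ratio()] table with an `is_dip` logical column
#' @export
call_dips <- function(track, promoters, ratio_max = 0.5, central = 250,
                      flank_outer = 2000, noise_floor_frac = 0.1) {
  stopifnot(ratio_max > 0, ratio_max < 1)
  out <- dip_ratio(track, promoters, central, flank_outer, noise_floor_frac)
  out$is_dip <- !out$degenerate & out$dip_ratio < ratio_max
  out
}

#' GC content of the sequence surrounding each TSS
#'
#' Fraction (G + C) / (A + C + G + T) over the `window` bp centered on the
#' TSS (`[tss - window/2, tss + window/2)`), case-insensitive; N bases are
#' excluded from numerator and denominator. A window that is entirely N
#' yields NA.
#'
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome
#' @param promoters promoter annotation data.frame
#' @param window total window width in bp (default 200)
#' @return data.frame `gene_id, gc_fraction`
#' @export
gc_content <- function(genome, promoters, window = 200) {
  stopifnot(window >= 2)
  half <- floor(window / 2)
  gc <- vapply(seq_len(nrow(promoters)), function(i) {
    chrom <- promoters$chrom[i]
    if (!(chrom %in% names(genome))) stop("chromosome not in genome: ", chrom)
    seq <- genome[[chrom]]
    s <- max(1, promoters$tss[i] - half + 1)     # 1-based inclusive
    e <- min(length(seq), promoters$tss[i] + half)
    if (e < s) stop("TSS window outside sequence for ", promoters$gene_id[i])
    sub <- Biostrings::subseq(seq, s, e)
    counts <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    tot <- sum(counts)
    if (tot == 0) return(NA_real_)
    unname((counts[["G"]] + counts[["C"]]) / tot)
  }, numeric(1))
  data.frame(gene_id = promoters$gene_id, gc_fraction = gc,
             stringsAsFactors = FALSE)
}
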