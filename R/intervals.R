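#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom stats rnorm runif rbinom rgamma rlnorm rpois setNames
#' @importFrom utils read.table write.table head
NULL

## Coordinate convention: 0-based, half-open [start, end) everywhere,
## matching BED/narrowPeak/bedGraph on disk.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of sequence names
#' @param start 0-based start positions
#' @param end exclusive end positions (must satisfy `end > start`)
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

## GRanges bridge: shifts to 1-based closed coordinates internally.
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Pairwise interval overlap test
#'
#' Two half-open intervals overlap iff they share a chromosome and
#' `a.start < b.end` and `b.start < a.end`; abutting intervals do not overlap.
#'
#' @param a,b data.frames of intervals (recycled to a common length)
#' @return logical vector
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  a <- a[ai, , drop = FALSE]; b <- b[bi, , drop = FALSE]
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Symmetric window around a transcription start site
#'
#' Returns `[tss - flank, tss + flank)` clipped at zero. The window is
#' strand-symmetric, so strand is ignored.
#'
#' @param promoters data.frame with columns `chrom` and `tss`
#'   (and optionally `gene_id`, `strand`, `gene_label`)
#' @param flank half-width in bp (default 2000, i.e. TSS +/- 2 kb)
#' @return interval data.frame, one row per promoter, carrying `gene_id`
#'   when present
#' @export
make_tss_window <- function(promoters, flank = 2000) {
  stopifnot(flank > 0)
  w <- genomic_intervals(promoters$chrom,
                         pmax(0, promoters$tss - flank),
                         promoters$tss + flank)
  if (!is.null(promoters$gene_id)) w$gene_id <- promoters$gene_id
  w
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is dropped if it overlaps any blacklist interval by at least one
#' base (any-overlap rule, as in ENCODE blacklist filtering).
#'
#' @param peaks peak data.frame (see [read_peaks()])
#' @param blacklist interval data.frame
#' @return the retained peaks, order preserved
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(blacklist) == 0 || nrow(peaks) == 0) return(peaks)
  hits <- GenomicRanges::findOverlaps(.as_granges(peaks), .as_granges(blacklist))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) peaks else peaks[-drop, , drop = FALSE]
}

#' Build a signal track from piecewise-constant runs
#'
#' A signal track is a set of non-overlapping runs `(chrom, start, end, value)`
#' giving per-base signal; bases not covered by any run carry value 0.
#' Runs are sorted by (chrom, start) and validated.
#'
#' @param runs data.frame with columns `chrom`, `start`, `end`, `value`
#' @return object of class `signal_track`
#' @export
signal_track <- function(runs) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(runs)))
  if (any(runs$end <= runs$start)) stop("track run end must be > start")
  if (any(!is.finite(runs$value))) stop("track values must be finite")
  o <- order(runs$chrom, runs$start)
  runs <- runs[o, , drop = FALSE]
  by_chr <- split(runs, runs$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)]))
      stop("track runs overlap within chromosome ", ch$chrom[1])
  }
  rownames(runs) <- NULL
  structure(runs, class = c("signal_track", "data.frame"))
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d runs on %d chromosome(s), total signal %.4g\n",
              nrow(x), length(unique(x$chrom)), track_total(x)))
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Total signal of a track (sum over bases of per-base value)
#' @param track a `signal_track`
#' @return numeric scalar
#' @export
track_total <- function(track) sum((track$end - track$start) * track$value)

#' Number of bases covered by track runs
#' @param track a `signal_track`
#' @return numeric scalar
#' @export
track_covered_bases <- function(track) sum(track$end - track$start)

#' Summed signal over query windows
#'
#' For each window, sums per-base signal: each run contributes
#' `value * overlap_width`. Additive over any partition of a window.
#' Windows on chromosomes absent from the track return 0 with a warning.
#'
#' @param track a `signal_track`
#' @param windows interval data.frame
#' @return numeric vector, one summed value per window
#' @export
window_signal <- function(track, windows) {
  out <- numeric(nrow(windows))
  if (nrow(windows) == 0) return(out)
  missing_chr <- !(windows$chrom %in% unique(track$chrom))
  if (any(missing_chr))
    warning("chromosome(s) absent from track: ",
            paste(unique(windows$chrom[missing_chr]), collapse = ", "))
  if (nrow(track) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(.as_granges(windows), .as_granges(track))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(windows$end[qi], track$end[si]) - pmax(windows$start[qi], track$start[si])
  contrib <- ov * track$value[si]
  agg <- tapply(contrib, qi, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Mean per-base signal over query windows
#' @inheritParams window_signal
#' @return numeric vector of `window_signal / width`
#' @export
window_mean_signal <- function(track, windows) {
  window_signal(track, windows) / (windows$end - windows$start)
}

#' Average replicate tracks with depth normalization
#'
#' Each track is first rescaled so its genome-wide total equals the mean of
#' the input totals (read-depth normalization), then tracks are averaged
#' per base. Bases covered by no track in the input are absent from the
#' output (value 0).
#'
#' @param tracks list of `signal_track` objects
#' @return a `signal_track`
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  totals <- vapply(tracks, track_total, numeric(1))
  if (any(totals <= 0)) stop("cannot depth-normalize a zero-signal track")
  target <- mean(totals)
  n <- length(tracks)
  scaled <- Map(function(tr, tot) {
    tr$value <- tr$value * (target / tot)
    tr
  }, tracks, totals)
  ## disjoin the union of all run boundaries, then average values per piece
  all_runs <- do.call(rbind, lapply(scaled, as.data.frame))
  gr <- .as_granges(all_runs)
  pieces <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(pieces, gr)
  val <- numeric(length(pieces))
  agg <- tapply(all_runs$value[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  val[as.integer(names(agg))] <- as.numeric(agg)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(pieces)),
                    start = GenomicRanges::start(pieces) - 1,
                    end = GenomicRanges::end(pieces),
                    value = val / n,
                    stringsAsFactors = FALSE)
  out <- out[out$value != 0, , drop = FALSE]
  signal_track(out)
}
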