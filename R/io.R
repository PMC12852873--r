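## On-disk formats. All writers emit deterministic ordering
## (chrom lexicographic, then start) and tab separation; readers are strict
## and name the offending line on malformed input.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path)
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.num_or_stop <- function(x, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    stop(sprintf("malformed %s at line %d", what, line_no[bad[1]]))
  v
}

#' Read called peaks from narrowPeak or BED
#'
#' narrowPeak (10 columns) carries fold-enrichment in column 7 and a
#' -log10 q-value in column 9, which is decoded to a linear `qvalue`
#' (`10^-col9`; the `-1` sentinel for "not available" maps to `qvalue = 1`).
#' Plain BED3/BED6 rows get `enrichment = 0` and `qvalue = 0`.
#'
#' @param path narrowPeak or BED file
#' @return data.frame of peaks sorted by (chrom, start) with columns
#'   `chrom,start,end,name,score,strand,enrichment,pvalue_mlog,qvalue_mlog,
#'   peak_offset,qvalue`
#' @export
read_peaks <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(.empty_peaks())
  }
  f <- .split_fields(lines)
  ncol <- lengths(f)
  if (any(ncol < 3)) stop(sprintf("malformed peak line %d: fewer than 3 columns",
                                  which(ncol < 3)[1]))
  n <- length(f)
  get <- function(i, default) vapply(seq_len(n), function(j)
    if (ncol[j] >= i) f[[j]][i] else default, character(1))
  ln <- seq_len(n)
  pk <- data.frame(
    chrom = get(1, NA_character_),
    start = .num_or_stop(get(2, NA_character_), ln, "peak start"),
    end = .num_or_stop(get(3, NA_character_), ln, "peak end"),
    name = get(4, "."),
    score = .num_or_stop(get(5, "0"), ln, "peak score"),
    strand = get(6, "."),
    enrichment = .num_or_stop(get(7, "0"), ln, "peak enrichment"),
    pvalue_mlog = .num_or_stop(get(8, "-1"), ln, "peak p-value"),
    qvalue_mlog = .num_or_stop(get(9, if (any(ncol >= 9)) "-1" else "Inf"), ln,
                               "peak q-value"),
    peak_offset = .num_or_stop(get(10, "-1"), ln, "peak offset"),
    stringsAsFactors = FALSE)
  ## BED dialect (<7 cols): defaults enrichment 0, qvalue 0 (qvalue_mlog Inf)
  if (!any(ncol >= 9)) pk$qvalue_mlog <- Inf
  bad <- which(pk$end <= pk$start)
  if (length(bad) > 0) stop(sprintf("peak line %d: end <= start", bad[1]))
  pk$qvalue <- ifelse(pk$qvalue_mlog < 0, 1, 10^(-pk$qvalue_mlog))
  if (any(pk$enrichment < 0 & ncol >= 7))
    pk$enrichment[pk$enrichment < 0] <- 0
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

.empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             enrichment = numeric(), pvalue_mlog = numeric(),
             qvalue_mlog = numeric(), peak_offset = numeric(),
             qvalue = numeric(), stringsAsFactors = FALSE)
}

.fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         format(x, scientific = FALSE, trim = TRUE),
         vapply(x, function(v) as.character(v), character(1)))
}

#' Write peaks in narrowPeak dialect
#'
#' Emits the 10 narrowPeak columns, rows ordered by (chrom, start).
#' Reading the result back with [read_peaks()] and writing it again
#' reproduces the file byte-identically.
#'
#' @param peaks peak data.frame from [read_peaks()] or built in code
#' @param path output file
#' @export
write_peaks <- function(peaks, path) {
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  qm <- peaks$qvalue_mlog
  if (is.null(qm)) qm <- ifelse(peaks$qvalue > 0, -log10(peaks$qvalue), Inf)
  qm <- ifelse(is.infinite(qm), -log10(pmax(peaks$qvalue, 1e-300)), qm)
  lines <- paste(peaks$chrom, .fmt_num(peaks$start), .fmt_num(peaks$end),
                 peaks$name, .fmt_num(peaks$score), peaks$strand,
                 .fmt_num(peaks$enrichment), .fmt_num(peaks$pvalue_mlog),
                 .fmt_num(qm), .fmt_num(peaks$peak_offset), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path 4-column bedGraph file
#' @return a `signal_track`
#' @export
read_bedgraph <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(signal_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric())))
  f <- .split_fields(lines)
  if (any(lengths(f) < 4))
    stop(sprintf("malformed bedGraph line %d", which(lengths(f) < 4)[1]))
  m <- do.call(rbind, f)
  ln <- seq_along(lines)
  signal_track(data.frame(chrom = m[, 1],
                          start = .num_or_stop(m[, 2], ln, "bedGraph start"),
                          end = .num_or_stop(m[, 3], ln, "bedGraph end"),
                          value = .num_or_stop(m[, 4], ln, "bedGraph value"),
                          stringsAsFactors = FALSE))
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  o <- order(track$chrom, track$start)
  tr <- as.data.frame(track)[o, , drop = FALSE]
  writeLines(paste(tr$chrom, .fmt_num(tr$start), .fmt_num(tr$end),
                   .fmt_num(tr$value), sep = "\t"), path)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Columns 1-6 are the two anchors; `name` is column 7, the loop score
#' column 8, and the FDR is read from `fdr_col` (default 11, matching
#' loop callers that append q-values after the standard BEDPE columns).
#'
#' @param path BEDPE file
#' @param fdr_col 1-based index of the FDR column
#' @return data.frame with columns `chrom1,start1,end1,chrom2,start2,end2,
#'   name,loop_score,fdr`
#' @export
read_loops <- function(path, fdr_col = 11) {
  lines <- .read_lines_checked(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(.empty_loops())
  f <- .split_fields(lines)
  need <- max(8, fdr_col)
  if (any(lengths(f) < need))
    stop(sprintf("malformed BEDPE line %d: need >= %d columns",
                 which(lengths(f) < need)[1], need))
  m <- do.call(rbind, lapply(f, `[`, seq_len(need)))
  ln <- seq_along(lines)
  lp <- data.frame(chrom1 = m[, 1],
                   start1 = .num_or_stop(m[, 2], ln, "anchor1 start"),
                   end1 = .num_or_stop(m[, 3], ln, "anchor1 end"),
                   chrom2 = m[, 4],
                   start2 = .num_or_stop(m[, 5], ln, "anchor2 start"),
                   end2 = .num_or_stop(m[, 6], ln, "anchor2 end"),
                   name = m[, 7],
                   loop_score = .num_or_stop(m[, 8], ln, "loop score"),
                   fdr = .num_or_stop(m[, fdr_col], ln, "loop FDR"),
                   stringsAsFactors = FALSE)
  if (any(lp$fdr < 0 | lp$fdr > 1)) stop("loop FDR outside [0, 1]")
  if (any(lp$loop_score < 0)) stop("negative loop score")
  lp
}

.empty_loops <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             name = character(), loop_score = numeric(), fdr = numeric(),
             stringsAsFactors = FALSE)
}

#' Write loops as BEDPE
#'
#' Emits 11 columns: the 6 anchor fields, name, loop score, strand dots,
#' and the FDR in column 11, ordered by (chrom1, start1, chrom2, start2).
#'
#' @param loops loop data.frame (see [read_loops()])
#' @param path output file
#' @export
write_loops <- function(loops, path) {
  o <- order(loops$chrom1, loops$start1, loops$chrom2, loops$start2)
  lp <- loops[o, , drop = FALSE]
  writeLines(paste(lp$chrom1, .fmt_num(lp$start1), .fmt_num(lp$end1),
                   lp$chrom2, .fmt_num(lp$start2), .fmt_num(lp$end2),
                   lp$name, .fmt_num(lp$loop_score), ".", ".",
                   .fmt_num(lp$fdr), sep = "\t"), path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `tss` (0-based),
#' `strand` (+/-), `gene_label` (SAT/MAT/SST/none).
#'
#' @param path TSV file
#' @return promoter annotation data.frame
#' @export
read_tss <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "gene_label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("TSS table missing columns: ",
                             paste(miss, collapse = ", "))
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tab$tss < 0)) stop("tss must be >= 0")
  tab[need]
}

#' Write a TSS annotation table
#' @param promoters promoter annotation data.frame
#' @param path output file
#' @export
write_tss <- function(promoters, path) {
  o <- order(promoters$chrom, promoters$tss)
  write.table(promoters[o, c("gene_id", "chrom", "tss", "strand", "gene_label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] keyed by sequence name
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)
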