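## End-to-end orchestration: classify promoters and enhancers, score loop
## targets, call dips and GC, deconvolve the gradient, and assemble the
## statistics report, from a single validated configuration.

#' Build and validate a pipeline run configuration
#'
#' @param tss path to the TSS table
#' @param peaks named list of per-mark narrowPeak paths (names among the
#'   five histone marks)
#' @param fusion_peaks path to the fusion narrowPeak file
#' @param tracks named list of bedGraph paths; `fusion` and `H2AK119ub`
#'   are required for target scoring, `SMARCA4_ko` for dip calling
#' @param loops path to the BEDPE loop file
#' @param gradient path to the densitometry TSV
#' @param fasta optional genome FASTA (enables the GC stage)
#' @param outdir output directory
#' @param params named list of parameter overrides: `qmax` (0.001),
#'   `flank` (2000), `fdr_max` (0.05), `ratio_max` (0.5), `central` (250),
#'   `gc_window` (200), `broad_min_width` (2000), `n_random` (100),
#'   `seed` (1)
#' @return validated `run_config` list
#' @export
run_config <- function(tss, peaks, fusion_peaks, tracks, loops, gradient,
                       fasta = NULL, outdir, params = list()) {
  defaults <- list(qmax = 0.001, flank = 2000, fdr_max = 0.05,
                   ratio_max = 0.5, central = 250, gc_window = 200,
                   broad_min_width = 2000, n_random = 100, seed = 1)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  cfg <- list(tss = tss, peaks = peaks, fusion_peaks = fusion_peaks,
              tracks = tracks, loops = loops, gradient = gradient,
              fasta = fasta, outdir = outdir, params = defaults)
  inputs <- c(tss, unlist(peaks), fusion_peaks, unlist(tracks), loops,
              gradient, fasta)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = c("run_config", "list"))
}

.write_stage <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: promoter classification, enhancer classification
#' (distal fusion-peak loci), TSS fusion-peak profiling, loop-weighted
#' target scoring, dip calling and GC content, gradient deconvolution,
#' and the statistics report. Re-running with the same inputs and seed
#' reproduces every output byte-identically; a failure in one stage
#' leaves the outputs of completed stages on disk and names the failed
#' stage.
#'
#' @param cfg a validated [run_config()]
#' @return a run report list (also written to `report.json`)
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$params
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = p, stages = list())
  stage <- "load_inputs"
  result <- tryCatch({
    promoters <- read_tss(cfg$tss)
    peaksets <- lapply(cfg$peaks, read_peaks)
    fusion_pk <- read_peaks(cfg$fusion_peaks)
    tracks <- lapply(cfg$tracks, read_bedgraph)
    loops <- read_loops(cfg$loops)
    profiles <- read_gradient_profiles(cfg$gradient)

    stage <- "classify_promoters"
    cls <- classify_promoters(promoters, peaksets, p$qmax, p$flank)
    .write_stage(cls, cfg$outdir, "promoter_classes.tsv")
    report$stages$classify_promoters <- list(
      n = nrow(cls), classes = as.list(table(cls$class)))

    stage <- "classify_enhancers"
    ## candidate distal elements: fusion peaks clear of all TSS windows
    prom_win <- make_tss_window(promoters, p$flank)
    distal <- fusion_pk[!interval_overlaps_any(fusion_pk, prom_win), ,
                        drop = FALSE]
    enh_cls <- data.frame(name = character(), class = character())
    if (nrow(distal) > 0) {
      sig <- signature_at(distal, peaksets, p$qmax)
      enh_cls <- data.frame(name = distal$name, chrom = distal$chrom,
                            start = distal$start, end = distal$end,
                            class = classify_enhancer(sig),
                            stringsAsFactors = FALSE)
    }
    .write_stage(enh_cls, cfg$outdir, "enhancer_classes.tsv")
    report$stages$classify_enhancers <- list(
      n = nrow(enh_cls), classes = as.list(table(enh_cls$class)))

    stage <- "profile_tss_peaks"
    prof <- profile_tss_peaks(fusion_pk[fusion_pk$qvalue < p$qmax, ,
                                        drop = FALSE],
                              promoters, p$flank, p$broad_min_width)
    .write_stage(prof, cfg$outdir, "tss_peak_profiles.tsv")
    report$stages$profile_tss_peaks <- list(
      n = nrow(prof), shapes = as.list(table(prof$shape)))

    stage <- "score_targets"
    scores <- cumulative_target_score(promoters, loops, tracks, p$flank,
                                      p$fdr_max)
    .write_stage(scores, cfg$outdir, "target_scores.tsv")
    report$stages$score_targets <- list(
      n = nrow(scores), n_with_loops = sum(scores$n_loops > 0))

    stage <- "call_dips"
    dip_track <- tracks[["SMARCA4_ko"]]
    dips <- NULL
    if (!is.null(dip_track)) {
      dips <- call_dips(dip_track, promoters, p$ratio_max, p$central, p$flank)
      .write_stage(dips, cfg$outdir, "dip_calls.tsv")
      report$stages$call_dips <- list(n = nrow(dips), n_dip = sum(dips$is_dip))
    }

    stage <- "gc_content"
    gc <- NULL
    if (!is.null(cfg$fasta)) {
      genome_seq <- read_genome(cfg$fasta)
      gc <- gc_content(genome_seq, promoters, p$gc_window)
      .write_stage(gc, cfg$outdir, "gc_content.tsv")
      report$stages$gc_content <- list(n = nrow(gc),
                                       mean_gc = mean(gc$gc_fraction,
                                                      na.rm = TRUE))
    }

    stage <- "deconvolve_gradient"
    deconv <- deconvolve_gradient(profiles)
    .write_stage(data.frame(subtype = names(deconv$estimate$pct),
                            pct = as.integer(deconv$estimate$pct),
                            sse = deconv$estimate$sse),
                 cfg$outdir, "gradient_mixture.tsv")
    report$stages$deconvolve_gradient <- list(
      pct = as.list(deconv$estimate$pct), sse = deconv$estimate$sse)

    stage <- "stats_report"
    comparisons <- list()
    sat_w <- prof$width[prof$gene_label == "SAT"]
    mat_w <- prof$width[prof$gene_label == "MAT"]
    if (length(sat_w) >= 2 && length(mat_w) >= 2)
      comparisons$fusion_peak_width_SAT_vs_MAT <-
        list(groups = list(sat_w, mat_w), test = "welch_t")
    if (!is.null(dips) && !is.null(gc)) {
      rnd <- select_random_promoters(promoters, min(p$n_random,
                                                    nrow(promoters)), p$seed)
      dip_gc <- gc$gc_fraction[gc$gene_id %in% dips$gene_id[dips$is_dip]]
      rnd_gc <- gc$gc_fraction[gc$gene_id %in% rnd$gene_id]
      if (length(dip_gc) >= 2 && length(rnd_gc) >= 2)
        comparisons$gc_dip_vs_random <-
          list(groups = list(dip = dip_gc, random = rnd_gc),
               test = "kruskal_wallis")
    }
    stats_tab <- if (length(comparisons) > 0) stats_report(comparisons)
                 else data.frame()
    .write_stage(stats_tab, cfg$outdir, "stats_report.tsv")
    report$stages$stats_report <- list(n = nrow(stats_tab))

    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Any-overlap test of intervals against a window set
#'
#' @param x,windows interval data.frames
#' @return logical vector: does `x[i, ]` overlap any window?
#' @export
interval_overlaps_any <- function(x, windows) {
  out <- logical(nrow(x))
  if (nrow(x) == 0 || nrow(windows) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(.as_granges(x), .as_granges(windows))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
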