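# chromBAF

Downstream analysis toolkit for fusion-oncoprotein epigenomics in synovial
sarcoma models. The SS18::SSX fusion incorporates into SWI/SNF (BAF)
chromatin-remodeling complexes and retargets them to H2AK119ub-marked
chromatin; chromBAF implements the post-peak-calling computations used to
characterize that redistribution, for analysts working from called peaks,
signal tracks, and loops rather than raw reads:

* **Combinatorial histone-mark classification** of promoters (TSS ± 2 kb,
  peaks at q < 0.001): the fusion-activated `SAT_PATTERN` state
  (H2AK119ub⁺/H3K4me3⁺/H3K27ac⁺/H3K27me3⁻), `BIVALENT`
  (H3K4me3⁺/H3K27me3⁺), `REPRESSED`, `ACTIVE`; and of distal enhancers
  (H3K4me1 ∩ H3K27ac, split by H2AK119ub), with broad/narrow fusion-peak
  profiling at TSSs.
* **HiChIP loop-weighted target scores**: loops filtered at FDR < 0.05,
  4-kb midpoint-centered distal anchor windows, and per promoter the
  cumulative score
  `Σ_tracks [ signal(TSS ± 2 kb) + Σ_loops loop_score × signal(anchor ± 2 kb) ]`
  over the fusion and H2AK119ub tracks.
* **TSS dip detection**: central (±250 bp) vs flank (±250–2000 bp) mean
  signal ratio with a noise floor, calling focal loss of BAF signal in
  knockout conditions; plus promoter **GC content** over the 200 bp around
  the TSS.
* **Glycerol-gradient deconvolution**: Gaussian fits to subtype marker
  profiles (BRD9/DPF2/PBRM1 → GBAF/CBAF/PBAF) over fractions 12–24 and an
  exhaustive integer-percentage grid search (all 5,151 triples summing to
  100) minimizing the SSE against the observed pan-BAF SMARCC1
  distribution, with bootstrap intervals.
* **Statistics and phenotype formulas**: Welch t, Kruskal–Wallis, Dunn
  post hoc with Bonferroni, Wilcoxon rank-sum (exact for small n), binned
  track Pearson correlation, tumor volume `D·d²/2`, region-weighted
  nuclear shape index, and nuclear density.
* **A seeded synthetic-data generator** (`simulate_all()`) that emits
  FASTA, TSS tables, per-mark narrowPeak, bedGraph tracks, BEDPE loops,
  densitometry and morphometry TSVs together with a truth table, so the
  entire pipeline is testable without any sequencing download.

## Worked example

```r
library(chromBAF)

dir <- tempfile()
sim <- simulate_all(sim_config(seed = 1), dir)     # writes all input files

marks <- c("H2AK119ub", "H3K4me3", "H3K27ac", "H3K27me3", "H3K4me1")
run <- run_all(run_config(
  tss = file.path(dir, "tss.tsv"),
  peaks = setNames(as.list(file.path(dir, paste0(marks, ".narrowPeak"))), marks),
  fusion_peaks = file.path(dir, "fusion.narrowPeak"),
  tracks = list(fusion = file.path(dir, "fusion.bedGraph"),
                H2AK119ub = file.path(dir, "H2AK119ub.bedGraph"),
                SMARCA4_ko = file.path(dir, "SMARCA4_ko.bedGraph")),
  loops = file.path(dir, "loops.bedpe"),
  gradient = file.path(dir, "gradient.tsv"),
  fasta = file.path(dir, "genome.fa"),
  outdir = file.path(dir, "run")))

str(run$stages$classify_promoters$classes)
#> List of 4
#>  $ ACTIVE     : int 120
#>  $ BIVALENT   : int 60
#>  $ REPRESSED  : int 60
#>  $ SAT_PATTERN: int 60
unlist(run$stages$deconvolve_gradient$pct)
#> GBAF CBAF PBAF
#>   56   14   30
run$stages$call_dips$n_dip
#> [1] 60
```

On the default simulation (300 genes, noise-free marks) classification
recovers every planted promoter class (the four counts above equal the
planted mix), the gradient estimate lands within ~1 point of the planted
(55, 15, 30) under 5% densitometry noise, and all 60 planted knockout
dips are called with no false positives. Per-stage tables
(`promoter_classes.tsv`, `target_scores.tsv`, `dip_calls.tsv`,
`gradient_mixture.tsv`, `stats_report.tsv`, ...) and a `report.json` are
written to the output directory.

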