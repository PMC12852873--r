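---
title: "Methods: chromatin signatures, loop-weighted target scores, and BAF subcomplex deconvolution"
author: "chromBAF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin signatures, loop-weighted target scores, and BAF subcomplex deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromBAF)
```

# Scope and model

chromBAF implements the downstream, post-peak-calling computations used to
study how the SS18::SSX fusion oncoprotein redistributes SWI/SNF (BAF)
chromatin-remodeling activity in synovial sarcoma models. It consumes
standard files — called peaks (narrowPeak/BED), signal tracks (bedGraph),
chromatin loops (BEDPE), TSS tables, FASTA, densitometry TSVs — and
provides five analysis stages plus a seeded synthetic-data generator that
plants known truth for all of them. Read alignment, peak calling, and loop
calling are upstream and out of scope: the package starts from their
outputs.

All genomic coordinates are 0-based, half-open, matching the on-disk
formats. Interval overlap machinery is delegated to GenomicRanges/IRanges;
sequences are handled with Biostrings.

# Promoter and enhancer signatures

A mark is *present* at a window when at least one called peak of that mark
with q-value `< 0.001` (strict, configurable) overlaps the window. Windows
are TSS ± 2 kb, strand-symmetric. The promoter rule set, applied in
precedence order:

* **SAT_PATTERN** — H2AK119ub⁺, H3K4me3⁺, H3K27ac⁺, H3K27me3⁻: the
  fusion-activated promoter state in which a PRC1-repressive mark
  (H2AK119ub) coexists with active marks;
* **BIVALENT** — H3K4me3⁺, H3K27me3⁺;
* **REPRESSED** — H3K27me3⁺ alone;
* **ACTIVE** — H3K4me3⁺, H3K27ac⁺ without H2AK119ub (the maintained-active
  control state);
* **UNCLASSIFIED** otherwise.

The precedence only resolves flag combinations outside the four canonical
states; SAT_PATTERN and BIVALENT are disjoint by construction (they differ
on H3K27me3). Distal elements are enhancers when H3K4me1 and H3K27ac peaks
intersect, split into ub⁺/ub⁻ by H2AK119ub; a candidate overlapping any
promoter window is rejected as not distal.

Promoter-associated fusion peaks are profiled by width and enrichment and
split into BROAD vs NARROW at 2 kb (strict `>`, configurable; an optional
two-means split of log widths places the boundary data-adaptively). The
2-kb default was chosen once as the natural separator between the
mark-peak-scale narrow mode (hundreds of bp) and the domain-scale broad
mode (several kb); the data show two width modes but no printed cutoff
exists, so the parameter is exposed.

"Within 2 kb of any TSS" is operationalized as interval overlap with the
TSS ± 2 kb window, consistent with every other windowed computation here;
whether the defining mark peak must cover the TSS itself or merely the
window is not specified upstream, and window overlap is adopted.

# Loop-weighted target scores

Loops pass the filter when `FDR < 0.05` (strict). For a promoter, a loop is
assigned when exactly one anchor overlaps the TSS window; both-anchor
("self") loops carry no distal element and are excluded. Each distal anchor
is standardized to a 4-kb window centered on the anchor midpoint —
midpoint-centering makes the score independent of the caller's native
anchor width. The score for track $s$ (fusion or H2AK119ub) is

$$
T_s(g) \;=\; \underbrace{\sum_{b \in \mathrm{TSS} \pm 2\,\mathrm{kb}} s(b)}_{\text{promoter}}
\;+\; \underbrace{\sum_{\ell \in L(g)} w_\ell \sum_{b \in A_\ell} s(b)}_{\text{distal}},
$$

with $w_\ell$ the loop score and $A_\ell$ the 4-kb distal anchor window;
the cumulative score sums fusion and H2AK119ub. The loop weight applies to
the distal term only (the promoter term carries no loop), and both tracks
are weighted identically. The score is linear in the track and additive
over loops, and the test suite checks it against a naive promoters × loops
double loop.

# Dip detection and GC content

Focal loss ("dip") of general-BAF ChIP signal at a promoter — the
signature of residual-complex displacement in knockout conditions — is
quantified as the ratio of the mean per-base signal over TSS ± 250 bp to
the pooled mean over the flanking bands (±250 to ±2000 bp). A promoter is
a dip call when the ratio is `< 0.5`. The call is suppressed (degenerate)
when the flank mean is at or below a noise floor, default 10% of the
track's mean per covered base — this avoids calling dips in unexpressed
loci where both windows are near zero. All four geometry/threshold
parameters are exposed. The upstream work displays dips in heatmaps
without a printed rule, so this ratio is this package's own operational
definition; absolute dip counts from other rules are not expected to
match.

GC content is (G+C)/(A+C+G+T) over the 200 bp centered on the TSS (±100
bp), case-insensitive, with N excluded from both counts; it is invariant
to strand by complement symmetry.

# Gradient deconvolution

Glycerol-gradient densitometry gives, per marker, 24 fraction
intensities; assembled BAF complexes sediment in fractions 12–24 and only
those are analyzed. Subtype markers (BRD9 → GBAF, DPF2 → CBAF, PBRM1 →
PBAF) are each fitted with a Gaussian in fraction index by nonlinear least
squares (Levenberg–Marquardt, moment initialization, moment fallback on
non-convergence; the two agree exactly on noise-free Gaussian input). A
fit whose sd collapses below 0.1 fractions is rejected as degenerate.

Each fitted component is sampled at fractions 12–24 and renormalized to
unit sum, as is the observed pan-BAF (SMARCC1) profile, so the objective
compares probability-like vectors and is invariant to blot exposure. The
mixture estimate is the integer triple (GBAF, CBAF, PBAF) summing to 100
that minimizes the sum of squared differences between predicted and
observed distributions — an exhaustive search over all 5,151 candidates,
with ties broken lexicographically for determinism. A residual-resampling
bootstrap provides percentile intervals. No printed reference percentages
exist to compare against, so correctness is established by
forward-construction (zero-noise mixtures are recovered exactly with zero
SSE) and by simulation (≈0.9 points mean absolute error per component at
5% multiplicative noise with components at means 14/17/20, sd 1.2).

# Statistics

Welch's heteroscedastic *t* (two-tailed), Kruskal–Wallis with midrank ties
correction (applied always; the upstream description does not state it,
but omitting it is never preferable), Dunn's post-hoc z with pooled-rank
ties correction and Bonferroni adjustment over all pairs, and the Wilcoxon
rank-sum test (exact enumeration for combined n ≤ 12 without ties, normal
approximation with continuity and ties corrections otherwise; the two
branches agree within 0.02 at the switch point). Binned Pearson
correlation partitions the genome into fixed bins — optionally restricted
to a site list — sums each track per bin, and correlates the bin vectors.
Phenotype formulas: tumor volume $D d^2/2$ (mm³, long/short caliper
diameters), region-fraction-weighted nuclear long/orthogonal axis ratio
(three nuclei per region), and nuclear density per 500 µm² square with an
explicit conversion to mm⁻².

# The synthetic-data generator

`sim_config()` fixes the study conditions: 2 chromosomes × 10 Mb, 300
genes (class mix 0.2/0.2/0.2/0.4 for SAT_PATTERN/BIVALENT/REPRESSED/
ACTIVE), TSSs placed on a wide, collision-free grid (± 1 kb jitter), flag
flip rate ε = 0 by default, broad fusion peaks log-normal (median 6 kb),
narrow median 400 bp on half the ACTIVE promoters, 2 loops per SAT
promoter with 30% decoys at FDR ≥ 0.05, gradient components at means
14/17/20 (sd 1.2) with true percentages (55, 15, 30) and 5%
multiplicative log-normal noise, CpG-island GC 0.65 over 600 bp on a 0.40
baseline, and knockout dip depth 0.1. These sizes are desk-scale choices
that reproduce the qualitative structure of the real data (two fusion
peak-width modes, fusion/GBAF co-localization, island-elevated GC at dip
promoters) while keeping the full test suite fast; every value is
overridable.

Design notes worth recording:

* **Noise models.** Bernoulli flag flips for peak presence, additive
  truncated-Gaussian noise for tracks, multiplicative log-normal noise
  for densitometry — the simplest models respecting each data type's
  support. Under flips, a present mark loses its peak and an absent one
  gains a passing peak, so classification accuracy has an exact
  closed-form expectation by enumerating the 2⁴ (promoter) or 2³
  (enhancer) flip patterns; the acceptance suite checks measured accuracy
  against it.
* **Analytic truth for scores.** Promoter signal is a binned Gaussian
  profile spanning exactly the TSS ± 2 kb window, and enhancer signal is a
  1-kb rectangle lying wholly inside its 4-kb anchor window, so the truth
  table's expected score components are simple closed-form sums computed
  independently of the package's overlap machinery, and zero-noise
  recovery must be exact to double precision.
* **Enhancer placement.** Distal enhancers sit 10–25 kb from their TSS in
  alternating-sign slots, guaranteeing (i) distality relative to all
  promoter windows and (ii) disjoint signal rectangles within a gene.
* **Determinism.** Each generator stage draws from its own seed offset
  under a restore-on-exit RNG guard, so one seed fixes every emitted byte
  and stages can be re-run independently.

What the generator does *not* emulate: mappability and copy-number
artifacts, read-level sampling noise, correlated flag errors (real peak
callers fail non-independently), asymmetric or multi-modal sedimentation
peaks, and inter-chromosomal loops. Passing tests therefore demonstrate
the correctness of the computations under the stated models, not the
biological error rates to expect on real libraries.

# Numerical choices and degenerate inputs

Strict inequalities at every published threshold (q < 0.001, FDR < 0.05,
dip ratio < 0.5, width > 2 kb) so boundary cases are deterministic.
narrowPeak q-values are decoded from the −log10 column (sentinel −1 → 1);
bare BED rows get enrichment 0 and q-value 0. Writers emit
chromosome-lexicographic, full-precision text so write → read → write is
byte-identical. Zero-signal tracks cannot be depth-normalized and raise an
error; a window on a chromosome absent from a track scores 0 with a
warning. The mixture grid search rebuilds all 5,151 candidates per call
(vectorized; milliseconds) rather than caching, keeping the function pure.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
dir <- tempfile()
sim <- simulate_all(cfg, dir)

marks <- c("H2AK119ub", "H3K4me3", "H3K27ac", "H3K27me3", "H3K4me1")
run <- run_all(run_config(
  tss = file.path(dir, "tss.tsv"),
  peaks = setNames(as.list(file.path(dir, paste0(marks, ".narrowPeak"))),
                   marks),
  fusion_peaks = file.path(dir, "fusion.narrowPeak"),
  tracks = list(fusion = file.path(dir, "fusion.bedGraph"),
                H2AK119ub = file.path(dir, "H2AK119ub.bedGraph"),
                SMARCA4_ko = file.path(dir, "SMARCA4_ko.bedGraph")),
  loops = file.path(dir, "loops.bedpe"),
  gradient = file.path(dir, "gradient.tsv"),
  fasta = file.path(dir, "genome.fa"),
  outdir = file.path(dir, "run")))
str(run$stages$deconvolve_gradient)
```

Problem sizes used throughout the tests: the default 300-gene genome for
end-to-end checks, 30-gene genomes for unit fixtures, 50 seeds for the
noisy-classification comparison, 200 replicates for mixture-recovery
simulation, and 2,000 replicates for the type-I-error audit of the three
tests.

# Known limitations

The dip rule and the broad/narrow boundary are declared operational
definitions, not recovered constants; counts derived from them are not
comparable across rule choices. The Gaussian component model cannot
represent skewed sedimentation profiles; with heavily overlapping
component means the mixture becomes ill-conditioned and recovery error
grows (verified monotone in simulation). Bootstrap intervals are
percentile intervals on a discrete integer grid and can be conservative
near the simplex boundary.
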