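# dagfit — ellipse parametrization of bimodal single-cell expression

Two-layer single-cell protocols (spliced/unspliced quantification, or
metabolic labeling of new vs. old transcripts) measure two counts per gene
per cell, so each gene places every cell in a 2-D *phase plane*:
mature RNA on the x-axis, nascent RNA on the y-axis. Under the standard
two-stage model of transcription — synthesis at rate α, maturation at
rate β, degradation at rate γ — a cell population at or near steady state
forms an elliptical cloud in this plane.

`dagfit` exploits that geometry. Per gene and phenotype it fits the conic

&nbsp;&nbsp;&nbsp;&nbsp;a·x² + b·xy + c·y² + d·x + e·y + f = 0,&nbsp;&nbsp;
with b² − 4ac < 0,

by direct constrained least squares (Fitzgibbon's formulation solved
through the numerically stable Halır–Flusser 3×3 reduced eigensystem),
and compares the two phenotypes of each gene through two statistics:

* **θ** = |φ₁ − φ₂| — the absolute difference of the major-axis
  orientations (degrees, not folded), and
* **ω** — the Sørensen–Dice overlap 2·|A∩B| / (|A|+|B|) of the two
  ellipse areas, estimated by box counting on a shared grid.

Crossing small/large ω with small/large θ yields four transcription
modality scenarios. Genes with a distinct angle but similar total
expression — **differentially angled genes (DAGs)**: full major-axis
length above a preset threshold in both fits, 10° < θ < 160°, mean
expression > 10 and |log₂ fold change| < 1 — separate phenotypes in ways
invisible to total-count differential expression, which calls **DEGs**
(|LFC| ≥ 1, FDR ≤ 0.01, mean > 10). The two definitions are mutually
exclusive by the LFC gates. Calls are intersected across batches plus the
pooled data ("recurrent" genes) and ranked by the minimal semi-axis ratio
over all fits (near-circular fits have unstable angles and rank last).

The package is aimed at people analyzing splicing- or labeling-resolved
single-cell data who want modality changes, not just abundance changes:
it provides the preprocessing chain for two-layer count matrices, the two
fitting strategies (free, and major-axis-through-origin), a bootstrap for
fit stability, the θ/ω statistics and modality classifier, DEG/DAG calling
with recurrence and ranking, GSEA-ready `.rnk` exports, a synthetic-data
generator with known ground truth, and a command-line interface.

## Worked example

```r
library(dagfit)

sim <- simulate_dataset(seed = 11)           # 100 genes, 3 batches, known truth
cfg <- preprocess_config("crc", seed = 11)   # library bounds 2000-50000, var >= 3
res <- run_pipeline(sim$matrix, cfg, c("ph1", "ph2"))
print(res)
```

```
dagfit pipeline result: 4 runs (b1, b2, b3, pooled)
  b1        100 genes fitted,  40 DEGs,  41 DAGs
  b2        100 genes fitted,  40 DEGs,  42 DAGs
  b3        100 genes fitted,  40 DEGs,  42 DAGs
  pooled    100 genes fitted,  40 DEGs,  41 DAGs
recurrent: 40 DEGs, 40 DAGs (DEG/DAG overlap: 0)
```

All 40 planted expression-shift genes come back as recurrent DEGs, all 40
planted angle-shift genes as recurrent DAGs, and the two sets never
overlap. The per-gene statistics live in `res$runs$pooled$stats` (theta,
omega, areas, axis ratios, scenario); overlap medians reproduce the
expected ordering — DEGs lowest, DAGs intermediate, non-relevant genes
near 1:

```r
st  <- res$runs$pooled$stats
grp <- ifelse(st$gene %in% res$runs$pooled$degs, "DEG",
       ifelse(st$gene %in% res$runs$pooled$dags, "DAG", "nonrel"))
tapply(st$omega, grp, median)
#>       DAG       DEG    nonrel
#> 0.7614449 0.2937058 0.9503209
```

A single gene end to end:

```r
fit <- fit_ellipse(gene_pair_clouds(preprocess(sim$matrix, cfg)$matrix,
                                    "s4_g01", c("ph1", "ph2"), cfg)$ph1$points)
fit
#> Ellipse fit (free strategy), 399 points
#> ellipse: center (0.5371, 0.4425), semi-axes (0.2669, 0.1777), phi 50.17 deg
#> fit error (mean_abs): 0.0786
```

This is one phenotype of a planted scenario-4 gene: a moderately
elliptical cloud (axis ratio 1.5) tilted to about 50°; its partner
phenotype is tilted across the other diagonal, giving a large angle
difference at high overlap — the DAG signature.
(`coef()`, `summary()`, `predict()`,
`residuals()` and `plot()` methods are available on the fit object, and
`bootstrap_fit()` gives percentile confidence intervals for the angle.)

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/dagfit.R simulate --out data --seed 11
Rscript inst/cli/dagfit.R call --in data --phenotypes ph1,ph2 \
    --profile crc --out results
```

## Layout

```
R/                  implementation (fitting, geometry, preprocessing,
                    modality stats, differential calls, synthetic data)
inst/cli/dagfit.R   command-line interface
tests/testthat/     unit, property and end-to-end tests
vignettes/          methods vignette (model, conventions, limitations)
scripts/acceptance.R
```
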