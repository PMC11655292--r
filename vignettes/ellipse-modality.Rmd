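---
title: "Ellipse models of bimodal single-cell expression: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipse models of bimodal single-cell expression: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagfit)
```

## The model

Two-layer single-cell data measure, per gene and cell, a nascent
(unspliced or newly synthesized) count $u$ and a mature (spliced or
pre-existing) count $s$. The two-stage kinetic picture — synthesis at
rate $\alpha$, maturation at rate $\beta$, degradation at rate $\gamma$ —
implies that a homogeneous cell population scatters around the steady
state of the $(s, u)$ phase plane, and that the scatter of a well-mixed
population is approximately a bivariate normal cloud: an ellipse.

`dagfit` therefore summarizes each (gene, phenotype) cloud by the conic

$$a x^2 + b x y + c y^2 + d x + e y + f = 0,
  \qquad b^2 - 4ac < 0,$$

fitted by direct constrained least squares: minimize $\lVert D\mathbf a
\rVert^2$ subject to $\mathbf a^{\mathsf T} C \mathbf a = 1$, where $D$
is the design matrix of monomials and $C$ encodes the ellipse constraint
$4ac - b^2 = 1$. The generalized eigenproblem $S\mathbf a = \lambda C
\mathbf a$ ($S = D^{\mathsf T} D$) is solved through the numerically
stable 3×3 reduced system (splitting $D$ into quadratic and linear
blocks), whose unique eigenvector with $4 a_1 a_3 - a_2^2 > 0$ yields the
quadratic coefficients; the linear ones follow by back-substitution. Data
are mean-centered before building the moment matrices, for conditioning,
and the conic is shifted back afterwards. Noiseless perimeter samples are
recovered to near machine precision (the test suite requires every
geometric parameter within $10^{-6}$ for axis ratios up to 20).

Geometry extraction uses the standard relations: the center solves the
gradient system, the squared semi-axes are $-f_c/\lambda_i$ for the
eigenvalues $\lambda_i$ of the quadratic form ($f_c$ = conic value at the
center), and the major-axis orientation is the half-angle
$\varphi = \tfrac12\,\mathrm{atan2}(b,\,a-c)$, disambiguated to the major
axis through the eigenvectors and reported in degrees in $[0, 180)$.
When the semi-axes agree to within $10^{-9}$ (relative) the orientation
is undefined; the package sets $\varphi = 0$ and flags the fit
near-circular — such fits carry no angular information, which is exactly
what the semi-axis-ratio rank (below) encodes.

### Two fitting strategies

* **free** (default): the algebraic fit above. An optional `refine`
  step polishes it by direct Nelder–Mead minimization of the geometric
  fit error over (center, orientation, log semi-axes). The polish uses
  several starts — the algebraic solution, a perpendicular and two
  elongated variants, the center-direction orientation, and the
  origin-constrained optimum itself — because the mean-absolute
  perimeter distance has multiple local basins on noisy clouds. Seeding
  with the constrained optimum makes
  $\mathrm{rmsd}(\text{free, refined}) \le \mathrm{rmsd}(\text{origin
  axis})$ hold by construction, turning the mathematical nesting of the
  two model families into a numerical guarantee.
* **origin_axis**: the major-axis line is forced through the origin —
  the steady-state-line assumption of the velocity phase plane.
  Parametrized as $(\varphi, t, A, B)$ with center $t(\cos\varphi,
  \sin\varphi)$ and optimized on the same geometric error, initialized
  from the free fit (center-direction and orientation-projection
  starts).

Both geometric optimizers restrict the axis ratio to at most 20. This is
the method's validity domain: unconstrained mean-absolute-distance
minimization degenerates into arbitrarily long thin strips threaded
through a cloud, which carry no biological meaning for phase-plane data.

### Fit error and point–ellipse distance

The fit error is the mean of absolute point-to-perimeter distances
(a true root-mean-square option exists: `rmsd_method = "rms"`), always
computed on un-jittered coordinates. The perimeter distance maps the
point into the ellipse frame and solves the first-quadrant foot-point
equation $F(s) = (Ax/(s+A^2))^2 + (By/(s+B^2))^2 - 1 = 0$ by Newton
iteration from the left bracket endpoint; $F$ is convex and decreasing
there, so the iteration converges monotonically without overshoot
(relative accuracy better than $10^{-8}$; points on the axes and circles
use closed forms).

## From fits to modality calls

For each gene the two phenotype fits give

* $\theta = |\varphi_1 - \varphi_2|$, the raw absolute angle difference
  in $[0, 180)$ — deliberately **not** folded to $[0, 90]$, because the
  DAG relevance window $10^\circ < \theta < 160^\circ$ presupposes the
  raw difference (a pair at 5° and 175° yields $\theta = 170$ and is
  excluded, although the axes are geometrically close);
* $\omega$, the Sørensen–Dice overlap $2|A\cap B|/(|A|+|B|)$ of the two
  ellipse areas. Analytic ellipse–ellipse intersection requires quartic
  root machinery, so all three areas are box-counted on one shared grid:
  cell centers of a `resolution`² grid (default 512) over the joint
  bounding box expanded by 2%, deterministically. Using the same grid
  for both areas and the intersection keeps the estimate symmetric and
  inside $[0,1]$. At resolution 512 the area error against $\pi A B$ is
  below 0.1% and the overlap matches the circle–circle closed form to
  about $3\times10^{-4}$. The denominator is the *sum* of areas (the
  standard Dice); a Jaccard option (`denominator = "union"`) exists for
  comparison.

The four modality scenarios cross small/large $\omega$ with small/large
$\theta$: 1 = small/small, 2 = small overlap + large angle, 3 = large
overlap + small angle, 4 = large/large. "Large angle" means
$\theta_{\mathrm{thr}} < \theta < 180 - \theta_{\mathrm{thr}}$ (default
10°, matching the DAG window); "large overlap" means $\omega \ge
\omega_{\mathrm{thr}}$ with a default of 0.5 — a package convention (the
$\omega$ distributions motivate a mid-range cutover but no published
number exists), exposed as a parameter.

### Differential calls

DEGs: $|\mathrm{LFC}| \ge 1$, $\mathrm{FDR} \le 0.01$, mean expression
$> 10$ (inclusive/strict exactly as the operators read). The preferred
input is an externally computed DE table (`read_de_table()`, DESeq2-style
columns); a built-in two-sided Wilcoxon rank-sum fallback on
library-normalized totals with Benjamini–Hochberg adjustment
(`compute_builtin_de()`) keeps the pipeline self-contained and is
labelled as such — it is not claimed equivalent to a dedicated engine.

DAGs: full major-axis length $> 0.1$ (cc preset) or $> 0.01$ (crc
preset) in min–max-normalized coordinates — required of **both**
phenotype fits, since both angles enter $\theta$ and a tiny ellipse has
an unreliable angle; $10^\circ < \theta < 160^\circ$; mean expression
$> 10$; $|\mathrm{LFC}| < 1$. The mean-expression gate is evaluated in
at least one phenotype by default (`mean_mode = "both"` available); the
published text does not say which. DEG ∩ DAG = ∅ follows from the LFC
gates and is asserted on every output.

Recurrent genes are the strict intersection of calls across runs (each
batch and the pooled data). The rank of a gene is the minimum over all
runs and both phenotypes of the semi-axis ratio (major/minor), and genes
are reported in descending rank: high ellipticity means a trustworthy
angle. Two pre-ranked `.rnk` exports are written for external GSEA,
ordered by $-\log_{10}(\mathrm{FDR}+0.001)\cdot\mathrm{LFC}$ and by
$\theta_\pi \cdot \mathrm{rank}$ with $\theta_\pi = \theta/180$ (θ in
pi-radians); `rank` is the semi-axis-ratio rank value (the published
metric is ambiguous between that and an ordinal position; the rank value
is used).

The comparison of $\theta$ distributions between DEGs and non-relevant
genes (non-DEGs with DAGs removed) uses the two-sided Wilcoxon rank-sum
test with the Hodges–Lehmann 95% shift interval — the standard companion
of the rank-sum test, assumed because the published interval estimator is
not named. Exact p-values are used for small tie-free samples; the test
suite pins the implementation against an exhaustive-permutation oracle
for group sizes up to 8.

## Preprocessing conventions

The chain is fixed in this order, with two named presets:

| step | cc preset | crc preset |
|------|-----------|------------|
| library-size bounds (inclusive) | 40 000–150 000 | 2 000–50 000 |
| gene variance filter (sample variance, $n-1$) | — | ≥ 3 |
| library normalization | count / cell total × mean viable-cell total | same |
| per-phenotype mean count (both phenotypes) | > 5 | > 5 |
| non-zero cells per phenotype | ≥ 20 | — |
| DAG major-axis-length gate | 0.1 | 0.01 |

Then gene-wise: drop cells with zero nascent, mature or total count for
that gene; min–max normalize the two axes independently; drop cells
above the 99th percentile (type-7 quantile, the mainstream default) on
**both** axes (literal reading of the joint-outlier rule; an "or" switch
exists); optionally jitter. Printed bounds are inclusive; "> 5" and
"> 10" are strict. The percentile trim can remove a cloud's joint
maximum, so normalized coordinates lie in $[0,1]^2$ but need not attain
1 after trimming.

Two normalization scopes are exposed. `build_gene_cloud()` normalizes by
the cloud's own range (each phenotype fills its own unit box), and also
accepts an explicit range. The pairwise pipeline (`gene_pair_clouds()`)
normalizes both phenotypes by the shared per-gene range of the pooled
pair: the overlap $\omega$ is only meaningful when the two ellipses live
in one coordinate system — an expression-shifted gene must show a *low*
overlap, which per-phenotype re-normalization would erase. Because the
shared map is one affine transform applied to both clouds, $\omega$ is
identical to its raw-count-plane value (Dice is affine-invariant), and
angles transform monotonically.

Jitter emulates a base-R-style uniform perturbation: amplitude
(axis range)/50 per coordinate, seeded per gene. It exists solely to
avoid singular moment matrices when counts are heavily discretized;
fitting uses jittered coordinates, while the fit error and all displays
use the un-jittered points.

`knn_smooth()` (k nearest neighbours on the joint per-cell profile,
self included, per phenotype or pooled) is included only to demonstrate
how smoothing distorts phase-plane shape; it is not part of the
recommended pipeline.

## Bootstrap

`bootstrap_fit()` resamples cells with replacement and adds uniform
jitter in $[-\varepsilon, +\varepsilon]$ per coordinate (the
conventional $\varepsilon = 0.5$ is half a count on the raw count
scale — rescale when bootstrapping normalized clouds), refits, and
records the orientation and area of each replicate; failed replicates
are counted, never imputed, and more than 50% failures is an error. The
reported interval is the percentile interval. Because the published
procedure says only that fits were bootstrapped and jittered, a
jitter-only mode (`resample = FALSE`) is also provided. Percentile
intervals on angles near the 0/180 wrap can be distorted; for strongly
elliptical clouds away from the wrap, 100-repeat calibration runs show
~95–98% empirical coverage of the true orientation. The conventional
replicate count is 1000; the shipped tests and the acceptance script use
200 replicates per cloud, which stabilizes the 2.5% and 97.5%
percentiles well enough for coverage assessment at a fraction of the
cost.

## The synthetic-data generator

`simulate_gene()` draws each phenotype as a bivariate normal in the unit
phase plane — center, 2σ semi-axes, orientation — then maps to counts by
scale (`count_scale`, default 40), round, truncate at zero, and finally
zeroes whole cells at a per-phenotype dropout rate. The Gaussian model
matches the elliptical premise of the method; it is deliberately not a
negative-binomial hierarchy, because fitting operates after
normalization where the elliptical cloud is the object of interest.
`simulate_dataset()` tiles genes from the four scenario presets plus
non-relevant fillers over several batches (small seeded perturbations of
angle and center per batch), balances fold-change directions so library
composition stays comparable between phenotypes, applies a log-normal
per-cell library-size factor, and plants a known fraction of cells below
and above the library bounds so the cell filters are exercised. Per-gene,
per-batch RNG streams are derived from the master seed, so any single
gene is reproducible in isolation.

Preset geometry (unit plane; conventions, chosen once so every preset's
analytic θ and ω fall inside its scenario's quadrant with a margin):

* **scenario 1** (small ω, small θ → DEG): two disjoint clouds with equal
  angles and a 3.7× total-count shift.
* **scenario 2** (small ω, large θ → DAG): two separated thin clouds
  (axis ratio 3.2) crossed at 90°, equal totals.
* **scenario 3** (large ω, small θ → DEG): nested same-angle ellipses
  with the expression shift realized through expression *frequency* —
  dropout 0.65 vs 0.05 — rather than position. A positional shift large
  enough for $|\mathrm{LFC}| \ge 1$ geometrically precludes $\omega \ge
  0.5$ for non-negative counts (the required spread pushes probability
  mass below zero), whereas a gene that fires in fewer cells of one
  phenotype but with identical kinetics when on yields LFC ≈ 1.4 at
  Dice ≈ 0.64 — the accessibility picture of modality change.
* **scenario 4** (large ω, large θ → DAG): co-centered clouds of axis
  ratio 1.6 crossed at 45° (orientations straddling 90°, so the angle
  difference survives normalization), equal totals; Dice ≈ 0.8.
* **non_relevant**: identical distributions; ω ≈ 0.9, θ ≈ 0.

These levels also stagger ω so the published qualitative ordering —
median ω(DEGs) < median ω(DAGs) < median ω(non-relevant) — emerges from
the geometry rather than from tuning.

What the generator does *not* emulate: overdispersed count noise,
ambient contamination, doublets, batch effects beyond small parameter
perturbations, pseudotime structure along the phase portrait, or
cell-cycle phase mixtures. Passing the recovery tests therefore shows
the machinery is correct and well-calibrated on elliptical data; it does
not certify performance on the full messiness of real scSLAM-seq or
spatial cell-cycle data, whose headline gene counts additionally depend
on an external DE engine and QC stack that are out of scope here.

## Numerical choices and degenerate inputs

* Fewer than 6 usable cells (6 = number of conic coefficients) is an
  explicit error, as is a singular scatter matrix (collinear points);
  callers may jitter and retry — the pipeline does this by default.
* The returned conic is scaled to $4ac - b^2 = 1$ with $a > 0$; the
  geometry round-trips through `geometry_to_conic()` within $10^{-9}$.
* Angles live in degrees in $[0,180)$ everywhere; radians appear only at
  math boundaries.
* Box-count resolution must be ≥ 64; convergence against $\pi AB$ is
  monotone in expectation over random ellipses (individual ellipses can
  fluctuate between neighbouring resolutions).
* All randomness (jitter, bootstrap, simulation) is seed-controlled;
  every pipeline run writes a JSON manifest with the effective
  configuration, seed and per-stage counts.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the method at these sizes,
chosen to exercise every claim while staying light: 200 random ellipses
(ratio ≤ 20) for exact recovery; 50 center distances at resolution 512
for the overlap oracle; 100 repeats of 500-cell clouds (axis ratio 3,
orientation 40°) with 200 bootstrap replicates each for angle recovery
and CI coverage; 200 synthetic genes at 300 cells per phenotype for
classifier recovery; and the default synthetic dataset (100 genes, 3
batches, 150 cells per phenotype per batch, count scale 40 with the crc
preset) for the end-to-end DEG/DAG recovery and ω ordering.

## Known limitations

Least-squares conic fits are outlier-sensitive; the pipeline mitigates
with the percentile trim, normalization and bootstrap rather than robust
M-estimation, which would be the natural next step. The angle is
meaningless for near-circular fits — use the rank (minimal semi-axis
ratio) as the confidence weight it is designed to be. Low-expression
genes yield unstable fits; the mean-count and axis-length gates exist
precisely to keep them out. The built-in DE fallback is a rank-sum test
on totals, adequate for synthetic validation but not a substitute for a
dedicated single-cell DE engine on real data.
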