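---
title: "Stage-aware multi-modal sparse regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-aware multi-modal sparse regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdmm)
```

## The problem

Imaging-genetics association studies ask which brain phenotypes covary with
a genetic risk variant. `msdmm` implements a single-SNP, multi-phenotype
formulation for depression cohorts staged by the 24-item Hamilton scale
(HAM-D24): healthy controls (HC, score ≤ 8), moderate depression (MD,
20–34), severe depression (SD, ≥ 35). Each subject contributes a
two-modality brain phenotype network over the 116 regions of the AAL atlas:

* **node features** — mean gray-matter density per ROI, averaged from a
  voxel-wise density volume within each atlas region;
* **edge features** — per-ROI weighted clustering coefficients of the
  subject's functional-connectivity (FC) network, built as the Pearson
  correlation matrix of ROI-mean BOLD time series (each series standardized
  to zero mean, unit variance).

The clustering coefficient of node $i$ uses weights scaled by the largest
connection weight in the network, $\bar w = w / \max(w)$:

$$CC(i) = \frac{2}{k_i(k_i - 1)} \sum_{\{j,h\}} \bar w_{ij}\,\bar w_{ih}\,\bar w_{jh},$$

summing over unordered pairs of neighbours of $i$; $k_i$ is the number of
incident nonzero edges and nodes with $k_i < 2$ score 0. Two points are
deliberate:

* The triple term is the plain **product** of the three scaled weights, not
  the cube-root (geometric-mean) form common elsewhere. With the
  $2/(k_i(k_i-1))$ factor this keeps $CC \in [0,1]$ and reduces to the
  binary clustering coefficient on unit-weight graphs. The cube-root
  variant is available via `geometric = TRUE` but is not the default.
* Pearson FC matrices contain negative weights, which the $\max(w)$ scaling
  does not anticipate. The default takes absolute values before scaling
  (`negative = "abs"`); clipping negatives to zero is the alternative. No
  FC thresholding and no Fisher-z transform are applied by default — the
  network stays fully weighted, so $k_i = d - 1$; an optional proportional
  threshold exists for sensitivity analyses.

## The association model

With $M$ modality matrices $X^m \in \mathbb{R}^{N \times d}$ and the
additively coded genotype $y \in \{0,1,2\}^N$, the full model (MSD-MM)
minimizes

$$\frac12 \sum_{m=1}^M \lVert y - X^m w^m \rVert_2^2
  + \lambda_1 \lVert W \rVert_{2,1}
  + \lambda_2 \sum_{m=1}^M (w^m)^\top (X^m)^\top L^m X^m w^m,$$

where $W = [w^1, \dots, w^M] \in \mathbb{R}^{d \times M}$ and
$\lVert W\rVert_{2,1} = \sum_j \lVert w_j \rVert_2$ sums the Euclidean
norms of the *rows* — the group-sparsity penalty that selects the same ROIs
in every modality. $L^m = D^m - S^m$ is the unnormalized graph Laplacian of
the same-stage similarity matrix ($S_{ij} = 1$ iff subjects $i,j$ share a
diagnosis stage); its quadratic form equals half the similarity-weighted
sum of squared differences between predicted values, so it pulls same-stage
subjects' predictions together. Stages are per-subject, so $S^m$ is
identical across modalities; it is stored per modality to keep the indexing
of the objective explicit. The Laplacian is not normalized; the ablation
variants follow the standard grid — SM (one modality), CM (concatenated
features, where the row penalty reduces to the lasso), MM (multi-task, no
Laplacian), and their `MSD-` counterparts with the stage term. The plain
variants force $\lambda_2 = 0$; the $\lambda_2$-at-zero code path is
bit-identical to MM by construction.

Two choices the objective itself leaves open:

* **Intercept and scaling.** The printed objective has no intercept.
  Densities and clustering coefficients have nonzero means, and penalized
  coefficients need comparable column scales, so by default each feature
  column is z-scored with *training* statistics and the model is fit to the
  centered response; `mean(y_train)` is stored as the per-modality
  intercept at prediction time. The response itself is never rescaled, so
  RMSE stays on the 0–2 genotype scale. Constant columns get a unit divisor
  with a warning.
* **Laplacian weighting.** The stage term enters exactly as written —
  $\lambda_2 \sum_m w^\top X^\top L X w$, with no factor $\tfrac12$ — even
  though the pairwise-distance expansion introduces a factor 2; the
  equality between the two forms is asserted by a property test.

## The solver

The objective is convex: a smooth quadratic (loss + Laplacian term) plus
the nonsmooth row penalty, solved by accelerated proximal gradient:

* gradient of the smooth part, column-wise:
  $(X^m)^\top(X^m w^m - y) + 2\lambda_2 (X^m)^\top L^m X^m w^m$;
* proximal step: the row-wise group soft-threshold
  $w_j \leftarrow \max(0, 1 - \tau/\lVert v_j \rVert_2) v_j$;
* step size: backtracking (halving) initialized from a power-iteration
  estimate of the largest curvature block
  $(X^m)^\top(I + 2\lambda_2 L^m) X^m$;
* momentum with a function-value safeguard: if the accelerated candidate
  increases the objective, momentum restarts and a plain proximal step is
  taken from the best iterate, so the recorded objective trace is
  non-increasing;
* termination: relative objective change ≤ `tol` (default 1e-6) or
  `max_iter` (default 1000).

For $\lambda_1 \ge \max_j \lVert [\,(X^1)^\top y, \dots, (X^M)^\top y\,]_j
\rVert_2$ (`lambda1_max()`, computed on the standardized scale the solver
uses) the zero matrix satisfies the optimality condition and the fit is
exactly zero — the upper end of any sensible penalty grid.

## Evaluation harness

`nested_cv()` runs repeated, stage-stratified k-fold cross-validation
(default 5×5): within each outer training set an inner k-fold grid search
selects $(\lambda_1, \lambda_2)$ minimizing mean inner-test RMSE averaged
over modalities (RMSE because it is the fitted loss; per-modality selection
is available via the grids), the model is refit on the full outer-training
set, and held-out RMSE and the Pearson correlation (CC) between predicted
and true genotype are recorded per modality. Repeats use fold seeds
`seed + r`. Stratification matters because the severe group is small
(about 17% of subjects); unstratified folds can lose a stage entirely.

ROI ranking averages the **absolute** fitted weights over all outer folds
and repeats (signed means are reported alongside; without the absolute
value, sign flips across folds cancel). `screen_snps()` repeats the whole
nested evaluation once per candidate SNP and ranks SNPs by mean test CC;
`sensitivity_grid()` maps mean test CC over a fixed $(\lambda_1,
\lambda_2)$ grid with shared folds; `permutation_null_cc()` provides a
seeded permutation null for calibration. No site/age/gender adjustment is
performed.

The default penalty grid is the half-decade ladder $10^{-5}, 3\times
10^{-5}, \dots, 1, 3$ for both penalties. Note the loss is unnormalized
(no $1/N$), so the informative $\lambda_1$ range scales with $N$: at
$N = 150$ on standardized synthetic features the fit goes from dense to
exactly empty across roughly $0.3$–$40$ (`lambda1_max()` ≈ 40). Grids
should bracket that path; the package's own acceptance runs use the ladder
restricted to $\{0.3, 1, 3, 10, 30\}$ for $\lambda_1$ and $\{10^{-5},
10^{-3}, 10^{-1}\}$ for $\lambda_2$, the small value making the Laplacian
term negligible so the full model nests MM.

## The synthetic cohort generator

Real cohort data cannot ship with the package, so `simulate_cohort()`
generates cohorts with exactly the structure the model assumes:

* **stages** in the pooled proportions of a two-site staged depression
  cohort (HC 64 / MD 78 / SD 29 of 171);
* **genotype** under Hardy–Weinberg equilibrium. The modeled SNP is a
  disease-*risk* variant, so the default minor-allele frequency rises with
  severity (HC 0.2, MD 0.35, SD 0.45; pooled ≈ 0.3), sampled under HWE
  within stage. This matters: if genotype and stage are independent, the
  stage Laplacian carries no information about the response, and the full
  model can only match MM up to hyperparameter-selection noise — we
  verified this empirically (mean paired test-CC gap ≈ −0.006 over ten
  seeds under an independent genotype). With the risk-gradient default the
  stage term is genuinely informative, and permuting stages destroys
  exactly that information — the property the direction-of-effect test
  exploits. Pass a scalar `maf` to simulate a stage-unrelated variant.
* **features**: a common support of `support_size` rows carries the
  genotype signal with modality-specific coefficients
  $c^m_j \sim N(1, 0.1)$, every subject of a stage shares a stage-specific
  mean shift, and the rest is Gaussian noise:
  $X^m_{ij} = \beta g_i c^m_j \mathbf{1}[j \in R] + \delta \mu_{s(i),j} +
  \varepsilon_{ij}$. Defaults: $N = 150$, $d = 116$, $|R| = 10$,
  $\beta = 0.5$, $\sigma = 1$, and $\delta = 0.5$ — a stage effect of the
  same order as the genotype effect, so stage structure is visible but does
  not dominate. The generator runs cause→effect (genotype causes features)
  while the model regresses genotype on features; this mirrors the
  phenotype→genotype regression direction of the association model.
* **raw-level fixtures**: `simulate_timeseries()` (block-community BOLD
  series with stage-dependent within-block correlation) and
  `simulate_atlas_volume()` (labeled density blocks with known region
  means) exercise the full feature-extraction path end to end.

All generators are bit-reproducible given a seed. What the generator does
*not* emulate: spatial voxel correlation, hemodynamics, scanner/site
effects, linkage disequilibrium between SNPs, and non-Gaussian noise —
so passing tests demonstrate correctness of the estimation machinery under
the model's own assumptions, not robustness to real-data violations of
them.

## Numerical choices and degenerate inputs

* Zero-variance BOLD series are an error naming the ROI; all-zero FC
  networks yield all-zero clustering coefficients with a warning
  ($\max(w)$ undefined).
* Absent triple edges contribute 0 to the clustering sum ($w_{jh} = 0$).
* CC between predicted and observed genotype is defined as 0 (flagged
  degenerate) when predictions have zero variance — the saturated-penalty
  regime.
* Inner-CV ties on RMSE break toward the first grid point (smaller
  $\lambda_1$, then smaller $\lambda_2$); allele-frequency ties in additive
  coding make the lexicographically smaller allele "major"; top-edge ties
  break by partner ROI name. All ties are therefore deterministic.
* HAM-D24 scores 9–19 fall between the control and patient definitions and
  stage to `NA` with a warning, mirroring the cohort's gap.
* Missing genotype calls are flagged and listwise-dropped per SNP;
  imputation is out of scope.

## Problem sizes used by the shipped checks

The test-suite and acceptance runs use the generator at its default study
conditions ($N = 150$) with $d = 116$ for support recovery and screening,
and a reduced feature dimension ($d = 20$, support 4) for the
variant-comparison sweeps, where many nested cross-validations are run per
seed; solver-versus-oracle checks use tiny instances ($N = 20$, $d = 8$)
where a plain proximal-gradient reference can be run to a numerical fixed
point. These sizes are the package's own choices for desk-scale
verification; all of them can be raised through the same function
arguments.

## Known limitations

* The direction-of-effect advantage of MSD-MM over MM on synthetic data is
  small: stage-shifted features already carry most of the stage
  information, so the Laplacian adds little beyond what the features
  expose. The shipped test asserts direction (non-negative paired gap),
  not magnitude.
* Single-SNP response only; no multivariate-response variant.
* No covariate adjustment, no significance testing of CC differences, and
  no multiple-testing correction across screened SNPs (raw CCs are
  reported, matching the reporting conventions of the design this package
  implements).
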