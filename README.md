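# msdmm

Stage-aware multi-modal sparse regression for imaging genetics.

## What it does

Imaging-genetics studies of major depressive disorder ask which brain
phenotypes covary with a genetic risk variant (an additively coded SNP,
0/1/2). `msdmm` builds a two-modality **brain phenotype network** per
subject over the 116 AAL atlas regions —

* *node features*: ROI-mean gray-matter densities from a voxel-wise
  density volume and an atlas;
* *edge features*: per-ROI weighted clustering coefficients
  `CC(i) = 2/(k_i(k_i−1)) · Σ_{j,h} w̄_ij w̄_ih w̄_jh` of the Pearson
  functional-connectivity network, with weights scaled by the maximum
  connection weight —

and regresses the SNP on both feature sets jointly (the **MSD-MM** model):

    min_W  ½ Σ_m ‖y − X^m w^m‖² + λ₁‖W‖₂,₁ + λ₂ Σ_m (w^m)ᵀ(X^m)ᵀ L^m X^m w^m

The row-wise L2,1 penalty selects the *same* ROIs in every modality; the
graph Laplacian `L = D − S` of the same-diagnosis-stage similarity matrix
(stages HC/MD/SD from HAM-D24 scores) pulls same-stage subjects' predicted
values together. The convex objective is solved by accelerated proximal
gradient with backtracking and a monotone safeguard. The ablation variants
SM, CM, MM, MSD-SM and MSD-CM are included, together with the full
evaluation harness: repeated stage-stratified nested cross-validation
(RMSE and prediction–genotype correlation per modality), ROI ranking by
cross-validated weight magnitude, top-edge reports from group-average FC
networks, per-SNP screening, penalty-sensitivity grids, and a seeded
synthetic-cohort generator with a planted sparse causal support so every
claim is testable without cohort data.

Audience: methodologists and analysts working on multimodal
neuroimaging–genotype association who need a reproducible reference
implementation with its statistical machinery fully under test.

## Worked example

```r
library(msdmm)

# a synthetic staged cohort at the default study conditions, scaled down
sim <- simulate_cohort(n = 150, d = 20, support_size = 4, seed = 42)
table(sim$stages)
#> HC MD SD
#> 56 68 26

# fit the full model at fixed penalties
fit <- msdmm_fit(sim$X, sim$y, sim$stages, lambda1 = 10, lambda2 = 0.001,
                 variant = "MSD-MM")
fit
#> <msdmm_fit> variant=MSD-MM  lambda1=10  lambda2=0.001
#>   20 features x 2 modalities; 9 nonzero rows; converged in 13 iterations

# nested cross-validated evaluation
cv <- nested_cv(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                lambda1_grid = c(1, 3, 10, 30),
                lambda2_grid = c(1e-5, 1e-3, 1e-1),
                repeats = 2, k = 5, seed = 1)
summary(cv)
#>   modality rmse_train cc_train rmse_test   cc_test rmse_test_sd cc_test_sd
#> 1     edge  0.5547506 0.593221 0.6002210 0.5099313   0.06425378  0.1110768
#> 2     node  0.5171281 0.666844 0.5718228 0.5870990   0.07233376  0.1060984

# which ROIs carry the association?
rank_rois(cv, modality = "node", top_k = 5)
#>   rank     roi mean_abs_weight mean_weight
#> 1    1 ROI_003      0.16147527  0.16147527
#> 2    2 ROI_019      0.14664372  0.14664372
#> 3    3 ROI_018      0.13616835  0.13616835
#> 4    4 ROI_007      0.06798803 -0.06798803
#> 5    5 ROI_014      0.06447632  0.06447632

sim$support
#> [1]  3 14 18 19
```

The fit keeps 9 of 20 feature rows; held-out correlation is ≈ 0.59 (node)
and ≈ 0.51 (edge) on the 0–2 genotype scale, and four of the five
top-ranked ROIs are the planted causal rows (3, 19, 18, 14). The weight
sign is informative (`mean_weight`); ranking uses the absolute value so
fold-to-fold sign flips cannot cancel.

A command-line pipeline wraps the same functions
(`system.file("cli", "msdmm.R", package = "msdmm")`):

```sh
Rscript msdmm.R simulate --n 150 --d 20 --timepoints 100 --seed 7 --out sim/
Rscript msdmm.R build-features --timeseries-dir sim/timeseries --out sim/
Rscript msdmm.R cv --node sim/features_node.tsv --edge sim/features_edge.tsv \
    --genotype sim/genotype.tsv --stages sim/stages.tsv --seed 7 --out cv/
Rscript msdmm.R rank-rois --weights cv/cv_weights.tsv --modality node --top-k 10 --out cv/
```

Every command writes a manifest (config, seed, input checksums, package
version) and reruns bit-identically under the same seed.

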