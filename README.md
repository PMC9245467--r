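# igesel — integrative gene–environment interaction analysis

`igesel` implements a two-stage penalized variable-selection model for
gene–environment (G×E) interaction studies that *vertically* integrates
multi-omics data: gene expressions together with their upstream
regulators (DNA methylation and copy-number alteration), rather than
pooling all omics layers as exchangeable predictors. It is aimed at
statistical genomics researchers who want to identify which genes, G×E
interactions and regulators drive a continuous disease outcome, and at
methodologists who need the simulation benchmark (data generator, LASSO
baselines, ROC/partial-AUC scoring) that goes with it.

## The model

Let `Y` (n) be the outcome, `E` (n×q) environmental factors, `G`
(n×p_g) gene expressions, and `R` (n×p_r) stacked regulators.

**Stage 1 — linear regulatory models (LRMs).** Each expression is
regressed on all regulators by LASSO,

    (1/2n) ||g_j − a_j − R θ_j||² + λ |θ_j|₁ ,

giving a sparse transition matrix `Θ̂ = (θ̂_1 … θ̂_{p_g})`. A recursive
rank-1 **sparse SVD** with deflation decomposes
`Θ̂ ≈ Σ_l d_l u_l v_lᵀ`; each triplet `(d_l, u_l, v_l)` is an LRM
linking a sparse set of regulators (support of `u_l`) to a sparse set of
expressions (support of `v_l`).

**Stage 2 — bi-level G×E model.** Expressions split into regulated
scores `GV_l = G v_l` and perpendicular-projection residuals `G̃`;
regulators are residualized to `R̃` the same way. The penalized model

    (1/2n) ||Y − Eα − X1 b1 − X2 b2 − R̃γ||²
      + λ Σ_l (||b1_l||₂ + ||b1_l||₁)
      + λ Σ_j (||b2_j||₂ + ||b2_j||₁)
      + λ ||γ||₁

uses one block of `q+1` columns per LRM (`X1`) and per residual gene
(`X2`): the main effect plus its q environmental interactions. The
sparse-group (bi-level) penalty selects whole blocks and individual
slots inside them; environmental main effects are unpenalized (weak
hierarchy); a single λ ties all three penalty terms. The solver
alternates a closed-form `α` update with blockwise sparse-group and
coordinate-wise LASSO updates (RcppArmadillo, Gram-based), with
warm-started paths over a shared penalty grid.

The package also ships the benchmark **simulator** (AR-1 / banded /
custom regulator covariance, rank-L sparse transition matrix, linear
outcome model), the **S-LASSO / J-LASSO** single-stage baselines, and
**ROC / partial-AUC** machinery for selection accuracy against the
generating truth.

## Worked example

```r
library(igesel)

cfg <- sim_config(n = 300, p_g = 60, p_r = 60, q = 4, L_true = 6,
                  support_size = 5, n_causal_genes = 10,
                  n_causal_regulators = 10, seed = 42)
sim <- simulate_dataset(cfg)
sim$dataset
#> omics_dataset: 300 subjects, 60 gene expressions, 60 regulators ( 30 + 30 ), 4 environmental factors

s1 <- fit_stage1(sim$dataset$G, sim$dataset$R, L = 6, seed = 42)
s1
#> regulatory_fit: 6 LRMs from a 60 x 60 transition matrix
#>   singular values: 55.8, 55, 50.5, 42.8, 37.3, 36.4
#>   loading supports: |u| = 5,5,5,5,5,5 ; |v| = 5,5,5,5,5,5

des <- decompose_dataset(sim$dataset, s1)
path <- fit_path(des)
path
#> path_fit: 100 penalty values in [ 0 , 3 ]; df range 0-390

roc_from_path(path, sim$truth, "gene_gxe", s1)
#> roc_result [gene_gxe]: 5 points, FPR range [0, 1], PAUC = 0.7034
roc_from_path(path, sim$truth, "regulators", s1)
#> roc_result [regulators]: 3 points, FPR range [0, 1], PAUC = 0.7105

roc_from_path(fit_j_lasso_path(sim$dataset), sim$truth, "gene_gxe")
#> roc_result [gene_gxe]: 12 points, FPR range [0, 1], PAUC = 0.7078
```

Reading the output: Stage 1 recovered six regulatory models, each
linking 5 regulators to 5 genes (the generating support size), with the
scale carried by the singular values. The path fit traverses the shared
penalty grid from the empty model (λ = 3) to the dense unpenalized
anchor (λ = 0); `PAUC` is the trapezoidal area under the selection ROC
built across that path, scored against the generating truth — here the
integrative model identifies gene/G×E effects and outcome-relevant
regulators with accuracy ≈ 0.70-0.71, against 0.5 for random selection.

A full-size benchmark replicate (`p_g = p_r = 200`, `n = 500`, the
published design) runs in ~20 s; `replicate_summary()` aggregates
mean ± sd PAUCs over replicates per covariance, signal strength, method
and family, in the layout of the published summary tables. A thin
command-line front end (`inst/cli/igesel.R`) exposes
`simulate` / `fit-stage1` / `fit` / `evaluate` with manifests for exact
re-runs.

The methods vignette (`vignettes/integrative-gxe-methods.Rmd`) explains
the model, every tunable parameter, the standardization and penalty-grid
conventions, what the simulator does and does not emulate, and a candid
account of which published benchmark quantities this implementation
reproduces and which it does not (and why).

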