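---
title: "Integrative gene-environment interaction analysis: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative gene-environment interaction analysis: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igesel)
```

## The scientific problem

Gene-environment (G×E) interaction studies ask how environmental
exposures modify the association between genetic features and a disease
outcome. When multi-omics data are available, gene expression does not
stand alone: DNA methylation and copy-number alterations regulate it.
Pooling all layers as exchangeable predictors (parallel integration)
ignores this regulatory flow; `igesel` implements a vertical-integration
alternative in two stages.

**Stage 1 — sparse regulatory models.** With expressions
$G \in \mathbb{R}^{n \times p_g}$ and stacked regulators
$R \in \mathbb{R}^{n \times p_r}$, each expression is regressed on all
regulators by LASSO,

$$\tfrac{1}{2n}\lVert g_j - a_j - R\theta_j\rVert_2^2 + \lambda
\lvert\theta_j\rvert_1,$$

giving a sparse transition matrix
$\widehat\Theta = (\widehat\theta_1,\dots,\widehat\theta_{p_g})$. A
recursive rank-1 *sparse SVD* then decomposes
$\widehat\Theta \approx \sum_{l=1}^{L} d_l u_l v_l^\top$: each triplet
$(d_l, u_l, v_l)$ is a *linear regulatory model* (LRM) linking a small
set of regulators (support of $u_l$) to a small set of expressions
(support of $v_l$). Each rank-1 problem minimizes

$$\tfrac{1}{2n}\lVert M - d\,uv^\top\rVert_F^2
  + \lambda_{svd}\lvert d\,u\rvert_1 + \lambda_{svd}\lvert d\,v\rvert_1$$

by alternating soft-thresholded regressions with unit-norm factors
($d$ carries the scale), followed by deflation
$M \leftarrow M - \widehat d\,\widehat u \widehat v^\top$.

**Stage 2 — bi-level penalized G×E model.** Expressions are split into
regulated scores $GV_l = G v_l$ and perpendicular-projection residuals
$\widetilde G_j = (I - P_{S_j}) G_j$, where $S_j$ indexes the LRMs whose
$v$-loading carries gene $j$ (genes in no LRM pass through unchanged);
regulators are residualized the same way against $RU_l = R u_l$. With
environments $E \in \mathbb{R}^{n \times q}$, the design stacks blocks
$X_{1l} = (GV_l, GV_l E_1, \dots, GV_l E_q)$ and
$X_{2j} = (\widetilde G_j, \widetilde G_j E_1, \dots, \widetilde G_j E_q)$,
and the model

$$\tfrac{1}{2n}\bigl\lVert Y - E\alpha - X_1 b_1 - X_2 b_2 -
\widetilde R \gamma \bigr\rVert_2^2
+ \lambda \sum_l \bigl(\lVert b_{1l}\rVert_2 + \lVert b_{1l}\rVert_1\bigr)
+ \lambda \sum_j \bigl(\lVert b_{2j}\rVert_2 + \lVert b_{2j}\rVert_1\bigr)
+ \lambda \lVert \gamma \rVert_1$$

is fit by alternating (i) the closed-form unpenalized update
$\widehat\alpha = (E^\top E)^{-1} E^\top(Y - X_1 b_1 - X_2 b_2 -
\widetilde R\gamma)$, (ii) sparse-group-LASSO updates over the $L + p_g$
blocks of size $q+1$, and (iii) coordinate-wise LASSO updates for
$\gamma$. The sparse-group penalty selects whole LRM (or residual-gene)
blocks and individual main/interaction slots inside them — bi-level
selection. Environmental main effects are never penalized (weak
hierarchy: a selected interaction always has its environmental main
effect in the model), and one $\lambda$ ties all three penalty terms.

## Algorithms and numerical choices

* The Stage-2 problem is jointly convex. The solver (RcppArmadillo) works
  on precomputed Gram matrices with incremental fitted-correlation
  updates; each sparse-group block uses the exact zero test
  $\lVert \mathrm{soft}(X_b^\top r / n, \lambda)\rVert_2 \le \lambda$ and
  otherwise an inner proximal-gradient loop on the blockwise objective.
  Every update decreases the objective; the test suite verifies the
  final objective against an independent proximal-gradient solver run on
  the full problem. Convergence: maximum coefficient change below
  `tol = 1e-5`, at most `max_iter = 500` sweeps; paths are fit in
  descending $\lambda$ with warm starts.
* The rank-1 sparse SVD alternates $\tilde u = \mathrm{soft}(Mv,
  n\lambda)$ and $\tilde v = \mathrm{soft}(M^\top u, n\lambda)$ with
  renormalization, stopping when the fitted rank-1 matrix changes by
  less than `1e-6` in Frobenius norm (at most 200 alternations; the
  Stage-1 wrapper allows 1000 because near-tied singular values converge
  slowly). The sign ambiguity is fixed by making the
  largest-magnitude entry of $v$ positive. A zero matrix returns the
  zero triplet.
* Per-gene LASSO penalties are chosen by five-fold cross-validation per
  gene (shared fold assignment, seeded); a fixed shared `lambda` is
  available. Columns of $G$ and $R$ are centered, not variance-scaled:
  expressions and their regulators arrive on comparable scales, and the
  intercept absorbs means.
* $\lambda_{svd}$ defaults to a BIC-type choice over a small grid of
  thresholds proportional to the largest transition weight. Because
  soft-thresholding biases loadings downward — which would inflate the
  residual at every nonzero penalty and steer any naive criterion toward
  the densest candidate — each candidate is scored on support-restricted
  *debiased* rank-1 refits, with the residual normalized by a robust
  (MAD) noise scale estimated from the nonzero entries of
  $\widehat\Theta$ and `log(#cells)` charged per nonzero loading entry.
  A fixed numeric `lambda_svd` overrides this.
* Membership tests on loadings use $|v_{lj}| > 10^{-12}$; thresholded
  loadings are exactly zero, so this is a safe machine-zero guard.
  Rank-deficient score blocks fall back to pseudo-inverse projection
  with a warning.
* **Standardization.** The Stage-2 and baseline penalized problems are
  solved on unit-variance design columns and a unit-variance response,
  with coefficients back-transformed to original units. This puts the
  shared penalty grid on the correlation scale: on the benchmark
  designs, raw regulated-expression scores have standard deviations in
  the tens, and without standardization the entire printed grid sits
  deep inside the dense regime (every regulated block active at the
  largest penalty), making path-based selection meaningless.
* **The penalty grid.** The benchmark grid is 100 equally spaced values
  on $[0, 3]$, *including the exact zero endpoint*. At $\lambda = 0$ the
  problem is solved as unpenalized minimum-norm least squares, whose
  coefficients are generically all nonzero; this anchors every selection
  ROC curve at the select-everything corner, which matters because the
  partial AUC is defined without extrapolation (below). A glmnet-style
  log-spaced alternative (`spacing = "log"`) is provided for analyses
  that need to resolve the weak-signal tail of the path; it is not the
  benchmark default because it materially changes the baseline methods'
  curves as well (see "Reproduction fidelity").

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the benchmark designs:
regulator rows are mean-zero multivariate normal under an AR-1
($0.25^{|i-j|}$), banded ($0.33$ at lag one), or user-supplied
covariance; a rank-$L$ transition matrix is built from sparse loading
vectors with disjoint supports (five Uniform(2,4) entries per vector by
default — disjointness is the construction that realizes the orthogonal
loading assumption exactly); expressions are $G = R\Theta +
\varepsilon$ with noise sharing the regulator covariance; environments
are AR-1($0.5$) normal; and the outcome adds environmental main effects
(Uniform(2,3)), gene main effects and G×E interactions on 30 causal
genes (4 of the $q+1$ slots each; Uniform(0.25,0.5) weak or
Uniform(0.5,1) strong), direct regulator effects on 30 regulators
(Uniform(1,2)), and standard normal error. All coefficients are
positive — the generator draws from positive uniforms only, with no
random sign flips. One integer seed drives a single RNG stream in a
fixed draw order, so a configuration reproduces bit-identically.

What the generator does **not** emulate: real methylation/CNA marginal
distributions (beta-valued, discrete), empirical covariances estimated
from tumor cohorts, missingness, batch structure, or censored survival
outcomes. Passing benchmarks here demonstrates correctness of the
machinery and selection behavior under the stated Gaussian designs, not
performance on real multi-omics data.

The 30 causal regulators are sampled uniformly from all $p_r$,
independent of the loading supports; the realized overlap is recorded in
the ground truth. The `disjoint` and `normalize_loadings` flags expose
the two generator ambiguities we identified (see below).

## Evaluation: selection calls, ROC, partial AUC

Fitted models live partly in LRM space, so selection is mapped back to
features: gene slot $(j,k)$ is called when the residual coefficient
$b_{2jk}$ is nonzero **or** some LRM $l$ carrying gene $j$ has $b_{1lk}$
nonzero; regulator $t$ is called when $\gamma_t$ is nonzero **or** some
LRM carrying it is selected at all. Baseline calls are read directly off
coefficient supports.

Two evaluation families are scored against the generating truth:

* `gene_gxe` — all $p_g(q+1)$ main/interaction slots against the true
  gene-effect pattern;
* `regulators` — the $p_r$ regulators against the *pathway* truth: a
  regulator is positive when it carries a direct effect ($\gamma$) or
  participates in any generating LRM (support of $U$), i.e. its signal
  reaches the outcome directly or through the expression layer.
  `regulators_direct` restricts positives to the direct effects. The
  pathway definition is the package default: it is the definition under
  which the integrative model's published regulator accuracies (and the
  published ordering of the baselines) are reproduced, and it matches
  the vertical-integration reading of "identifying regulators" —
  regulators that matter through mediation count. The choice is
  consequential (the direct-only reading scores the integrative model
  ~0.2 lower) and is exposed as an option rather than buried.

At each grid value the true/false positive rates are computed, points
are sorted by FPR keeping the maximal TPR at ties, $(0,0)$ is prepended,
and the **partial AUC** is the trapezoidal area over the FPR range the
path actually attains, with no extrapolation. With the zero-endpoint
anchor the attained range ends at $(1,1)$; methods are still rewarded
only for the ordering quality of their paths.

## Reproduction fidelity and known limitations

Running `replicate_summary()` on the four in-scope scenarios (AR-1
weak/strong at $n = 500$, banded weak at $n = 500$, AR-1 weak at
$n = 1000$; 6-10 replicates) this implementation reproduces:

* the integrative model's regulator accuracy (mean PAUC ≈ 0.75 on AR-1
  weak, against 0.76 published);
* the joint-LASSO gene/G×E accuracy (≈ 0.57, against 0.54 published);
* the joint LASSO's sample-size response (≈ 0.62 at $n = 1000$, matching
  the published 0.62);
* the method ordering — the integrative model beats the joint LASSO on
  the gene/G×E family in every scenario, and both beat random selection.

It does **not** fully reproduce the published *magnitudes* of the
integrative model's gene/G×E PAUCs (we measure ≈ 0.64 on the weak AR-1
design against 0.73 published, with replicate standard deviation
≈ 0.02). The gap is a path-resolution effect we can localize precisely:
the residual-expression blocks enter the path at penalties between the
grid's smallest positive value and zero, a region the equally spaced
grid cannot resolve. Two alternative readings recover the published
integrative values — a log-spaced grid of the same range and size
(measured 0.72-0.82), or unit-normalizing the generating loading columns
and fitting on raw scales (measured 0.77, with regulator accuracy 0.84)
— but each simultaneously inflates the joint-LASSO baseline to
0.75-0.94 (published: 0.54) and reverses the published method ordering:
any setting that resolves the weak-signal tail for the integrative path
also resolves it for an exact LASSO path, whose late entries order
nearly perfectly. No single consistent reading reproduces every printed
number with shared grids and exact solvers. We ship the configuration
that preserves the published relative structure (the ordering claim in
every scenario) and matches the baseline and regulator values; the
`spacing = "log"` grid and `normalize_loadings` generator flag document
the alternatives. The same resolution limit caps the measured
sample-size effect below the published $n = 1000$ magnitude (0.89) and
blunts the seed-paired improvement, although the baseline's published
$n = 1000$ value (0.62) reproduces exactly (measured 0.623).

Other limitations: the empirical-covariance scenarios from the tumor
cohorts and censored (survival) outcomes are out of scope; the
collaborative-regression comparator is not implemented (defined in its
own literature, not in the sources this package is built from); and
cross-validated penalty selection refits Stage 1 inside each training
fold by default (`refit_stage1 = FALSE` reproduces the cheaper reading,
since the published analysis does not say which was used).

## Problem sizes used by the test suite

The acceptance-style tests run the four scenarios at full design size
($p_g = p_r = 200$, $q = 4$, $n \in \{500, 1000\}$) with 10 replicates
each — one replicate takes roughly 20-45 s here thanks to the Gram-based
solver — while unit and property tests use reduced designs (tens of
features, $n \le 400$) chosen so each one exercises the documented
contract rather than Monte-Carlo power.
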