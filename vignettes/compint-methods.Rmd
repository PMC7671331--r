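---
title: "Methods: joint latent-variable modelling of compositional omics views"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint latent-variable modelling of compositional omics views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compint)
```

## The model

`compint` integrates several omics matrices ("views") measured on the same
samples through a set of view-specific mean models that share one matrix of
latent sample scores `Z` (n × M).  Each view keeps its own link function
and variance model, so heterogeneous data types contribute on their own
terms rather than being concatenated or pre-transformed.

**Compositional count views.**  Sequence count data only carry relative
information: the total count of a sample reflects the sequencing run, not
the biology.  We therefore model each sample's *composition* through the
centered log-ratio (clr) link.  With per-feature offsets `u_x` (the clr of
the baseline composition), optional confounder terms, loading rows
`Γ` and sequencing depths `s_i` (row totals over observed cells, held
fixed as ancillary statistics):

$$E(X_{ij} \mid Z_i) = \left[\mathrm{clr}^{-1}(u_x + R_i\Phi + Z_i^\top
\Gamma)\right]_j s_i.$$

The inverse clr is the softmax, so each fitted row is a composition scaled
by the sample's depth; no zero imputation is needed anywhere in the model
(a 0.5 pseudocount appears only in the optimizer's starting values).
Equivalently, each dimension *perturbs* the lower-dimensional composition
in the Aitchison sense with direction `clr^{-1}(Γ_m)` and strength
`Z_im`; `composition_chain()` implements this reading and the tests assert
its exact agreement with the softmax form.

**Gaussian views** (microarray/proteome/metabolome intensities, optionally
log-transformed on load) use the identity link with feature offsets equal
to observed means.

**Identifiability restrictions.**  Score columns are centered (so scores
measure departure from the average sample, and are identified against the
offsets) and mutually orthogonal, `Z'Z = diag(ψ)`; each view's loading
rows are sum-zero (count views, since the clr scale fixes rows only up to
a constant), orthogonal and normalized in a diagonal weight metric Ω:
`Γ Ω Γ' = I`.  Loadings carry the normalization and scores carry the
scale ψ.  The weight metric defaults to the mean relative abundance under
the independence model for count views (down-weighting rare, noisy
features) and to inverse shrunken variances for gaussian views, both
normalized to sum p; it is configurable via the `weights` argument.

## Quasi-likelihood estimation and the abundance–variance trend

No parametric count distribution fits sequence data well, so count views
are estimated by quasi-likelihood: only means and variances are specified,
and parameters solve

$$\sum_{\text{observed } (i,j)} \frac{\partial E(X_{ij})}{\partial\kappa}
\frac{X_{ij}-E(X_{ij})}{V[E(X_{ij})]} = 0.$$

The variance model separates depth from composition:
`Var(X_ij) = v_m(π_ij) · s_i`, where `v_m` maps a feature's *modelled*
relative abundance to its per-depth-unit variance.  `v_m` is estimated
nonparametrically per dimension: feature-wise weighted variances
(squared residuals over `s_i`, averaged with denominator `n_j − 1` over
observed cells) are regressed on log independence-model abundance with a
cubic smoothing spline (smoothness by GCV), then restricted by the Poisson
heuristic — the prediction is floored at `v(π) = π` everywhere, equals the
Poisson line exactly below the 10th abundance percentile, and blends
geometrically into the spline between the 10th and 20th percentiles.  The
blend keeps `v` continuous; a discontinuous variance model leaves the
estimating equations without a stable root, which we observed as
non-decaying oscillations of the optimizer.  Because residuals change as
dimensions are added, the trend is re-estimated on the first few passes of
each dimension (at most `max_trend_iter = 5`, or until it changes by less
than 1%) and then frozen so the parameters can converge against a fixed
objective.  Gaussian feature variances are re-estimated per dimension from
residual variances (df = observed cells − 1 − fitted terms) and shrunken
towards a common value by the standard empirical-Bayes squeeze; the prior
is moment-matched via `limma::fitFDist`, and the posterior formula is
exposed in `shrink_variances()` so known priors can be plugged in.

## The fitting algorithm

Dimensions are fitted sequentially — dimension m is estimated with
dimensions 1..m−1 frozen — so lower dimensions do not depend on how many
are requested (asserted to 1e-8 in the tests).  Within a dimension the
blocks alternate: one damped Newton step for the scores (or the gradient
in constrained mode) on the equations stacked across views, then one
restricted Gauss–Newton step per view for the loading row, then exact
re-imposition of the restrictions, then (early passes) variance-model
re-estimation.  Three numerical choices matter:

* **Restricted (KKT) steps.**  Each block's Newton step is solved jointly
  with the linearized restrictions, `[J C; C' 0][δ; μ] = [score; 0]`,
  rather than stepping freely and projecting afterwards.  Unconstrained
  steps fight the normalization — every view pulls the shared scale
  towards its own preferred amplitude and the projection undoes it each
  pass, a limit cycle we observed directly.  With tangent-space steps the
  re-imposed restrictions are second-order retractions and the alternation
  settles.  At a solution the KKT step is zero exactly when the raw score
  is a linear combination of restriction gradients, i.e. when the
  *identified* model's estimating equations are solved; `quasi_score()`
  therefore reports this information-standardized restricted score, and
  the convergence table asserts it below `100 × tol`.
* **Backtracking.**  The Fisher information used in the steps ignores the
  dependence of the variance weights on the parameters (through the trend),
  so raw steps can overshoot; each block halves its step until the
  projected score norm stops increasing.
* **Adaptive relaxation.**  The two-block alternation can acquire an
  eigenvalue near −1 (period-2 cycling) or near +1 (slow contraction).  We
  track the direction cosine of consecutive combined steps and shrink the
  step fraction under oscillation (×0.6, floor 0.1) or restore it under
  steady progress (×1.25, cap 1).

Starting values are deterministic: the leading singular-vector pair of the
working residuals (clr of pseudocounted proportions minus the current
linear predictor for count views; plain residuals for gaussian views),
stacked across views after scaling each view to unit mean square.  The
whole fit is therefore reproducible without a seed.  Convergence is
declared when the largest absolute parameter change in an outer pass drops
below `tol` (default 1e-6, default `max_iter` 1000); a dimension whose
score scale ψ collapses (below n·1e-12, or 1e-10 relative to earlier
dimensions) is reported as degenerate and the fit returns fewer
dimensions.  After each dimension the sign is fixed by making the largest
loading of the first view positive.

## Sample-specific variables

Confounder effects (`confounders =`) are estimated per view under the
independence model — cyclic restricted Gauss–Newton over design columns
for count views, per-feature least squares (pseudoinverse, since
no-reference dummy blocks are rank-deficient by construction) for gaussian
views — and then frozen, so the latent variables are estimated
conditionally on them.  A constrained fit (`constrain =`) replaces free
scores by `Z = cΛ`: categorical variables expand to one indicator column
per level with *no* reference level, continuous columns are centered and
scaled to unit standard deviation, gradient columns are orthonormal, and
the entries of each categorical block sum to zero, which removes the
dummy-coding redundancy symmetrically.  Because `Λ'Λ = I` together with
`ΓΩΓ' = I` would pin the model's amplitude entirely, constrained fits
keep the gradient orthonormal and let the loading rows carry the scale
(they stay sum-zero and mutually Ω-orthogonal but are not normalized);
consequently `Z'Z` is not diagonal in constrained mode — the gradient
restriction replaces the score restriction.  Requesting more dimensions
than the restricted gradient space supports returns the fittable number
with a warning.

## Missing data and influence

Missing cells are excluded from every estimating-equation sum (valid under
missing-at-random); a sample absent from one view is all-missing there and
still contributes through the other views.  The explicit equations also
yield influence diagnostics: the influence of cell (i, j) on `Z_im` is its
estimating-function contribution divided by the per-sample information,
a one-step leave-one-out approximation (`influence_scores()`;
`influence_by_view()` totals absolute influences per view, revealing which
dataset drives the estimation).  The information is computed analytically
for gaussian views and by central finite differences (relative step 1e-6)
for count views, where hand-derived softmax Jacobians are error-prone; the
tests check the two routes against each other and verify the one-step
prediction against an actual deletion-refit (relative error below 25% on a
gaussian fixture).

## The simulator and what it does (not) emulate

`simulate_views()` reproduces a two-group parametric benchmark: per-view
feature parameters are drawn from configurable parametric pools
(log-normal baseline abundances with `sdlog = 2`, giving the heavy-tailed
rank-abundance profile of real microbiomes; gamma NB dispersions with mean
0.5, which place the high-abundance variance well above the Poisson line;
log-normal depths around 2·10⁴), counts are negative binomial and
intensities gaussian, and 10% of features receive a fold change in group
2 — 4-fold for counts, ×1.1 for gaussian views (a "0.1 fold change" read
as a relative mean shift; configurable).  With `compensation = TRUE` roughly
1/(fc+1) of the DA mass (taken from the smallest DA features) goes up
fc-fold and the remaining DA features are scaled down by the common factor
that exactly preserves total expected abundance, so non-DA relative
abundances are identical between groups; without compensation all DA
features go up and renormalization drags every other relative abundance
down.  `permute_views()` implements the matched null: each view's rows are
independently permuted, preserving all within-view structure while
destroying cross-view alignment.  The pools are parametric stand-ins — the
generator does not emulate phylogenetic correlation among features,
longitudinal designs, or zero-inflation beyond what the NB produces — so
passing tests demonstrate correctness of the method under its own
assumptions, not performance on any particular real dataset.

## Evaluation statistics

`score_sum_correlation()` correlates score columns with per-view and
overall sample sums (missing cells as zero) — near-zero values on count
data mean depth does not drive the ordination.  `pseudo_f()` quantifies
group separation as the Calinski–Harabasz ratio
`(SSB/(k−1))/(SSW/(n−k))` on Euclidean distances in score space, with a
distance-based (PERMANOVA-style) variant that coincides for Euclidean
distances; degenerate perfect separation returns `Inf`.
`wilcoxon_inner_product()` ranks all pairwise loading inner products
(within and between views, or between only) and standardizes the rank sum
of the truly correlated pairs — both features differentially abundant in
the same direction — using the null moments with midranks:
`z = (W − n₁(n₁+n₂+1)/2) / \sqrt{n₁n₂(n₁+n₂+1)/12}`.

## Multiplots

`multiplot_coordinates()`/`plot()` place samples at score pairs, feature
labels at loading pairs, and gradient labels at Λ rows.  Thresholding
(default: top 15 loading norms per view, ties at the cutoff all retained)
affects display only — loadings are never altered.  Axes are forced square
so inter-sample distances are faithful, and no variance-explained
percentages are shown: such fractions are not well defined across
heterogeneous noise levels, and the spread of scores along each axis is
itself the importance measure.  For compositional views, single labels
should not be read alone; `feature_link_projection()` returns
`Z_i'(γ_a − γ_b)`, the sample's log-ratio change for the pair relative to
the independence model — the quantity a reader extracts geometrically by
projecting a sample dot onto the link between two feature labels — and
the tests assert its exact agreement with the fitted mean model.
Coordinates export to TSV at full precision (`write_multiplot()`), so
plots are reproducible without the plotting layer.

## Problem sizes used in tests

The test-suite and acceptance script run at the benchmark's sample size
(n = 40, two groups of 20) with 200–1000 features per view, 20 seeded
replicates for recovery and permutation properties, p = 500 features and
n = 100 samples for trend recovery, and small dedicated fixtures
(n = 15–30) for algebraic and influence checks.  These sizes give stable
statistics while keeping a full run to a few minutes on one CPU.

## Known limitations

* Score dimensions beyond the true signal rank are estimation noise; their
  per-sample magnitude scales like `1/√depth`, so *their* sample-sum
  correlations fluctuate (with random sign) from run to run.  The
  depth-insensitivity guarantee concerns signal-carrying dimensions and
  the permuted-null setting.
* The per-dimension variance trend assumes `Var = v(π)·s` exactly.  Under
  strong NB overdispersion a sample whose depth is far from the rest has a
  per-depth-unit variance the pooled trend cannot represent
  (`π + φπ²s` depends on s), which re-weights that sample's cells.
* Confounder coefficients are conditioned on and frozen before latent
  estimation; they are not re-estimated jointly.
* No standard errors or formal inference are produced; the package is an
  exploration and visualization tool.  Automatic choice of M, sparsity
  penalties, and non-MAR missingness are out of scope.
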