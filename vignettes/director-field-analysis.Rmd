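---
title: "Director field analysis of diffusion tensor images: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Director field analysis of diffusion tensor images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfatools)
```

# The problem

Conventional voxelwise DTI metrics — fractional anisotropy (FA) and mean
diffusivity (MD) — summarize water diffusion *within* one voxel. They say
nothing about how the dominant fiber orientation *changes between*
neighbouring voxels. Director field analysis (DFA) fills that gap: it treats
the principal eigenvector of the diffusion tensor at each voxel as a
*director* — an axis defined only up to sign, as in nematic liquid crystals
— and quantifies the elementary ways a director field can be spatially
distorted:

* **splay** — fibers fan out perpendicular to their own axis,
* **bend** — the fiber direction changes along the fiber,
* **twist** — neighbouring fibers rotate about the fiber axis,

plus their root-sum-square, the **total distortion**. `dfatools` implements
this geometric analysis end to end: tensor fitting, index computation,
permutation-based group statistics, clinical-score association, and a
cross-validated ROI-feature classification harness, together with synthetic
generators that create every input with known ground truth.

# The distortion model

Let $n(x)$ be the unit director field and $J = \nabla n$ its spatial
Jacobian, $J_{ij} = \partial n_i / \partial x_j$ (units 1/mm). The package
computes the classical Frank (liquid-crystal) scalar modes

$$s = |\nabla\!\cdot n| = |\mathrm{tr}\,J|, \qquad
  b = \lVert (n\!\cdot\!\nabla)\,n \rVert = \lVert J n \rVert, \qquad
  t = |n \cdot (\nabla\!\times n)|,$$

and the total distortion $d = \sqrt{s^2 + b^2 + t^2}$. These forms were
chosen because they

1. match the verbal definitions of the three modes (fanning perpendicular
   to the axis; curvature along the axis; rotation of neighbours about the
   axis),
2. reproduce the canonical synthetic-field selectivity claims analytically
   (each circular/twist phantom activates exactly one index; see below), and
3. are free of any transverse-frame choice: completing $n$ into a local
   frame $\{n, u_2, u_3\}$ leaves a rotational gauge ambiguity in
   $u_2, u_3$, and the Frank scalars are invariant to it. A frame-component
   variant ($\sqrt{a_{22}^2+a_{33}^2}$, $\sqrt{b_2^2+b_3^2}$,
   $\sqrt{a_{23}^2+a_{32}^2}$ with $a_{\alpha\beta} = u_\alpha^\top J
   u_\beta$) is available via `distortionIndices(..., variant = "frame")`
   for comparison with frame-based implementations.

**Sign gauge.** Directors are axes: $n$ and $-n$ are the same object.
Before differencing, every neighbour vector $v$ is re-signed so that
$v \cdot n(\text{center}) \ge 0$. All four maps are therefore invariant
under arbitrary voxelwise sign flips of the stored eigenvectors (tested to
$10^{-12}$).

**Discretization.** Derivatives are 2nd-order central differences in mm
units, falling back to 1st-order one-sided differences at mask edges;
voxels that needed a one-sided difference are flagged as boundary-affected
and excluded from the `interior` mask that all summaries use. Voxels with
no valid neighbour along some axis carry no derivative at all. The
per-voxel spacing-free mode (`perVoxel = TRUE`, rad/voxel) exists because
published DFA maps do not always state their units; the default is rad/mm.

**What is exact and what is $O(h^2)$.** On the twist phantom the discrete
scheme is *exact*: splay and bend vanish identically, and the twist map is
constant to machine precision, with value $\sin(\theta')/h$ for a rotation
rate $\theta'$ rad/voxel and spacing $h$ (the chord of the rotation; it
differs from the analytic $\theta'/h$ by a relative $\theta'^2/6$, about
0.17% at $\theta' = 0.1$). On the circular splay/bend phantoms the
*twist* map is exactly zero (the field is planar), but the bend-on-splay
and splay-on-bend cross terms retain a genuine $O(h^2)$ truncation residual
concentrated near the singular center, decaying like $(h/r)^2$ with radius.
This is intrinsic: a finite neighbourhood of a radial field is numerically
indistinguishable from a slightly bent field, so no consistent local
estimator can return exactly zero there. The tests assert the exact zeros
at $10^{-12}$ and the $O(h^2)$ decay of the cross terms under grid
refinement, rather than pretending the residual is zero.

**Degenerate directors.** Voxels with FA below `faMin` (default 0.2, the
usual white-matter skeleton threshold) or with a near-degenerate leading
eigenvalue pair ($\lambda_1-\lambda_2 < 10^{-6}\lambda_1$) have no
meaningful principal direction and are masked, not arbitrarily oriented.

# Tensor fitting

`fitTensors` solves the log-linear model
$\ln S_i = \ln S_0 - b_i\, g_i^\top D\, g_i$ by weighted least squares
(weights = squared fitted signal, one refinement pass after an OLS start;
`method = "ols"` is available). The estimator is exact on noiseless data —
the round-trip phantom test demands relative error below $10^{-8}$ and
observes $\sim 10^{-14}$ — and is the standard fast choice under noise.
Voxels with any non-positive in-mask signal are *excluded* from the output
mask (with a reported count) rather than clamped, because $\ln$ of a
clamped value would bias the whole voxel fit. Negative fitted eigenvalues
(possible under noise) are clamped to zero for FA/MD only, which guarantees
$FA \in [0,1]$ and $MD \ge 0$; the raw tensor is kept for direction
extraction. At a noise level of $\sigma/S_0 = 1/40$ the median FA bias on a
uniform phantom is small but nonzero (order 0.01–0.03); this is a property
of magnitude-MRI noise, documented here rather than asserted tightly.
b-values below 50 s/mm² count as $b=0$ (vendor rounding tolerance);
gradient vectors within $10^{-3}$ of unit norm are renormalized.

# Synthetic data: what it emulates, what it does not

`makePatternField` builds the three canonical phantoms (plus a uniform
control) as planar constructions replicated along the third axis, default
grid $21\times21\times5$ at 2 mm isotropic — matching the planar published
illustrations of the three modes. The singular central voxel of the
splay/bend patterns is kept in the grid but flagged, and all index
summaries exclude it. `directorsToTensors` realizes a field as axially
symmetric tensors $D = \lambda_\perp I + (\lambda_\parallel -
\lambda_\perp) n n^\top$; the defaults $\lambda_\parallel = 1.7\times
10^{-3}$, $\lambda_\perp = 0.3\times 10^{-3}$ mm²/s (FA ≈ 0.80) are typical
healthy white-matter values, chosen because the source illustrations do not
state theirs. `simulateDWI` applies the single-shell protocol (64
deterministic Fibonacci-hemisphere directions at $b = 1000$ s/mm², 8
$b=0$ volumes, 2 mm voxels) and Rician noise via the two-channel Gaussian
construction $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$; one seeded generator
drives each call, so a seed fully determines the output.

`makeAtlasLabels` tiles the grid into 48 rectangular regions carrying the
standard white-matter tract name list; only the cardinality and names of
the real atlas are mirrored, never its geometry. `makeCohort` draws ROI
features as group mean shift (in within-group SD units) plus unit Gaussian
noise, ages and sexes from per-group models that default to the
demographics of a facial-movement-disorder case-control study (patient
groups FP/HFS/MS and healthy controls), and clinical scores through a
Gaussian copula against the normal scores of a tracked feature followed by
a strictly monotone affine transform — Spearman targets are invariant to
any monotone transform, and the copula correlation $2\sin(\pi\rho/6)$ makes
the population Spearman association equal the target.

Synthetic cohorts deliberately omit several properties of real data:
features are spatially and mutually independent given the group (real ROI
metrics are strongly correlated), there is no registration error, no
atlas-geometry realism, no site or scanner effects, and noise is Gaussian
at the feature level. Passing calibration tests on these cohorts therefore
validates the *statistical machinery* (error control, calibration,
ranking behaviour), not performance on real MRI data.

# Group statistics

`permutationFWE` implements Freedman–Lane residual permutation: nuisance
effects (design columns given zero weight by the contrast — here age and
sex) are fitted and removed, residuals are row-permuted, the nuisance fit
is added back, and the full model is refit per permutation. Family-wise
error is controlled by the permutation distribution of the spatial maximum
of the statistic, optionally TFCE-enhanced
($\sum_h e(v,h)^{E} h^{H}\,\mathrm{d}h$ with the conventional $E = 0.5$,
$H = 2$, step $h_{max}/100$ by default, 26-connectivity; the negative tail
is enhanced by sign-split). Corrected p-values use the
$(1+\#\{\cdot\})/(n_{perm}+1)$ estimator, so $p \ge 1/(n_{perm}+1)$ and
zero p-values cannot occur; when fewer distinct permutations exist than
requested, all of them are enumerated with a warning and the p-value is the
exact proportion. Inference is one-sided in the contrast direction (negate
the contrast for the other tail); multi-row contrasts give an F statistic
for multi-group tests. Cluster reporting keeps 26-connected components of
the corrected $p < \alpha$ set with voxel count strictly greater than 50
(configurable) and annotates each with its peak statistic and the atlas
region of maximal overlap. Registration and skeleton projection are
deliberately out of scope: analysis runs within whatever mask it is given,
with the synthetic atlas mask standing in for a skeleton.

Null-cohort simulation (two groups of 15, age/sex nuisance, 1000
permutations, 500 replicates) puts the familywise type-I error within the
95% binomial interval of the nominal 0.05; the test suite runs this on
$4\times4\times2$ grids to keep the full suite within minutes — validity of
the max-statistic argument does not depend on grid size.

# Clinical associations

`spearmanTest` uses midranks for ties, an exact two-sided permutation null
(full enumeration) for $n \le 9$, and the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above. Constant inputs leave the
correlation undefined and are flagged `NA` — never reported as $\rho = 0$.
`associationTable` drops subjects with missing scores pairwise, records the
remaining $n$, and applies Benjamini–Hochberg FDR *within each clinical
score's family* of feature tests — the most conservative reading consistent
with per-score reporting; `familyBy = "all"` pools everything instead, and
the choice is recorded in the output structure by construction (one family
per score column).

# Classification harness

`assembleFeatures` builds the three ROI-feature sets (per-ROI FA+MD,
per-ROI four DFA indices, or all six; 96/192/288 features with the
48-region atlas), in deterministic ROI-major column order.
Cross-validation is stratified (the source procedure says "randomly
split"; stratification guarantees both classes in every fold at these
sample sizes — a non-issue for large cohorts, essential for groups of
~30), with seeded, bit-reproducible folds. The automated-ML stacking
framework of the source pipeline is replaced by a fixed, documented
ensemble — L2-regularized multinomial logistic regression, a 100-tree
random forest, and an RBF-kernel SVM with probability calibration —
averaged with equal weights; the roster mirrors the standalone baselines
the source compares against, and a fixed ensemble keeps the harness
reproducible. Feature standardization is fit on training folds only
(a test asserts that a test-only outlier cannot perturb other predictions).

"Average TPR and FPR across folds" is ambiguous; both readings are
implemented. The default interpolates each fold's empirical ROC onto a
fixed 101-point FPR grid and averages vertically; because the empirical ROC
is a right-continuous step function, the interpolation is *constant* from
the upper corner of each vertical segment — linear interpolation between
step corners would systematically inflate the averaged curve (we measured
null AUC ≈ 0.65 with linear ramps versus ≈ 0.5 with the step-faithful
scheme at 8-subject folds). The alternative (`method = "threshold"`)
averages (FPR, TPR) pairs over a common probability-threshold grid.
Label-permuted cohorts give mean fold-averaged AUC within 0.5 ± 0.1 over
100 seeds; fully separable cohorts give exactly 1; cohorts whose group
differences live only in the DFA metrics rank AUC(DFA) > AUC(FA+MD) in
effectively every replicate, and the mirrored construction reverses the
ranking — the qualitative pattern that motivates carrying geometric
features alongside FA/MD.

# Problem sizes in the shipped tests

The test suite exercises every claim at sizes chosen to keep the whole run
in a few minutes on one core while leaving the statistical assertions
well-powered: phantom grids 21×21×5 (protocol-scale fit exactness),
permutation calibration at 500 replicates × 1000 permutations on
$4\times4\times2$ grids, FDR calibration at 500 replicates, classification
calibration at 100 seeds with 6-ROI cohorts of paper-scale group sizes
(50 + 33). None of these sizes is load-bearing for the properties tested.

# Known limitations

* Single-tensor model only: voxels with crossing fibers have an ill-defined
  director, and no multi-tensor or ODF generalization is attempted.
* The DFA cross-index $O(h^2)$ residual near orientation singularities
  (fan/vortex centers) means off-target indices are small but not zero
  there on real grids.
* No preprocessing: denoising, brain extraction, eddy/motion correction,
  registration and skeletonization are upstream of this package.
* The permutation engine assumes exchangeable subjects under the reduced
  model; it does not handle repeated measures or exchangeability blocks.
* Synthetic cohorts are feature-independent given group labels; real ROI
  features are correlated, so real-data classifier AUCs are not predicted
  by phantom AUCs.
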