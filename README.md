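# dfatools

Geometric white-matter microstructure analysis from diffusion tensor
imaging (DTI), for neuroimaging researchers who want to look *between*
voxels as well as within them.

Classical DTI metrics — fractional anisotropy (FA) and mean diffusivity
(MD) — describe diffusion inside a single voxel. Director field analysis
(DFA) treats the principal eigenvector of each voxel's diffusion tensor as
a *director* (an axis defined up to sign, as in nematic liquid crystals)
and measures how the resulting axis field is distorted across neighbouring
voxels. With `n(x)` the unit director field and `J = ∇n` its spatial
Jacobian, the package computes the three elementary distortion modes and
their composition:

    splay   s = |∇·n|  = |tr J|          fibers fan out
    bend    b = ‖(n·∇)n‖ = ‖J n‖         direction changes along the fiber
    twist   t = |n·(∇×n)|                neighbours rotate about the axis
    total   d = sqrt(s² + b² + t²)

in rad/mm, sign-gauge invariant and free of any transverse-frame choice.
Around the indices sits a complete, tested pipeline:

* **dti**: gradient tables (FSL bval/bvec dialect), weighted log-linear
  tensor fitting (exact on noiseless data), FA/MD maps, the affected-side
  left-right flip convention;
* **dfa**: director extraction (FA ≥ 0.2, degeneracy masking), the four
  distortion maps with boundary flagging;
* **group statistics**: voxelwise GLM with age/sex nuisance covariates,
  Freedman-Lane permutation testing with max-statistic FWE control and
  optional TFCE, cluster reporting with the "> 50 voxels" rule;
* **clinical associations**: Spearman correlation (exact small-sample p)
  with Benjamini-Hochberg FDR per score family;
* **classification**: ROI feature sets (per-ROI FA+MD, DFA, or both:
  96/192/288 features with the 48-region atlas), stratified 10-fold
  cross-validation of a logistic + random-forest + RBF-SVM probability
  ensemble, fold-averaged ROC/AUC, multiclass confusion matrices;
* **synthetic data**: canonical splay/bend/twist phantoms, DWI simulation
  (64 directions at b = 1000 s/mm², 8 b = 0, 2 mm voxels, Rician noise), a
  48-region stand-in atlas with the standard tract name list, and
  multi-group cohorts with prescribed effect sizes, covariates, and
  clinical scores hitting exact Spearman targets via a Gaussian copula.

Everything is S4 with validity checking (`TensorField`, `DirectorField`,
`DistortionMaps`, `CohortTable`, `StatMap`, ...), NIfTI-1 in and out via
RNifti, and a thin command-line front end in `inst/cli/dfa.R`
(`simulate`, `fit`, `dfa`, `stats`, `assoc`, `classify`).

## Worked example

Simulate a twisted-fiber phantom, fit tensors from its noisy diffusion
signal, and recover the distortion geometry:

```r
library(dfatools)

field   <- makePatternField("twist", gridShape = c(21, 21, 5), twistRate = 0.1)
tensors <- directorsToTensors(field, lambdaParallel = 1.7e-3, lambdaPerp = 0.3e-3)
dwi     <- simulateDWI(tensors, s0 = 1000, noiseSigma = 25, seed = 1)
fit     <- fitTensors(dwi)
scalarMaps(tensorEigensystem(fit$tensors))$FA
#> ScalarMap (FA): 21 x 21 x 5 grid
#>   in-mask range: [0.7628, 0.8311], mean 0.7988

distortionIndices(extractDirectors(fit$tensors, faMin = 0.2))
#> DistortionMaps (rad/mm): 21 x 21 x 5 grid, 2205 defined / 1083 interior voxels
#>   splay  mean 0.003916  max 0.01503
#>   bend   mean 0.004341  max 0.01306
#>   twist  mean 0.04998  max 0.06636
#>   total  mean 0.05046  max 0.06714
```

The phantom twists at 0.1 rad per 2 mm voxel, so the true twist index is
0.05 rad/mm: the fitted map recovers it (mean 0.04998) while splay and bend
stay an order of magnitude lower, driven only by noise. FA concentrates
around the ground-truth 0.799 of the simulated tensors.

Downstream, a synthetic case-control cohort whose group differences live
only in the geometric indices is cleanly separated by DFA features but not
by FA+MD — and a clinical score tracking one ROI shows up as the top
association:

```r
eff <- expand.grid(group = "FP", roi = c(3, 4, 25, 26),
                   metric = c("splay", "bend", "twist", "total_distortion"),
                   stringsAsFactors = FALSE)
eff$delta <- 0.8
co <- makeCohort(groups = c(HC = 33, FP = 50), nRois = 48, effects = eff,
                 clinicalTargets = list(TFGS = list(roi = 3,
                   metric = "total_distortion", rho = 0.6, groups = "FP",
                   mean = 18.6, sd = 17.2)),
                 seed = 42)

foldAveragedRoc(crossValidate(assembleFeatures(co, "DFA"),   k = 10, seed = 42), "FP")$auc
#> [1] 0.9071429
foldAveragedRoc(crossValidate(assembleFeatures(co, "FA_MD"), k = 10, seed = 42), "FP")$auc
#> [1] 0.4971429

tab <- associationTable(co, metrics = "total_distortion", scores = "TFGS")
head(tab[order(tab$p), c("roi", "rho", "p", "q", "n")], 2)
#>      roi   rho       p     q  n
#> 3    GCC 0.402 0.00379 0.182 50
#> 26 SCR_L 0.298 0.03528 0.614 50
```

The tracked region (GCC) tops the table at raw p = 0.004; after FDR
correction across all 48 regions the q-value (0.18) is not significant at
n = 50 — a realistic reminder of what per-family multiple-testing control
costs at these sample sizes.

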