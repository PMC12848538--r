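#' @import methods
NULL

#' Gradient table for a diffusion-weighted acquisition
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions. Directions are
#' stored in image coordinates (FSL dialect: three rows, one column per
#' volume). Volumes with b below `b0Threshold` are treated as b=0 and may
#' carry a zero vector.
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs 3 x n numeric matrix of gradient directions.
#' @slot b0Threshold b-values below this (s/mm^2) count as b=0.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix", b0Threshold = "numeric"),
  prototype(b0Threshold = 50)
)

setValidity("GradientTable", function(object) {
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L)
    return("bvecs must be a 3 x n numeric matrix")
  if (length(object@bvals) != ncol(object@bvecs))
    return(sprintf("length mismatch: %d b-values vs %d b-vectors",
                   length(object@bvals), ncol(object@bvecs)))
  if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
    return("b-values must be finite and non-negative")
  dw <- object@bvals >= object@b0Threshold
  if (any(dw)) {
    nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
    if (any(nrm == 0))
      return("zero gradient vector on a diffusion-weighted volume")
    if (any(abs(nrm - 1) > 1e-6))
      return("diffusion-weighted gradient vectors must have unit norm (1e-6)")
  }
  TRUE
})

#' 4D diffusion-weighted volume
#'
#' @slot data 4D array (x, y, z, volume) of signal values.
#' @slot gtab [GradientTable-class] matching the 4th dimension.
#' @slot mask 3D logical analysis mask.
#' @slot spacing voxel size in mm per axis.
#' @slot axes three-letter orientation code (e.g. "RAS"); the letter on an
#'   axis tells which anatomical direction increases along it.
#' @slot meta free-form metadata list (records e.g. lateral-flip state).
#' @export
setClass("DWIVolume",
  representation(data = "array", gtab = "GradientTable", mask = "array",
                 spacing = "numeric", axes = "character", meta = "list"),
  prototype(axes = "RAS", meta = list())
)

setValidity("DWIVolume", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be a 4D array")
  if (dim(object@data)[4] != length(object@gtab@bvals))
    return("4th dimension must equal the gradient-table length")
  if (!identical(dim(object@mask), dim(object@data)[1:3]))
    return("mask dimensions must match the spatial grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive voxel sizes (mm)")
  TRUE
})

#' Voxelwise symmetric diffusion tensor field
#'
#' Tensors are stored as six unique components per voxel in the order
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), units mm^2/s.
#'
#' @slot values 4D array (x, y, z, 6).
#' @slot mask 3D logical validity mask.
#' @slot spacing voxel size in mm per axis.
#' @export
setClass("TensorField",
  representation(values = "array", mask = "array", spacing = "numeric")
)

setValidity("TensorField", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || d[4] != 6L)
    return("values must be a 4D array with 6 tensor components")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask dimensions must match the spatial grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive voxel sizes (mm)")
  v <- matrix(object@values, ncol = 6L)[as.logical(object@mask), , drop = FALSE]
  if (length(v) && any(!is.finite(v)))
    return("in-mask tensors must be finite")
  TRUE
})

#' Director (principal-direction) field
#'
#' A field of axes: unit 3-vectors defined only up to sign. All quantities
#' computed from a DirectorField must be invariant under voxelwise sign
#' flips n -> -n.
#'
#' @slot vectors 4D array (x, y, z, 3) of unit directors.
#' @slot mask 3D logical validity mask.
#' @slot spacing voxel size in mm per axis.
#' @export
setClass("DirectorField",
  representation(vectors = "array", mask = "array", spacing = "numeric")
)

setValidity("DirectorField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4D array with 3 components")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask dimensions must match the spatial grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive voxel sizes (mm)")
  v <- matrix(object@vectors, ncol = 3L)[as.logical(object@mask), , drop = FALSE]
  if (length(v)) {
    nrm <- sqrt(rowSums(v^2))
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-9))
      return("in-mask directors must have unit norm")
  }
  TRUE
})

#' Voxelwise eigensystem of a tensor field
#'
#' @slot values 4D array (x, y, z, 3) of eigenvalues, descending.
#' @slot vectors 5D array (x, y, z, component, eigenindex), orthonormal.
#' @slot mask 3D logical validity mask.
#' @slot spacing voxel size in mm per axis.
#' @export
setClass("TensorEigensystem",
  representation(values = "array", vectors = "array", mask = "array",
                 spacing = "numeric")
)

#' Scalar metric map
#'
#' @slot values 3D array of metric values.
#' @slot metric metric name, e.g. "FA", "MD", "splay".
#' @slot mask 3D logical validity mask.
#' @slot spacing voxel size in mm per axis.
#' @slot axes three-letter orientation code.
#' @slot meta free-form metadata list.
#' @export
setClass("ScalarMap",
  representation(values = "array", metric = "character", mask = "array",
                 spacing = "numeric", axes = "character", meta = "list"),
  prototype(axes = "RAS", meta = list())
)

setValidity("ScalarMap", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (!identical(dim(object@mask), dim(object@values)))
    return("mask dimensions must match the value grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive voxel sizes (mm)")
  if (length(object@metric) != 1L) return("metric must be a single name")
  TRUE
})

#' Orientational distortion maps
#'
#' Splay, bend, twist and total distortion of a director field, in rad/mm
#' (or rad/voxel when computed spacing-free). `defined` marks voxels where
#' the spatial derivative exists; `interior` additionally excludes voxels
#' that needed one-sided (boundary) differences and flagged singularities.
#'
#' @slot splay,bend,twist,total 3D arrays of index values.
#' @slot defined 3D logical, derivative defined.
#' @slot interior 3D logical, defined and free of boundary effects.
#' @slot spacing voxel size in mm per axis.
#' @slot units "rad/mm" or "rad/voxel".
#' @export
setClass("DistortionMaps",
  representation(splay = "array", bend = "array", twist = "array",
                 total = "array", defined = "array", interior = "array",
                 spacing = "numeric", units = "character"),
  prototype(units = "rad/mm")
)

setValidity("DistortionMaps", function(object) {
  d <- dim(object@splay)
  for (nm in c("bend", "twist", "total", "defined", "interior"))
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("'%s' grid does not match 'splay'", nm))
  ok <- as.logical(object@defined)
  for (nm in c("splay", "bend", "twist", "total")) {
    v <- slot(object, nm)[ok]
    if (length(v) && any(v < -1e-12, na.rm = TRUE))
      return(sprintf("'%s' must be non-negative where defined", nm))
  }
  TRUE
})

#' Subjects-by-features cohort with labels, covariates and clinical scores
#'
#' @slot subjects data.frame with subject_id, group, age, sex (0/1).
#' @slot features numeric matrix, one column per (ROI, metric) pair,
#'   ROI-major column order, named "<roi>.<metric>".
#' @slot scores numeric matrix of clinical scores (may have NAs).
#' @slot roiNames,metricNames the grid of feature names.
#' @export
setClass("CohortTable",
  representation(subjects = "data.frame", features = "matrix",
                 scores = "matrix", roiNames = "character",
                 metricNames = "character")
)

setValidity("CohortTable", function(object) {
  n <- nrow(object@subjects)
  if (!all(c("subject_id", "group", "age", "sex") %in% names(object@subjects)))
    return("subjects must have subject_id, group, age, sex")
  if (nrow(object@features) != n) return("features rows must match subjects")
  if (nrow(object@scores) != n) return("scores rows must match subjects")
  if (ncol(object@features) !=
      length(object@roiNames) * length(object@metricNames))
    return("feature count must be n_rois x n_metrics")
  TRUE
})

#' Feature matrix for classification
#'
#' @slot x numeric matrix, subjects x features.
#' @slot labels factor of group labels.
#' @slot subjectIds character subject identifiers.
#' @slot featureSet which assembly produced it ("FA_MD", "DFA", "ALL").
#' @export
setClass("FeatureMatrix",
  representation(x = "matrix", labels = "factor", subjectIds = "character",
                 featureSet = "character")
)

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@x) != length(object@labels))
    return("labels must match feature rows")
  if (nrow(object@x) != length(object@subjectIds))
    return("subjectIds must match feature rows")
  if (anyNA(object@x)) return("assembled features must not contain NAs")
  TRUE
})

#' Design for permutation GLM inference
#'
#' @slot X design matrix (subjects x predictors), including intercept and
#'   nuisance covariates.
#' @slot contrast contrast matrix, one row per contrast component; a single
#'   row gives a t statistic, several rows an F statistic.
#' @slot nPerm number of random permutations.
#' @slot alpha significance level for FWE-corrected maps.
#' @slot enhancement "none" (voxel max-statistic) or "tfce".
#' @slot tfceE,tfceH,tfceDh TFCE extent/height exponents and step.
#' @slot connectivity 6, 18 or 26.
#' @slot seed RNG seed for the permutation stream.
#' @export
setClass("StatDesign",
  representation(X = "matrix", contrast = "matrix", nPerm = "numeric",
                 alpha = "numeric", enhancement = "character",
                 tfceE = "numeric", tfceH = "numeric", tfceDh = "numeric",
                 connectivity = "numeric", seed = "numeric"),
  prototype(nPerm = 1000, alpha = 0.05, enhancement = "none",
            tfceE = 0.5, tfceH = 2, tfceDh = NA_real_, connectivity = 26,
            seed = NA_real_)
)

setValidity("StatDesign", function(object) {
  if (ncol(object@contrast) != ncol(object@X))
    return("contrast length must equal the number of predictors")
  if (object@nPerm < 1) return("nPerm must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (!object@enhancement %in% c("none", "tfce"))
    return("enhancement must be 'none' or 'tfce'")
  if (!object@connectivity %in% c(6, 18, 26))
    return("connectivity must be 6, 18 or 26")
  if (qr(object@X)$rank < ncol(object@X))
    return("design matrix is rank deficient")
  TRUE
})

#' Voxelwise statistic map with permutation FWE correction
#'
#' @slot stat 3D array of observed statistics.
#' @slot pcorr 3D array of FWE-corrected p-values.
#' @slot maxDist permutation distribution of the spatial maximum.
#' @slot mask 3D logical analysis mask.
#' @slot meta metadata list (contrast, seed, enhancement, nPerm).
#' @export
setClass("StatMap",
  representation(stat = "array", pcorr = "array", maxDist = "numeric",
                 mask = "array", meta = "list"),
  prototype(meta = list())
)

setValidity("StatMap", function(object) {
  if (!identical(dim(object@stat), dim(object@pcorr)))
    return("stat and pcorr grids must match")
  p <- object@pcorr[as.logical(object@mask)]
  p <- p[is.finite(p)]
  if (length(p) && (any(p <= 0) || any(p > 1)))
    return("corrected p-values must lie in (0, 1]")
  TRUE
})
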