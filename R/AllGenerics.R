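#' Accessors for image-like objects
#'
#' `imgData` returns the value array, `imgMask` the logical validity mask and
#' `voxelSize` the per-axis voxel spacing in mm.
#'
#' @param x an image-like object (DWIVolume, TensorField, DirectorField,
#'   ScalarMap, DistortionMaps, TensorEigensystem, StatMap).
#' @return an array, a logical array, or a numeric length-3 vector.
#' @aliases imgData imgMask voxelSize
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setGeneric("imgMask", function(x) standardGeneric("imgMask"))

#' @rdname imgData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

setMethod("imgData", "DWIVolume", function(x) x@data)
setMethod("imgData", "TensorField", function(x) x@values)
setMethod("imgData", "DirectorField", function(x) x@vectors)
setMethod("imgData", "ScalarMap", function(x) x@values)
setMethod("imgData", "TensorEigensystem", function(x) x@values)
setMethod("imgData", "StatMap", function(x) x@stat)

for (cl in c("DWIVolume", "TensorField", "DirectorField", "ScalarMap",
             "TensorEigensystem", "StatMap"))
  setMethod("imgMask", cl, function(x) array(as.logical(x@mask), dim(x@mask)))
setMethod("imgMask", "DistortionMaps",
          function(x) array(as.logical(x@defined), dim(x@defined)))

for (cl in c("DWIVolume", "TensorField", "DirectorField", "ScalarMap",
             "TensorEigensystem", "DistortionMaps"))
  setMethod("voxelSize", cl, function(x) x@spacing)
rm(cl)

#' Gradient-table accessors
#'
#' @param x a [GradientTable-class] or [DWIVolume-class].
#' @return `bValues`: numeric vector (s/mm^2); `bVectors`: 3 x n matrix;
#'   `nVolumes`: integer count.
#' @aliases bValues bVectors nVolumes
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname bValues
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname bValues
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

setMethod("bValues", "GradientTable", function(x) x@bvals)
setMethod("bValues", "DWIVolume", function(x) x@gtab@bvals)
setMethod("bVectors", "GradientTable", function(x) x@bvecs)
setMethod("bVectors", "DWIVolume", function(x) x@gtab@bvecs)
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))
setMethod("nVolumes", "DWIVolume", function(x) dim(x@data)[4])

#' Extract one distortion-index map
#'
#' @param x a [DistortionMaps-class] object.
#' @param which one of "splay", "bend", "twist", "total_distortion".
#' @param interiorOnly if `TRUE`, boundary-affected voxels are set to `NA`.
#' @return a [ScalarMap-class].
#' @export
setGeneric("distortionMap",
           function(x, which, interiorOnly = FALSE)
             standardGeneric("distortionMap"))

#' Cohort accessors
#'
#' @param x a [CohortTable-class].
#' @return `cohortSubjects`: data.frame of subject_id/group/age/sex;
#'   `cohortFeatures`, `cohortScores`: numeric matrices; `roiNames`,
#'   `metricNames`, `scoreNames`: character vectors.
#' @aliases cohortSubjects cohortFeatures cohortScores roiNames metricNames
#'   scoreNames
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname cohortSubjects
#' @export
setGeneric("cohortFeatures", function(x) standardGeneric("cohortFeatures"))

#' @rdname cohortSubjects
#' @export
setGeneric("cohortScores", function(x) standardGeneric("cohortScores"))

#' @rdname cohortSubjects
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname cohortSubjects
#' @export
setGeneric("metricNames", function(x) standardGeneric("metricNames"))

#' @rdname cohortSubjects
#' @export
setGeneric("scoreNames", function(x) standardGeneric("scoreNames"))

setMethod("cohortSubjects", "CohortTable", function(x) x@subjects)
setMethod("cohortFeatures", "CohortTable", function(x) x@features)
setMethod("cohortScores", "CohortTable", function(x) x@scores)
setMethod("roiNames", "CohortTable", function(x) x@roiNames)
setMethod("metricNames", "CohortTable", function(x) x@metricNames)
setMethod("scoreNames", "CohortTable", function(x) colnames(x@scores))

#' Mirror an image along the left-right axis
#'
#' Implements the affected-side convention: images of subjects whose affected
#' side is the left are mirrored so that the "right" side is the affected side
#' throughout; images with `flip = FALSE` (e.g. healthy controls) are
#' returned unchanged, bit for bit. The left-right axis is taken from the
#' object's orientation code; an unknown orientation is an error, never a
#' silent guess.
#'
#' @param x a [ScalarMap-class], [DWIVolume-class], or `RNifti` image.
#' @param flip logical; mirror when `TRUE`.
#' @return an object of the same class; metadata records the flip state.
#' @export
setGeneric("flipLateral", function(x, flip = TRUE) standardGeneric("flipLateral"))
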