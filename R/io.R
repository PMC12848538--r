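#' Write a scalar map as NIfTI-1
#'
#' The voxel spacing is stored in the header pixdim and the metric name in
#' the description field.
#'
#' @param map a [ScalarMap-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return invisibly, `path`.
#' @export
writeScalarMap <- function(map, path) {
  img <- RNifti::asNifti(map@values)
  RNifti::pixdim(img) <- map@spacing
  img$descrip <- map@metric
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a scalar map
#'
#' @param path NIfTI file path.
#' @param metric metric name; defaults to the header description when set.
#' @param mask optional logical array; defaults to finite, nonzero voxels.
#' @return a [ScalarMap-class].
#' @export
readScalarMap <- function(path, metric = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  hdr <- RNifti::niftiHeader(img)
  if (is.null(metric)) {
    metric <- trimws(hdr$descrip)
    if (!nzchar(metric)) metric <- "unknown"
  }
  sp <- abs(hdr$pixdim[2:4])
  sp[sp == 0] <- 1
  ax <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(ax) || !nzchar(ax)) ax <- "???"
  if (is.null(mask)) mask <- is.finite(vals) & vals != 0
  new("ScalarMap", values = vals, metric = metric, mask = mask,
      spacing = sp, axes = ax)
}

#' Write a simulated acquisition as NIfTI + bval/bvec
#'
#' Produces `<prefix>.nii.gz`, `<prefix>.bval` and `<prefix>.bvec` (FSL
#' dialect, image-coordinate convention).
#'
#' @param dwi a [DWIVolume-class].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeDWI <- function(dwi, prefix) {
  img <- RNifti::asNifti(dwi@data)
  RNifti::pixdim(img) <- c(dwi@spacing, 1)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  paths <- writeGradientTable(dwi@gtab, paste0(prefix, ".bval"),
                              paste0(prefix, ".bvec"))
  invisible(c(nii, paths))
}

#' Read a 4D acquisition from NIfTI + bval/bvec
#'
#' @param niiPath 4D NIfTI file.
#' @param bvalPath,bvecPath FSL-dialect gradient files.
#' @param mask optional logical array (default: voxels with positive mean
#'   b=0 signal).
#' @return a [DWIVolume-class].
#' @export
readDWI <- function(niiPath, bvalPath, bvecPath, mask = NULL) {
  img <- RNifti::readNifti(niiPath)
  stopifnot(length(dim(img)) == 4L)
  dat <- array(as.numeric(img), dim(img))
  gtab <- loadGradientTable(bvalPath, bvecPath, nVolumes = dim(dat)[4])
  hdr <- RNifti::niftiHeader(img)
  sp <- abs(hdr$pixdim[2:4])
  sp[sp == 0] <- 1
  ax <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(ax) || !nzchar(ax)) ax <- "???"
  if (is.null(mask)) {
    b0 <- gtab@bvals < gtab@b0Threshold
    meanB0 <- apply(dat[, , , b0, drop = FALSE], 1:3, mean)
    mask <- is.finite(meanB0) & meanB0 > 0
  }
  new("DWIVolume", data = dat, gtab = gtab, mask = mask, spacing = sp,
      axes = ax)
}

#' Write a label atlas as NIfTI-1
#'
#' @param atlas result of [makeAtlasLabels].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAtlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a tensor field as 4D NIfTI
#'
#' Components are stored as six volumes in lower-triangular row order
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), the dialect used throughout this package.
#'
#' @param tensors a [TensorField-class].
#' @param path NIfTI file path.
#' @return `writeTensorField` invisibly returns `path`; `readTensorField`
#'   returns a [TensorField-class].
#' @export
writeTensorField <- function(tensors, path) {
  img <- RNifti::asNifti(tensors@values)
  RNifti::pixdim(img) <- c(tensors@spacing, 1)
  img$descrip <- "tensor_lower_triangular"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeTensorField
#' @param mask optional logical array; defaults to voxels with a nonzero
#'   tensor.
#' @export
readTensorField <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 4L, dim(img)[4] == 6L)
  vals <- array(as.numeric(img), dim(img))
  hdr <- RNifti::niftiHeader(img)
  sp <- abs(hdr$pixdim[2:4])
  sp[sp == 0] <- 1
  if (is.null(mask))
    mask <- apply(vals != 0, 1:3, any) & apply(is.finite(vals), 1:3, all)
  new("TensorField", values = vals, mask = mask, spacing = sp)
}
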