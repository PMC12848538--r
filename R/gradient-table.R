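#' Construct a gradient table
#'
#' Validates and normalizes a diffusion gradient scheme. b-values below
#' `b0Threshold` (default 50 s/mm^2, a common tolerance for vendor rounding)
#' are treated as b=0 and may carry zero vectors. Direction vectors whose
#' norm is within `normTol` of 1 are renormalized; a zero vector on a
#' diffusion-weighted volume is an error.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x n matrix (or n x 3, transposed automatically) of
#'   gradient directions in image coordinates.
#' @param b0Threshold b-values below this count as b=0.
#' @param normTol accepted deviation of |g| from 1 before renormalization.
#' @return a [GradientTable-class].
#' @examples
#' gt <- gradientTable(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
#' bValues(gt)
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50, normTol = 1e-3) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (or 3 columns)")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("count mismatch: %d b-values but %d b-vectors",
                 length(bvals), ncol(bvecs)))
  dw <- bvals >= b0Threshold
  nrm <- sqrt(colSums(bvecs^2))
  if (any(dw & nrm == 0))
    stop("nonzero b-value with a zero gradient vector")
  if (any(dw & abs(nrm - 1) > normTol))
    stop(sprintf("gradient vector norm deviates from 1 by more than %g", normTol))
  bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm[dw], `/`)
  bvecs[, !dw & nrm > 0] <- sweep(bvecs[, !dw & nrm > 0, drop = FALSE], 2,
                                  nrm[!dw & nrm > 0], `/`)
  new("GradientTable", bvals = bvals, bvecs = bvecs, b0Threshold = b0Threshold)
}

#' Read FSL-dialect bval/bvec files
#'
#' The bval file holds one whitespace-separated row of b-values; the bvec
#' file three rows (x, y, z components), one column per volume, in image
#' coordinates.
#'
#' @param bvalPath,bvecPath paths to the text files.
#' @param nVolumes if given, the expected number of volumes; a mismatch is
#'   an error.
#' @inheritParams gradientTable
#' @return a [GradientTable-class].
#' @export
loadGradientTable <- function(bvalPath, bvecPath, nVolumes = NULL,
                              b0Threshold = 50) {
  if (!file.exists(bvalPath)) stop("bval file not found: ", bvalPath)
  if (!file.exists(bvecPath)) stop("bvec file not found: ", bvecPath)
  bvals <- scan(bvalPath, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecPath))
  if (nrow(bv) != 3L)
    stop("bvec file must have exactly 3 rows")
  if (ncol(bv) != length(bvals))
    stop(sprintf("bval/bvec mismatch: %d b-values but %d direction columns",
                 length(bvals), ncol(bv)))
  if (!is.null(nVolumes) && length(bvals) != nVolumes)
    stop(sprintf("gradient table has %d entries but %d volumes expected",
                 length(bvals), nVolumes))
  gradientTable(bvals, bv, b0Threshold = b0Threshold)
}

#' Write FSL-dialect bval/bvec files
#'
#' @param gtab a [GradientTable-class].
#' @param bvalPath,bvecPath output paths.
#' @return invisibly, the two paths.
#' @export
writeGradientTable <- function(gtab, bvalPath, bvecPath) {
  cat(paste(format(gtab@bvals, trim = TRUE), collapse = " "), "\n",
      file = bvalPath, sep = "")
  write.table(format(gtab@bvecs, digits = 17, trim = TRUE), bvecPath,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bvalPath, bvecPath))
}

#' Default single-shell acquisition scheme
#'
#' Eight b=0 volumes followed by 64 diffusion-weighted directions at
#' b = 1000 s/mm^2 (deterministic Fibonacci-hemisphere directions), matching
#' a common 2 mm isotropic clinical DTI protocol.
#'
#' @param nDirections number of diffusion-weighted directions.
#' @param nB0 number of b=0 volumes (prepended).
#' @param bValue shell b-value in s/mm^2.
#' @return a [GradientTable-class] with `nB0 + nDirections` entries.
#' @export
defaultGradientTable <- function(nDirections = 64, nB0 = 8, bValue = 1000) {
  dirs <- fibonacciDirections(nDirections)
  bvals <- c(rep(0, nB0), rep(bValue, nDirections))
  bvecs <- cbind(matrix(0, 3, nB0), dirs)
  gradientTable(bvals, bvecs)
}

setMethod("show", "GradientTable", function(object) {
  dw <- object@bvals >= object@b0Threshold
  cat("GradientTable:", length(object@bvals), "volumes (",
      sum(dw), "diffusion-weighted,", sum(!dw), "b=0 )\n")
  cat("  shells (s/mm^2):",
      paste(sort(unique(round(object@bvals[dw]))), collapse = ", "), "\n")
})
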