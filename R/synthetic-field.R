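#' Canonical distortion pattern director fields
#'
#' Builds the three canonical orientational-distortion phantoms used to
#' illustrate director field analysis, plus a uniform control field. Each
#' pattern is a planar (2D) construction in the first two grid axes,
#' replicated across the third axis:
#'
#' * `"splay"` — in-plane radial unit vectors about `center`; fibers fan out
#'   from the central voxel.
#' * `"bend"` — in-plane tangential unit vectors about `center`; fibers run
#'   on circles around the central voxel.
#' * `"twist"` — directors perpendicular to the first grid axis, rotated
#'   about that axis by `twistRate` radians per voxel of travel along it.
#' * `"uniform"` — one constant direction; every distortion index is zero.
#'
#' The singular central voxel of the splay and bend patterns (where the
#' radial direction is undefined) is excluded from the validity mask.
#'
#' @param pattern one of "splay", "bend", "twist", "uniform".
#' @param gridShape integer length-3 grid size; pattern axes must be >= 5.
#' @param voxelSize voxel spacing in mm per axis.
#' @param twistRate rotation in radians per voxel along the twist axis
#'   (required for `pattern = "twist"`).
#' @param center pattern center in voxel coordinates (defaults to the grid
#'   midpoint); used by splay/bend only.
#' @return a [DirectorField-class].
#' @examples
#' f <- makePatternField("splay", gridShape = c(21, 21, 5))
#' sum(imgMask(f))   # all voxels except the singular center column
#' @export
makePatternField <- function(pattern = c("splay", "bend", "twist", "uniform"),
                             gridShape = c(21, 21, 5),
                             voxelSize = c(2, 2, 2),
                             twistRate = 0.1,
                             center = NULL) {
  pattern <- match.arg(pattern)
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, length(voxelSize) == 3L,
            all(voxelSize > 0))
  patternAxes <- switch(pattern, splay = 1:2, bend = 1:2, twist = 1L,
                        uniform = integer(0))
  if (any(gridShape[patternAxes] < 5L))
    stop("degenerate grid: pattern axes must span at least 5 voxels")
  if (pattern == "twist" && (!is.numeric(twistRate) || is.na(twistRate)))
    stop("twistRate must be given for the twist pattern")
  if (is.null(center)) center <- (gridShape + 1) / 2
  d <- gridShape
  vec <- array(0, c(d, 3L))
  mask <- array(TRUE, d)

  if (pattern %in% c("splay", "bend")) {
    # physical in-plane offsets from the pattern center
    dx <- (seq_len(d[1]) - center[1]) * voxelSize[1]
    dy <- (seq_len(d[2]) - center[2]) * voxelSize[2]
    DX <- outer(dx, rep(1, d[2]))
    DY <- outer(rep(1, d[1]), dy)
    R <- sqrt(DX^2 + DY^2)
    sing <- R < .Machine$double.eps^0.5
    Rsafe <- ifelse(sing, 1, R)
    if (pattern == "splay") { ux <- DX / Rsafe; uy <- DY / Rsafe }
    else                    { ux <- -DY / Rsafe; uy <- DX / Rsafe }
    for (k in seq_len(d[3])) {
      vec[, , k, 1] <- ux
      vec[, , k, 2] <- uy
      mask[, , k] <- !sing
    }
    # placeholder director at the flagged singular voxel(s)
    vec[, , , 1][rep(sing, d[3])] <- 1
  } else if (pattern == "twist") {
    theta <- twistRate * (seq_len(d[1]) - 1)
    vec[, , , 2] <- array(rep(cos(theta), times = d[2] * d[3]), d)
    vec[, , , 3] <- array(rep(sin(theta), times = d[2] * d[3]), d)
  } else {
    vec[, , , 3] <- 1
  }
  new("DirectorField", vectors = vec, mask = mask,
      spacing = as.numeric(voxelSize))
}

#' Realize a director field as a diffusion tensor field
#'
#' Each in-mask voxel receives the axially symmetric tensor
#' `D = lambdaPerp * I + (lambdaParallel - lambdaPerp) * n n'`, whose
#' eigenvalues are exactly (lambdaParallel, lambdaPerp, lambdaPerp) and whose
#' principal eigenvector is collinear with the director `n`. Out-of-mask
#' voxels are filled with the isotropic tensor `lambdaPerp * I` so the field
#' stays positive definite everywhere.
#'
#' @param field a [DirectorField-class] of unit directors.
#' @param lambdaParallel,lambdaPerp tensor eigenvalues in mm^2/s, with
#'   `lambdaParallel >= lambdaPerp > 0`. Defaults are typical healthy white
#'   matter values.
#' @return a [TensorField-class].
#' @export
directorsToTensors <- function(field, lambdaParallel = 1.7e-3,
                               lambdaPerp = 0.3e-3) {
  stopifnot(is(field, "DirectorField"))
  if (!(lambdaParallel >= lambdaPerp && lambdaPerp > 0))
    stop("require lambdaParallel >= lambdaPerp > 0")
  d <- dim(field@vectors)[1:3]
  v <- matrix(field@vectors, ncol = 3L)
  msk <- as.logical(field@mask)
  nrm <- sqrt(rowSums(v[msk, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("directors must have unit norm")
  dl <- lambdaParallel - lambdaPerp
  t6 <- matrix(0, nrow(v), 6L)
  t6[, 1] <- lambdaPerp + dl * v[, 1]^2 * msk
  t6[, 2] <- dl * v[, 1] * v[, 2] * msk
  t6[, 3] <- dl * v[, 1] * v[, 3] * msk
  t6[, 4] <- lambdaPerp + dl * v[, 2]^2 * msk
  t6[, 5] <- dl * v[, 2] * v[, 3] * msk
  t6[, 6] <- lambdaPerp + dl * v[, 3]^2 * msk
  new("TensorField", values = array(t6, c(d, 6L)),
      mask = field@mask, spacing = field@spacing)
}

setMethod("show", "DirectorField", function(object) {
  d <- dim(object@vectors)[1:3]
  cat("DirectorField:", paste(d, collapse = " x "), "grid,",
      sum(object@mask), "valid voxels\n")
  cat("  spacing (mm):", paste(object@spacing, collapse = " x "), "\n")
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@values)[1:3]
  cat("TensorField:", paste(d, collapse = " x "), "grid,",
      sum(object@mask), "in-mask voxels\n")
  cat("  spacing (mm):", paste(object@spacing, collapse = " x "), "\n")
})
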