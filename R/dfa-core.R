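#' Extract the director field from a tensor field
#'
#' The director at each voxel is the principal eigenvector of the diffusion
#' tensor, an axis defined only up to sign. Voxels where the principal
#' direction is not meaningful are removed from the validity mask: FA below
#' `faMin` (default 0.2, mirroring the usual white-matter skeleton
#' threshold) or a degenerate leading eigenvalue pair
#' (`l1 - l2 < degenTol * |l1|`), where the eigenvector is arbitrary.
#'
#' @param tensors a [TensorField-class].
#' @param faMin minimum FA for a voxel to carry a valid director.
#' @param degenTol relative eigenvalue-gap tolerance for degeneracy.
#' @return a [DirectorField-class].
#' @export
extractDirectors <- function(tensors, faMin = 0.2, degenTol = 1e-6) {
  stopifnot(is(tensors, "TensorField"))
  eig <- tensorEigensystem(tensors)
  d <- dim(eig@values)[1:3]
  lam <- matrix(eig@values, ncol = 3L)
  fa <- faFromEigenvalues(lam)
  degen <- (lam[, 1] - lam[, 2]) < degenTol * pmax(abs(lam[, 1]),
                                                  .Machine$double.xmin)
  mask <- as.logical(eig@mask) & fa >= faMin & !degen
  if (!any(mask)) stop("no voxel carries a valid director (empty mask)")
  vecs <- array(eig@vectors[, , , , 1L], c(d, 3L))
  # renormalize against eigen-solver rounding; zero out invalid voxels
  vm <- matrix(vecs, ncol = 3L)
  nrm <- sqrt(rowSums(vm^2))
  ok <- mask & nrm > 0
  vm[ok, ] <- vm[ok, , drop = FALSE] / nrm[ok]
  vm[!ok, ] <- rep(c(1, 0, 0), each = sum(!ok))
  new("DirectorField", vectors = array(vm, c(d, 3L)),
      mask = array(mask & ok, d), spacing = tensors@spacing)
}

#' Spatial derivative (Jacobian) of a director field
#'
#' Central differences along each grid axis, in 1/mm. Because directors are
#' axes (sign-indeterminate), each neighbour vector `v` is replaced by `-v`
#' whenever `v . n(center) < 0` before differencing, which makes the result
#' invariant under arbitrary voxelwise sign flips of the stored field. At
#' mask edges a one-sided first-order difference is used and the voxel is
#' flagged as boundary-affected; a voxel with no valid neighbour along some
#' axis has no derivative and is excluded from the `defined` mask.
#'
#' @param field a [DirectorField-class].
#' @param perVoxel if `TRUE`, derivatives are per voxel instead of per mm.
#' @return list with `J` (5D array: x, y, z, vector component, spatial
#'   axis), `defined` and `boundary` logical 3D arrays.
#' @export
directorJacobian <- function(field, perVoxel = FALSE) {
  stopifnot(is(field, "DirectorField"))
  d <- dim(field@vectors)[1:3]
  vec <- field@vectors
  mask <- array(as.logical(field@mask), d)
  h <- if (perVoxel) c(1, 1, 1) else field@spacing
  J <- array(NA_real_, c(d, 3L, 3L))
  defined <- mask
  boundary <- array(FALSE, d)
  alignTo <- function(nb) {
    dotp <- nb[, , , 1] * vec[, , , 1] + nb[, , , 2] * vec[, , , 2] +
      nb[, , , 3] * vec[, , , 3]
    s <- ifelse(dotp < 0, -1, 1)
    out <- nb
    for (i in 1:3) out[, , , i] <- nb[, , , i] * s
    out
  }
  for (ax in 1:3) {
    fwd <- shiftArray(vec, ax, by = -1L, fill = NA_real_)
    bwd <- shiftArray(vec, ax, by = +1L, fill = NA_real_)
    fwdOk <- shiftArray(mask, ax, by = -1L, fill = FALSE) & mask
    bwdOk <- shiftArray(mask, ax, by = +1L, fill = FALSE) & mask
    fwd <- alignTo(fwd)
    bwd <- alignTo(bwd)
    central <- fwdOk & bwdOk
    fwdOnly <- fwdOk & !bwdOk
    bwdOnly <- bwdOk & !fwdOk
    none <- mask & !fwdOk & !bwdOk
    for (i in 1:3) {
      der <- array(NA_real_, d)
      der[central] <- (fwd[, , , i][central] - bwd[, , , i][central]) /
        (2 * h[ax])
      der[fwdOnly] <- (fwd[, , , i][fwdOnly] - vec[, , , i][fwdOnly]) / h[ax]
      der[bwdOnly] <- (vec[, , , i][bwdOnly] - bwd[, , , i][bwdOnly]) / h[ax]
      J[, , , i, ax] <- der
    }
    boundary <- boundary | (mask & !central)
    defined <- defined & !none
  }
  list(J = J, defined = defined, boundary = boundary)
}

#' Orientational distortion indices of a director field
#'
#' Computes the three elementary distortion modes of an axis field, in the
#' classical liquid-crystal (Frank) scalar form, from the sign-aligned
#' spatial Jacobian `J` of the director `n`:
#'
#' * splay `s = |div n| = |trace(J)|` — fanning of fibers perpendicular to
#'   their own axis;
#' * bend `b = ||(n . grad) n|| = ||J n||` — change of direction along the
#'   fiber;
#' * twist `t = |n . curl n|` — rotation of neighbouring fibers about the
#'   fiber axis.
#'
#' All three are invariant to any rotation of the transverse frame and to
#' global or voxelwise sign flips of the director, and the total distortion
#' is their root-sum-square. An alternative local-frame variant
#' (`variant = "frame"`) reports sums of squared frame components
#' (`sqrt(a22^2 + a33^2)` for splay, `sqrt(b2^2 + b3^2)` for bend,
#' `sqrt(a23^2 + a32^2)` for twist, with `a_{ij} = u_i' J u_j` in a
#' transverse frame `u2, u3`) for comparison.
#'
#' @param field a [DirectorField-class].
#' @param variant "frank" (default) or "frame".
#' @param perVoxel if `TRUE`, indices are rad/voxel instead of rad/mm.
#' @return a [DistortionMaps-class]; voxels without a defined derivative are
#'   `NA` and excluded from the `defined` mask.
#' @examples
#' f <- makePatternField("twist", c(21, 5, 5), twistRate = 0.1)
#' m <- distortionIndices(f)
#' mean(m@twist[m@interior])   # about 0.1 / voxel size, constant
#' @export
distortionIndices <- function(field, variant = c("frank", "frame"),
                              perVoxel = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is(field, "DirectorField"))
  jac <- directorJacobian(field, perVoxel = perVoxel)
  d <- dim(field@vectors)[1:3]
  J <- jac$J
  n1 <- field@vectors[, , , 1]
  n2 <- field@vectors[, , , 2]
  n3 <- field@vectors[, , , 3]
  if (variant == "frank") {
    splay <- abs(J[, , , 1, 1] + J[, , , 2, 2] + J[, , , 3, 3])
    bx <- J[, , , 1, 1] * n1 + J[, , , 1, 2] * n2 + J[, , , 1, 3] * n3
    by <- J[, , , 2, 1] * n1 + J[, , , 2, 2] * n2 + J[, , , 2, 3] * n3
    bz <- J[, , , 3, 1] * n1 + J[, , , 3, 2] * n2 + J[, , , 3, 3] * n3
    bend <- sqrt(bx^2 + by^2 + bz^2)
    cx <- J[, , , 3, 2] - J[, , , 2, 3]
    cy <- J[, , , 1, 3] - J[, , , 3, 1]
    cz <- J[, , , 2, 1] - J[, , , 1, 2]
    twist <- abs(n1 * cx + n2 * cy + n3 * cz)
  } else {
    nM <- cbind(as.vector(n1), as.vector(n2), as.vector(n3))
    # deterministic transverse frame: u2 from the axis least aligned with n
    ref <- diag(3)[, apply(abs(nM), 1, which.min), drop = FALSE]
    u2 <- cbind(nM[, 2] * ref[3, ] - nM[, 3] * ref[2, ],
                nM[, 3] * ref[1, ] - nM[, 1] * ref[3, ],
                nM[, 1] * ref[2, ] - nM[, 2] * ref[1, ])
    u2 <- u2 / pmax(sqrt(rowSums(u2^2)), .Machine$double.xmin)
    u3 <- cbind(nM[, 2] * u2[, 3] - nM[, 3] * u2[, 2],
                nM[, 3] * u2[, 1] - nM[, 1] * u2[, 3],
                nM[, 1] * u2[, 2] - nM[, 2] * u2[, 1])
    JM <- matrix(J, ncol = 9L)  # columns (i,ax) in column-major order
    proj <- function(u, v) {    # u' J v per voxel
      out <- 0
      for (axj in 1:3) for (i in 1:3)
        out <- out + u[, i] * JM[, i + 3L * (axj - 1L)] * v[, axj]
      out
    }
    a22 <- proj(u2, u2); a33 <- proj(u3, u3)
    a23 <- proj(u2, u3); a32 <- proj(u3, u2)
    b2 <- proj(u2, nM);  b3 <- proj(u3, nM)
    splay <- array(sqrt(a22^2 + a33^2), d)
    bend <- array(sqrt(b2^2 + b3^2), d)
    twist <- array(sqrt(a23^2 + a32^2), d)
  }
  splay[!jac$defined] <- NA_real_
  bend[!jac$defined] <- NA_real_
  twist[!jac$defined] <- NA_real_
  total <- sqrt(splay^2 + bend^2 + twist^2)
  new("DistortionMaps", splay = splay, bend = bend, twist = twist,
      total = total, defined = jac$defined,
      interior = jac$defined & !jac$boundary,
      spacing = field@spacing,
      units = if (perVoxel) "rad/voxel" else "rad/mm")
}

#' Total orientational distortion
#'
#' Root-sum-square of the splay, bend and twist maps,
#' `d = sqrt(s^2 + b^2 + t^2)`, evaluated voxelwise.
#'
#' @param splay a [DistortionMaps-class], or a numeric array of splay values.
#' @param bend,twist numeric arrays (when `splay` is an array).
#' @return a [ScalarMap-class].
#' @export
totalDistortion <- function(splay, bend = NULL, twist = NULL) {
  if (is(splay, "DistortionMaps")) {
    m <- splay
    vals <- sqrt(m@splay^2 + m@bend^2 + m@twist^2)
    return(new("ScalarMap", values = vals, metric = "total_distortion",
               mask = array(as.logical(m@defined), dim(vals)),
               spacing = m@spacing))
  }
  if (is.null(bend) || is.null(twist))
    stop("bend and twist arrays are required")
  if (!identical(dim(splay), dim(bend)) || !identical(dim(splay), dim(twist)))
    stop("component map shapes do not match")
  vals <- sqrt(splay^2 + bend^2 + twist^2)
  dm <- if (is.null(dim(vals))) c(length(vals), 1L, 1L) else dim(vals)
  vals <- array(vals, dm)
  new("ScalarMap", values = vals, metric = "total_distortion",
      mask = array(is.finite(vals), dm), spacing = c(1, 1, 1))
}

#' @describeIn distortionMap extract splay/bend/twist/total as a ScalarMap.
#' @export
setMethod("distortionMap", "DistortionMaps",
          function(x, which, interiorOnly = FALSE) {
  which <- match.arg(which, c("splay", "bend", "twist", "total_distortion"))
  vals <- switch(which, splay = x@splay, bend = x@bend, twist = x@twist,
                 total_distortion = x@total)
  mask <- if (interiorOnly) x@interior else x@defined
  vals[!mask] <- NA_real_
  new("ScalarMap", values = vals, metric = which,
      mask = array(as.logical(mask), dim(vals)), spacing = x@spacing)
})

setMethod("show", "DistortionMaps", function(object) {
  cat("DistortionMaps (", object@units, "): ",
      paste(dim(object@splay), collapse = " x "), " grid, ",
      sum(object@defined), " defined / ", sum(object@interior),
      " interior voxels\n", sep = "")
  for (nm in c("splay", "bend", "twist", "total")) {
    v <- slot(object, nm)[object@interior]
    if (length(v))
      cat(sprintf("  %-6s mean %.4g  max %.4g\n", nm, mean(v), max(v)))
  }
})
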