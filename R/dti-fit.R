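#' Fit diffusion tensors voxelwise
#'
#' Log-linear least-squares tensor reconstruction: for each in-mask voxel the
#' model `ln S_i = ln S0 - b_i g_i' D g_i` is solved for the seven unknowns
#' (ln S0 and the six tensor components). The default is weighted least
#' squares with one refinement pass, weights equal to the squared fitted
#' signal; this is exact on noiseless data and the standard fast estimator.
#' Voxels with any non-positive in-mask signal are excluded from the output
#' mask (taking logs of such values would distort the fit); the exclusion
#' count is reported via a message.
#'
#' @param dwi a [DWIVolume-class] with at least 7 volumes spanning 6 or more
#'   distinct diffusion-weighted directions.
#' @param method "wls" (default) or "ols".
#' @return a list with `tensors` (a [TensorField-class]) and `s0` (a
#'   [ScalarMap-class] of fitted S0 values).
#' @examples
#' tf <- directorsToTensors(makePatternField("uniform", c(5, 5, 5)))
#' fit <- fitTensors(simulateDWI(tf, noiseSigma = 0))
#' max(abs(imgData(fit$tensors) - imgData(tf)))
#' @export
fitTensors <- function(dwi, method = c("wls", "ols")) {
  method <- match.arg(method)
  stopifnot(is(dwi, "DWIVolume"))
  gtab <- dwi@gtab
  b <- gtab@bvals
  g <- gtab@bvecs
  dwsel <- b >= gtab@b0Threshold
  if (length(b) < 7L)
    stop("need at least 7 volumes to fit a tensor")
  if (sum(dwsel) < 6L)
    stop("need at least 6 diffusion-weighted directions")
  # design: ln S = X theta, theta = (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
  gx <- g[1, ]; gy <- g[2, ]; gz <- g[3, ]
  X <- cbind(1, -b * gx^2, -2 * b * gx * gy, -2 * b * gx * gz,
             -b * gy^2, -2 * b * gy * gz, -b * gz^2)
  if (qr(X)$rank < 7L)
    stop("rank-deficient design: gradient directions are collinear")
  d <- dim(dwi@data)[1:3]
  S <- matrix(dwi@data, ncol = dim(dwi@data)[4])   # voxels x volumes
  mask <- as.logical(dwi@mask)
  if (!any(mask)) stop("empty mask")
  bad <- mask & matrixStatsAnyNonPos(S)
  if (any(bad))
    message(sum(bad), " voxel(s) with non-positive signal excluded from mask")
  use <- mask & !bad
  theta <- matrix(NA_real_, sum(use), 7L)
  Y <- t(log(S[use, , drop = FALSE]))              # volumes x voxels
  ols <- solve(crossprod(X), crossprod(X, Y))      # 7 x voxels
  theta <- t(ols)
  if (method == "wls") {
    fitted <- X %*% ols                            # volumes x voxels
    W <- exp(2 * fitted)                           # squared fitted signal
    for (v in seq_len(ncol(Y))) {
      w <- W[, v]
      XtW <- t(X * w)
      theta[v, ] <- solve(XtW %*% X, XtW %*% Y[, v])
    }
  }
  t6 <- matrix(0, prod(d), 6L)
  t6[use, ] <- theta[, 2:7]
  s0 <- array(0, d)
  s0[use] <- exp(theta[, 1])
  maskArr <- array(use, d)
  list(tensors = new("TensorField", values = array(t6, c(d, 6L)),
                     mask = maskArr, spacing = dwi@spacing),
       s0 = new("ScalarMap", values = s0, metric = "S0", mask = maskArr,
                spacing = dwi@spacing, axes = dwi@axes))
}

# rowwise any(x <= 0) without allocating a logical matrix copy per call
matrixStatsAnyNonPos <- function(S) {
  out <- rep(FALSE, nrow(S))
  for (j in seq_len(ncol(S))) out <- out | S[, j] <= 0
  out
}

#' Voxelwise eigensystem of a tensor field
#'
#' Eigenvalues are returned in descending order with orthonormal
#' eigenvectors; the spectral reconstruction `sum_k lambda_k e_k e_k'`
#' equals the input tensor to numerical precision. Voxels with non-finite
#' tensors are dropped from the mask.
#'
#' @param tensors a [TensorField-class].
#' @return a [TensorEigensystem-class].
#' @export
tensorEigensystem <- function(tensors) {
  stopifnot(is(tensors, "TensorField"))
  d <- dim(tensors@values)[1:3]
  t6 <- matrix(tensors@values, ncol = 6L)
  mask <- as.logical(tensors@mask)
  finite <- rowSums(!is.finite(t6)) == 0
  mask <- mask & finite
  vals <- array(0, c(d, 3L))
  vecs <- array(0, c(d, 3L, 3L))
  valM <- matrix(0, prod(d), 3L)
  vecM <- matrix(0, prod(d), 9L)
  idx <- which(mask)
  for (v in idx) {
    e <- eigen(tensorAsMatrix(t6[v, ]), symmetric = TRUE)
    valM[v, ] <- e$values
    vecM[v, ] <- as.vector(e$vectors)
  }
  vals[] <- valM
  vecs[] <- vecM
  new("TensorEigensystem", values = vals, vectors = vecs,
      mask = array(mask, d), spacing = tensors@spacing)
}

#' Eigenvalue-based scalar maps (FA and MD)
#'
#' `MD = (l1 + l2 + l3) / 3` and
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`. Negative eigenvalues
#' (possible under noise) are clamped to zero before evaluating the closed
#' forms, which guarantees FA in [0, 1] and MD >= 0; an all-zero tensor is
#' assigned FA = 0. The raw tensors are not modified.
#'
#' @param eig a [TensorEigensystem-class].
#' @return named list of [ScalarMap-class] objects: `FA`, `MD`.
#' @export
scalarMaps <- function(eig) {
  stopifnot(is(eig, "TensorEigensystem"))
  d <- dim(eig@values)[1:3]
  lam <- matrix(eig@values, ncol = 3L)
  fa <- array(faFromEigenvalues(lam), d)
  md <- array(mdFromEigenvalues(lam), d)
  fa[!eig@mask] <- 0
  md[!eig@mask] <- 0
  list(FA = new("ScalarMap", values = fa, metric = "FA", mask = eig@mask,
                spacing = eig@spacing),
       MD = new("ScalarMap", values = md, metric = "MD", mask = eig@mask,
                spacing = eig@spacing))
}

# Which array axis runs left-right, from a three-letter orientation code.
lrAxis <- function(axes) {
  if (length(axes) != 1L || is.na(axes) || !nzchar(axes))
    stop("ambiguous orientation: no axis code recorded")
  letters3 <- strsplit(toupper(axes), "")[[1]]
  ax <- which(letters3 %in% c("L", "R"))
  if (length(ax) != 1L)
    stop("ambiguous orientation: cannot identify the left-right axis in '",
         axes, "'")
  ax
}

flipAlong <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' @describeIn flipLateral mirror a scalar map.
#' @export
setMethod("flipLateral", "ScalarMap", function(x, flip = TRUE) {
  if (!isTRUE(flip)) return(x)
  ax <- lrAxis(x@axes)
  x@values <- flipAlong(x@values, ax)
  x@mask <- flipAlong(x@mask, ax)
  x@meta$flippedLR <- !isTRUE(x@meta$flippedLR)
  x
})

#' @describeIn flipLateral mirror a 4D diffusion-weighted volume.
#' @export
setMethod("flipLateral", "DWIVolume", function(x, flip = TRUE) {
  if (!isTRUE(flip)) return(x)
  ax <- lrAxis(x@axes)
  x@data <- flipAlong(x@data, ax)
  x@mask <- flipAlong(x@mask, ax)
  x@meta$flippedLR <- !isTRUE(x@meta$flippedLR)
  x
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values[as.logical(object@mask)]
  cat("ScalarMap (", object@metric, "): ",
      paste(dim(object@values), collapse = " x "), " grid\n", sep = "")
  if (length(v))
    cat(sprintf("  in-mask range: [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
})
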