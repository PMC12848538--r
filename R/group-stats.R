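#' Per-ROI mean values of a scalar map
#'
#' Mean of the in-mask, non-flagged voxels of `map` within each atlas label
#' (a re-implementation of the usual ROI mean extraction). A region with no
#' usable voxel yields `NA`, never 0.
#'
#' @param map a [ScalarMap-class] or numeric 3D array.
#' @param atlas result of [makeAtlasLabels], or an integer 3D label array.
#' @param mask optional extra logical array restricting the summary.
#' @return data.frame with columns `label`, `roi`, `mean`, `nVoxels`.
#' @export
roiSummaries <- function(map, atlas, mask = NULL) {
  vals <- if (is(map, "ScalarMap")) map@values else map
  vmask <- if (is(map, "ScalarMap")) array(as.logical(map@mask), dim(vals))
           else is.finite(vals)
  labels <- if (is.list(atlas)) atlas$labels else atlas
  nms <- if (is.list(atlas)) atlas$names else attr(atlas, "names3d")
  if (!identical(dim(labels), dim(vals)))
    stop("atlas grid does not match the map grid")
  if (!is.null(mask)) vmask <- vmask & as.logical(mask)
  vmask <- vmask & is.finite(vals)
  k <- max(labels)
  out <- data.frame(label = seq_len(k),
                    roi = if (!is.null(nms)) nms else sprintf("ROI%02d", seq_len(k)),
                    mean = NA_real_, nVoxels = 0L,
                    stringsAsFactors = FALSE)
  use <- labels > 0L & vmask
  if (any(use)) {
    sums <- tapply(vals[use], labels[use], sum)
    cnts <- tapply(rep(1L, sum(use)), labels[use], sum)
    ids <- as.integer(names(sums))
    out$mean[ids] <- as.numeric(sums / cnts)
    out$nVoxels[ids] <- as.integer(cnts)
  }
  out
}

#' Construct a permutation-GLM design
#'
#' @inheritParams StatDesign-class
#' @param X design matrix (subjects x predictors) including the intercept
#'   and nuisance covariates (e.g. age, sex).
#' @param contrast numeric vector (t contrast) or matrix with one row per
#'   component (F contrast), length/columns matching `ncol(X)`.
#' @param nPerm,alpha,enhancement,tfceE,tfceH,tfceDh,connectivity,seed see
#'   [StatDesign-class].
#' @return a [StatDesign-class].
#' @export
statDesign <- function(X, contrast, nPerm = 1000, alpha = 0.05,
                       enhancement = c("none", "tfce"), tfceE = 0.5,
                       tfceH = 2, tfceDh = NA, connectivity = 26,
                       seed = NA) {
  enhancement <- match.arg(enhancement)
  X <- as.matrix(X)
  if (is.null(dim(contrast))) contrast <- matrix(contrast, nrow = 1)
  new("StatDesign", X = X, contrast = contrast, nPerm = nPerm, alpha = alpha,
      enhancement = enhancement, tfceE = tfceE, tfceH = tfceH,
      tfceDh = as.numeric(tfceDh), connectivity = connectivity,
      seed = as.numeric(seed))
}

# Vectorized GLM statistics: Y is volumes x voxels. Returns the t (single
# contrast row) or F statistic per voxel; voxels with zero residual
# variance are NA.
glmStatistic <- function(Y, X, C) {
  n <- nrow(X); p <- ncol(X); q <- nrow(C)
  A <- solve(crossprod(X))
  B <- A %*% crossprod(X, Y)              # p x V
  res <- Y - X %*% B
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  CB <- C %*% B                           # q x V
  if (q == 1L) {
    se <- sqrt(sigma2 * as.numeric(C %*% A %*% t(C)))
    stat <- as.numeric(CB) / se
  } else {
    W <- solve(C %*% A %*% t(C))
    quad <- colSums(CB * (W %*% CB))
    stat <- quad / (q * sigma2)
  }
  stat[sigma2 <= .Machine$double.eps * mean(abs(Y))^2 | !is.finite(stat)] <- NA_real_
  stat
}

#' Voxelwise GLM contrast map
#'
#' Ordinary least-squares fit of each voxel's values on the design matrix;
#' returns the t statistic `c'b / sqrt(s2 c'(X'X)^-1 c)` for a single-row
#' contrast, or the F statistic for a multi-row contrast. Voxels with zero
#' residual variance (identical values across subjects) are flagged `NA`,
#' never returned as infinite.
#'
#' @param maps 4D array (x, y, z, subject) of subject maps.
#' @param design a [StatDesign-class] (only `X` and `contrast` are used).
#' @param mask logical 3D array of voxels to evaluate (default: all finite).
#' @return 3D array of statistics (`NA` outside the mask or where flagged).
#' @export
glmContrastMap <- function(maps, design, mask = NULL) {
  stopifnot(length(dim(maps)) == 4L, is(design, "StatDesign"))
  d <- dim(maps)[1:3]
  n <- dim(maps)[4]
  if (nrow(design@X) != n)
    stop("design rows must match the number of subject maps")
  if (n < ncol(design@X) + 1L)
    stop("need more subjects than predictors")
  M <- t(matrix(maps, ncol = n))          # subjects x voxels
  if (is.null(mask)) mask <- array(colSums(!is.finite(M)) == 0, d)
  v <- as.logical(mask)
  out <- array(NA_real_, d)
  out[v] <- glmStatistic(M[, v, drop = FALSE], design@X, design@contrast)
  out
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum over thresholds h in (0, hmax] of extent(v, h)^E * h^H *
#' dh`, where `extent(v, h)` is the size of the supra-threshold connected
#' component containing `v` at height `h`. Negative values are enhanced by
#' sign-split: the negated grid is enhanced separately and subtracted.
#'
#' @param stat numeric 3D array (non-finite values treated as background).
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh threshold step; default `max/100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return numeric 3D array of enhanced values.
#' @export
tfceEnhance <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  stopifnot(length(dim(stat)) == 3L)
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  s <- stat
  s[!is.finite(s)] <- 0
  tfceOneSided(pmax(s, 0), E, H, dh, connectivity) -
    tfceOneSided(pmax(-s, 0), E, H, dh, connectivity)
}

tfceOneSided <- function(s, E, H, dh, connectivity) {
  out <- array(0, dim(s))
  hmax <- max(s)
  if (hmax <= 0) return(out)
  if (is.null(dh)) dh <- hmax / 100
  for (h in seq(dh, hmax, by = dh)) {
    fg <- s >= h
    lab <- labelComponents(fg, connectivity)
    if (!any(fg)) break
    ext <- tabulate(lab[fg])
    out[fg] <- out[fg] + ext[lab[fg]]^E * h^H * dh
  }
  out
}

#' Permutation-based FWE-corrected group inference
#'
#' Freedman-Lane residual permutation: nuisance effects (the design columns
#' given zero weight by every contrast row) are fitted and removed, the
#' residuals are row-permuted, the nuisance fit is added back, and the full
#' model is refit for each permutation. The null distribution is the
#' permutation distribution of the spatial maximum of the (optionally
#' TFCE-enhanced) statistic, giving corrected p-values
#' `p(v) = (1 + #[perm max >= observed(v)]) / (nPerm + 1)`. Inference is
#' one-sided in the direction of a t contrast (use the negated contrast for
#' the other tail); F contrasts are inherently one-sided. When fewer
#' distinct permutations exist than requested, all of them are enumerated
#' exhaustively (with a warning) and the p-value becomes the exact
#' proportion.
#'
#' @param maps 4D array (x, y, z, subject).
#' @param design a [StatDesign-class].
#' @param mask logical 3D array (default: all-finite voxels).
#' @return a [StatMap-class].
#' @export
permutationFWE <- function(maps, design, mask = NULL) {
  stopifnot(length(dim(maps)) == 4L, is(design, "StatDesign"))
  d <- dim(maps)[1:3]
  n <- dim(maps)[4]
  X <- design@X
  C <- design@contrast
  if (nrow(X) != n) stop("design rows must match the number of subject maps")
  M <- t(matrix(maps, ncol = n))
  if (is.null(mask)) mask <- array(colSums(!is.finite(M)) == 0, d)
  v <- as.logical(mask)
  Y <- M[, v, drop = FALSE]
  useTfce <- design@enhancement == "tfce"
  enhance <- function(statVec) {
    if (!useTfce) return(statVec)
    grid <- array(0, d)
    grid[v] <- statVec
    dh <- if (is.na(design@tfceDh)) NULL else design@tfceDh
    e <- tfceEnhance(grid, design@tfceE, design@tfceH, dh,
                     design@connectivity)
    e[v]
  }
  obsStat <- glmStatistic(Y, X, C)
  obsEnh <- enhance(obsStat)
  # Freedman-Lane reduced model: nuisance = zero-weight columns
  nuis <- colSums(abs(C)) == 0
  Z <- X[, nuis, drop = FALSE]
  if (ncol(Z) == 0L) Z <- matrix(1, n, 1)
  Bz <- solve(crossprod(Z), crossprod(Z, Y))
  fitZ <- Z %*% Bz
  Ez <- Y - fitZ
  nDistinct <- factorial(n)
  exhaustive <- is.finite(nDistinct) && nDistinct <= design@nPerm
  if (exhaustive) {
    warning("fewer distinct permutations (", nDistinct, ") than requested; ",
            "enumerating exhaustively")
    perms <- allPermutations(n)
  } else {
    perms <- withSeed(if (is.na(design@seed)) NULL else design@seed,
                      t(replicate(design@nPerm, sample.int(n))))
  }
  nPerm <- nrow(perms)
  maxDist <- numeric(nPerm)
  for (k in seq_len(nPerm)) {
    Yk <- Ez[perms[k, ], , drop = FALSE] + fitZ
    sk <- glmStatistic(Yk, X, C)
    ek <- enhance(sk)
    maxDist[k] <- max(ek, na.rm = TRUE)
  }
  if (exhaustive) {
    pv <- vapply(obsEnh, function(o)
      if (is.na(o)) NA_real_ else sum(maxDist >= o) / nPerm, numeric(1))
  } else {
    pv <- vapply(obsEnh, function(o)
      if (is.na(o)) NA_real_ else (1 + sum(maxDist >= o)) / (nPerm + 1),
      numeric(1))
  }
  stat <- array(NA_real_, d); stat[v] <- obsStat
  pc <- array(NA_real_, d); pc[v] <- pv
  new("StatMap", stat = stat, pcorr = pc, maxDist = maxDist,
      mask = array(v, d),
      meta = list(contrast = C, seed = design@seed, nPerm = nPerm,
                  enhancement = design@enhancement,
                  exhaustive = exhaustive, alpha = design@alpha))
}

#' Significant supra-threshold clusters
#'
#' Connected components (26-connectivity by default) of the corrected
#' p < alpha set, retaining clusters with a voxel count strictly greater
#' than `minVoxels` (the "> 50 voxels" reporting rule by default). Each
#' cluster is annotated with its peak statistic and the atlas region of
#' maximal overlap.
#'
#' @param stat a [StatMap-class].
#' @param atlas optional [makeAtlasLabels] result or integer label array.
#' @param alpha corrected significance threshold.
#' @param minVoxels minimum voxel count (exclusive).
#' @param connectivity 6, 18 or 26.
#' @return data.frame with columns `cluster`, `nVoxels`, `peakStat`,
#'   `roi`, `overlap`; zero rows when nothing is significant.
#' @export
significantClusters <- function(stat, atlas = NULL, alpha = 0.05,
                                minVoxels = 50, connectivity = 26) {
  stopifnot(is(stat, "StatMap"))
  sig <- !is.na(stat@pcorr) & stat@pcorr < alpha & as.logical(stat@mask)
  out <- data.frame(cluster = integer(0), nVoxels = integer(0),
                    peakStat = numeric(0), roi = character(0),
                    overlap = numeric(0), stringsAsFactors = FALSE)
  if (!any(sig)) return(out)
  lab <- labelComponents(sig, connectivity)
  sizes <- tabulate(lab[sig])
  keep <- which(sizes > minVoxels)
  if (!length(keep)) return(out)
  labels <- if (is.list(atlas)) atlas$labels else atlas
  nms <- if (is.list(atlas)) atlas$names else NULL
  rows <- lapply(seq_along(keep), function(i) {
    cl <- keep[i]
    inCl <- lab == cl
    peak <- max(stat@stat[inCl], na.rm = TRUE)
    roi <- NA_character_; ov <- NA_real_
    if (!is.null(labels)) {
      labIn <- labels[inCl]
      labIn <- labIn[labIn > 0L]
      if (length(labIn)) {
        tab <- tabulate(labIn)
        dom <- which.max(tab)
        ov <- tab[dom] / sizes[cl]
        roi <- if (!is.null(nms)) nms[dom] else sprintf("ROI%02d", dom)
      }
    }
    data.frame(cluster = i, nVoxels = sizes[cl], peakStat = peak,
               roi = roi, overlap = ov, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

setMethod("show", "StatMap", function(object) {
  cat("StatMap:", paste(dim(object@stat), collapse = " x "), "grid,",
      sum(object@mask), "in-mask voxels\n")
  cat("  permutations:", length(object@maxDist),
      if (isTRUE(object@meta$exhaustive)) "(exhaustive)" else "", "\n")
  p <- object@pcorr[as.logical(object@mask)]
  cat("  voxels with corrected p < 0.05:", sum(p < 0.05, na.rm = TRUE), "\n")
})
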