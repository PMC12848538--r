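# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. A NULL seed uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
    return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Shift a 3D (or 3D+component) array by one voxel along `axis`; vacated
# positions are filled with `fill`. Positive `by` moves content toward
# higher indices, so shifted[i] == original[i - by].
shiftArray <- function(a, axis, by = 1L, fill = NA) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - by
  keep <- src >= 1L & src <= d[axis]
  out <- array(fill, d)
  idxTo <- idx; idxTo[[axis]] <- which(keep)
  idxFrom <- idx; idxFrom[[axis]] <- src[keep]
  out <- do.call(`[<-`, c(list(out), idxTo, list(do.call(`[`, c(list(a), idxFrom, list(drop = FALSE))))))
  out
}

# Deterministic, well-spread unit directions on the hemisphere via the
# Fibonacci lattice; adequate conditioning for a 7-parameter tensor design.
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  rbind(r * cos(phi), r * sin(phi), z)
}

# 26/18/6-neighbourhood integer offsets (excluding the origin).
connectivityOffsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Iterative minimum-label
# propagation over the neighbourhood offsets; returns an integer array with
# 0 outside the foreground and labels 1..k (relabelled consecutively).
labelComponents <- function(fg, connectivity = 26) {
  d <- dim(fg)
  stopifnot(length(d) == 3L)
  lab <- array(0, d)
  lab[fg] <- seq_len(sum(fg))
  offs <- connectivityOffsets(connectivity)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      sh <- lab
      for (ax in 1:3) {
        by <- offs[k, ax]
        if (by != 0) sh <- shiftArray(sh, ax, by, fill = 0)
      }
      upd <- fg & sh > 0 & sh < lab
      if (any(upd)) { lab[upd] <- sh[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  storage.mode(lab) <- "integer"
  lab
}

# Expand the 6 unique tensor components (xx,xy,xz,yy,yz,zz) at one voxel
# into a symmetric 3x3 matrix.
tensorAsMatrix <- function(v6) {
  matrix(c(v6[1], v6[2], v6[3],
           v6[2], v6[4], v6[5],
           v6[3], v6[5], v6[6]), 3, 3)
}

# g' D g for every (voxel, direction): tensors as V x 6 matrix, dirs 3 x n.
tensorQuadForm <- function(t6, dirs) {
  gx <- dirs[1, ]; gy <- dirs[2, ]; gz <- dirs[3, ]
  G <- rbind(gx^2, 2 * gx * gy, 2 * gx * gz, gy^2, 2 * gy * gz, gz^2)
  t6 %*% G
}

# All permutations of 1..n as an (n! x n) matrix, lexicographic order.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    blk <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

# Standard closed forms for eigenvalue-based DTI metrics. Negative
# eigenvalues are clamped at zero first; an all-zero triple gives FA = 0.
faFromEigenvalues <- function(lambda) {
  l <- pmax(lambda, 0)
  if (is.null(dim(l))) l <- matrix(l, nrow = 1)
  md <- rowMeans(l)
  num <- rowSums((l - md)^2)
  den <- rowSums(l^2)
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  pmin(pmax(fa, 0), 1)
}

mdFromEigenvalues <- function(lambda) {
  l <- pmax(lambda, 0)
  if (is.null(dim(l))) l <- matrix(l, nrow = 1)
  rowMeans(l)
}
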