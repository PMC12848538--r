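# Shared fixtures, built in code at test time.

# Small uniform-field phantom realized as tensors.
uniformTensors <- function(grid = c(5, 5, 5), dir = c(0, 0, 1)) {
  f <- makePatternField("uniform", gridShape = grid)
  v <- f@vectors
  for (i in 1:3) v[, , , i] <- dir[i] / sqrt(sum(dir^2))
  f@vectors <- v
  directorsToTensors(f)
}

# Random smooth-ish director field: random unit vectors (worst case for
# smoothness, fine for algebraic identities like the RSS composition).
randomDirectorField <- function(grid = c(7, 7, 4), seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(grid) * 3), c(grid, 3))
  nrm <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  for (i in 1:3) v[, , , i] <- v[, , , i] / nrm
  new("DirectorField", vectors = v, mask = array(TRUE, grid),
      spacing = c(2, 2, 2))
}

# Flip stored director signs at random voxels (gauge transformation).
randomSignFlip <- function(field, seed = 99) {
  set.seed(seed)
  d <- dim(field@vectors)[1:3]
  s <- array(sample(c(-1, 1), prod(d), replace = TRUE), d)
  for (i in 1:3) field@vectors[, , , i] <- field@vectors[, , , i] * s
  field
}

# Rotate a director field grid by 90 degrees about a grid axis: exact
# relabelling of voxels plus rotation of the vector components.
rotateField90 <- function(field, axis) {
  v <- field@vectors
  m <- field@mask
  d <- dim(v)[1:3]
  rot <- switch(axis,
    `1` = function(a) aperm(a, c(1, 3, 2, 4))[, , dim(a)[2]:1, , drop = FALSE],
    `2` = function(a) aperm(a, c(3, 2, 1, 4))[dim(a)[3]:1, , , , drop = FALSE],
    `3` = function(a) aperm(a, c(2, 1, 3, 4))[, dim(a)[1]:1, , , drop = FALSE])
  R <- switch(axis,
    `1` = matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),
    `2` = matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3),
    `3` = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  comps <- lapply(1:3, function(i) rot(v[, , , i, drop = FALSE]))
  dNew <- dim(comps[[1]])[1:3]
  out <- array(0, c(dNew, 3))
  for (i in 1:3)
    out[, , , i] <- R[i, 1] * comps[[1]] + R[i, 2] * comps[[2]] +
      R[i, 3] * comps[[3]]
  new("DirectorField", vectors = out, mask = rot(array(m, c(d, 1)))[, , , 1],
      spacing = field@spacing[switch(axis, `1` = c(1, 3, 2),
                                     `2` = c(3, 2, 1), `3` = c(2, 1, 3))])
}

# Brute-force TFCE oracle: a fine threshold sweep whose connected components
# come from igraph on an explicit voxel-adjacency edge list — an
# implementation path fully independent of the package's label propagation.
gridEdgeList <- function(d, connectivity = 26) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    from <- which(ok)
    to <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    edges <- rbind(edges, cbind(from, to)[from < to, , drop = FALSE])
  }
  unique(edges)
}

tfceBruteForce <- function(stat, E = 0.5, H = 2, nSteps = 1000,
                           connectivity = 26) {
  d <- dim(stat)
  hmax <- max(stat)
  out <- array(0, d)
  if (hmax <= 0) return(out)
  dh <- hmax / nSteps
  edges <- gridEdgeList(d, connectivity)
  sv <- as.vector(stat)
  for (h in seq(dh, hmax, by = dh)) {
    fg <- sv >= h
    if (!any(fg)) break
    keep <- fg[edges[, 1]] & fg[edges[, 2]]
    g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(sv) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    # isolated fg voxels are their own singleton components
    ext <- tabulate(memb[fg] , nbins = max(memb))
    out[fg] <- out[fg] + ext[memb[fg]]^E * h^H * dh
  }
  out
}
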