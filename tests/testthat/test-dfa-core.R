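test_that("director extraction keeps anisotropic, excludes degenerate voxels", {
  d <- c(4, 4, 3)
  vals <- array(0, c(d, 6))
  vals[, , , 1] <- 1.7e-3; vals[, , , 4] <- 0.3e-3; vals[, , , 6] <- 0.3e-3
  # one isotropic voxel
  vals[2, 2, 2, 1] <- 0.7e-3; vals[2, 2, 2, 4] <- 0.7e-3
  vals[2, 2, 2, 6] <- 0.7e-3
  tf <- new("TensorField", values = vals, mask = array(TRUE, d),
            spacing = c(2, 2, 2))
  df <- extractDirectors(tf, faMin = 0.2)
  expect_false(df@mask[2, 2, 2])           # direction undefined: excluded
  expect_true(df@mask[1, 1, 1])
  expect_equal(abs(df@vectors[1, 1, 1, ]), c(1, 0, 0), tolerance = 1e-12)
  # all-isotropic field: empty validity mask is an error
  vals[] <- 0
  vals[, , , c(1, 4, 6)] <- 0.7e-3
  tfIso <- new("TensorField", values = vals, mask = array(TRUE, d),
               spacing = c(2, 2, 2))
  expect_error(extractDirectors(tfIso), "empty mask")
})

test_that("jacobian vanishes on uniform fields regardless of stored signs", {
  f <- makePatternField("uniform", c(6, 6, 4))
  jac <- directorJacobian(f)
  expect_lt(max(abs(jac$J[2:5, 2:5, 2:3, , ])), 1e-15)
  # alternating stored signs: alignment must still give a zero derivative
  fAlt <- f
  s <- array((-1)^(slice.index(f@mask, 1) + slice.index(f@mask, 2)),
             dim(f@mask))
  for (i in 1:3) fAlt@vectors[, , , i] <- f@vectors[, , , i] * s
  jacAlt <- directorJacobian(fAlt)
  expect_lt(max(abs(jacAlt$J)), 1e-15)
  # boundary voxels are flagged; interior voxels are not
  expect_true(all(jac$boundary[1, , ]))
  expect_false(any(jac$boundary[3, 3, 2]))
})

test_that("twist-field derivative magnitude matches the analytic rate", {
  rate <- 0.1; sp <- 2
  f <- makePatternField("twist", c(15, 7, 5), voxelSize = rep(sp, 3),
                        twistRate = rate)
  jac <- directorJacobian(f)
  dn <- sqrt(jac$J[, , , 1, 1]^2 + jac$J[, , , 2, 1]^2 + jac$J[, , , 3, 1]^2)
  interior <- !jac$boundary & jac$defined
  # central chord of a rotating unit vector: sin(rate)/spacing, an O(rate^2)
  # discretization of the analytic rate/spacing
  expect_lt(max(abs(dn[interior] - sin(rate) / sp)), 1e-12)
  expect_lt(abs(mean(dn[interior]) - rate / sp), rate / sp * rate^2 / 5)
  # derivatives along the invariant axes vanish identically
  expect_lt(max(abs(jac$J[, , , , 2][rep(interior, 3)])), 1e-15)
  expect_lt(max(abs(jac$J[, , , , 3][rep(interior, 3)])), 1e-15)
})

test_that("distortion indices are selective on the canonical fields", {
  splayF <- distortionIndices(makePatternField("splay", c(21, 21, 5)))
  bendF <- distortionIndices(makePatternField("bend", c(21, 21, 5)))
  twistF <- distortionIndices(makePatternField("twist", c(21, 7, 5),
                                               twistRate = 0.1))
  uni <- distortionIndices(makePatternField("uniform", c(9, 9, 5)))
  # on-target indices are positive
  expect_gt(mean(splayF@splay[splayF@interior]), 0)
  expect_gt(mean(bendF@bend[bendF@interior]), 0)
  expect_gt(mean(twistF@twist[twistF@interior]), 0)
  # discretely exact zeros: twist on both planar circular fields, and both
  # off-target indices on the twist field
  expect_lt(max(twistF@splay[twistF@interior]), 1e-12)
  expect_lt(max(twistF@bend[twistF@interior]), 1e-12)
  expect_lt(max(splayF@twist[splayF@interior]), 1e-12)
  expect_lt(max(bendF@twist[bendF@interior]), 1e-12)
  # the twist map of the twist field is constant (zero CV) in the interior
  tw <- twistF@twist[twistF@interior]
  expect_lt(stats::sd(tw) / mean(tw), 1e-12)
  # uniform field: every index is zero
  expect_lt(max(uni@total[uni@interior]), 1e-15)
})

test_that("cross-pattern finite-difference residuals shrink as O(h^2)", {
  # bend measured on the splay pattern is zero in the continuum; the
  # discrete residual at a fixed physical radius must drop ~4x when the
  # voxel size is halved against the same continuous pattern
  resAt <- function(grid, sp) {
    f <- makePatternField("splay", c(grid, grid, 3), voxelSize = rep(sp, 3))
    m <- distortionIndices(f)
    ctr <- (grid + 1) / 2
    idx <- which(m@interior[, , 2], arr.ind = TRUE)
    r <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2) * sp
    ring <- r > 8 & r < 12        # physical radius 8-12 mm
    vals <- m@bend[, , 2][m@interior[, , 2]]
    max(vals[ring])
  }
  coarse <- resAt(21, 2)
  fine <- resAt(41, 1)
  expect_gt(coarse / fine, 2.5)
  expect_lt(coarse / fine, 8)
})

test_that("all maps are invariant under voxelwise sign gauge flips", {
  f <- makePatternField("splay", c(11, 11, 3))
  g <- randomSignFlip(f, seed = 4)
  m1 <- distortionIndices(f)
  m2 <- distortionIndices(g)
  for (nm in c("splay", "bend", "twist", "total")) {
    a <- slot(m1, nm); b <- slot(m2, nm)
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-12)
  }
})

test_that("maps are equivariant under exact 90-degree grid rotations", {
  f <- makePatternField("twist", c(9, 8, 7), twistRate = 0.15)
  m <- distortionIndices(f)
  rot3 <- function(a, ax) {
    b <- array(a, c(dim(a), 1))
    b <- switch(ax,
      `1` = aperm(b, c(1, 3, 2, 4))[, , dim(a)[2]:1, , drop = FALSE],
      `2` = aperm(b, c(3, 2, 1, 4))[dim(a)[3]:1, , , , drop = FALSE],
      `3` = aperm(b, c(2, 1, 3, 4))[, dim(a)[1]:1, , , drop = FALSE])
    array(b, dim(b)[1:3])
  }
  for (ax in 1:3) {
    fr <- rotateField90(f, ax)
    mr <- distortionIndices(fr)
    for (nm in c("splay", "bend", "twist", "total")) {
      want <- rot3(slot(m, nm), ax)
      got <- slot(mr, nm)
      ok <- rot3(m@interior, ax) > 0 & mr@interior
      expect_lt(max(abs(want[ok] - got[ok])), 1e-10)
    }
  }
})

test_that("total distortion is the root-sum-square of the components", {
  for (seed in 1:3) {
    f <- randomDirectorField(c(6, 6, 4), seed = seed)
    m <- distortionIndices(f)
    resid <- m@total^2 - (m@splay^2 + m@bend^2 + m@twist^2)
    expect_lt(max(abs(resid[m@defined])), 1e-10)
    td <- totalDistortion(m)
    expect_equal(td@values[m@defined], m@total[m@defined], tolerance = 1e-12)
  }
  # array form and the Pythagorean spot checks
  t3 <- totalDistortion(array(3, c(1, 1, 1)), array(0, c(1, 1, 1)),
                        array(4, c(1, 1, 1)))
  expect_equal(as.numeric(t3@values), 5)
  t0 <- totalDistortion(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)),
                        array(0, c(2, 2, 1)))
  expect_true(all(t0@values == 0))
  expect_error(totalDistortion(array(0, c(2, 2, 1)), array(0, c(3, 2, 1)),
                               array(0, c(2, 2, 1))), "shape")
  # pure splay field: total equals splay voxelwise
  ms <- distortionIndices(makePatternField("splay", c(15, 15, 3)))
  onlySplay <- ms@interior & ms@bend < 1e-14 & ms@twist < 1e-14
  expect_equal(ms@total[onlySplay], ms@splay[onlySplay], tolerance = 1e-12)
})

test_that("frame-variant indices satisfy the same structural identities", {
  f <- makePatternField("twist", c(13, 7, 5), twistRate = 0.1)
  m <- distortionIndices(f, variant = "frame")
  expect_lt(max(m@splay[m@interior]), 1e-12)
  expect_lt(max(m@bend[m@interior]), 1e-12)
  tw <- m@twist[m@interior]
  expect_lt(stats::sd(tw) / mean(tw), 1e-10)
  g <- randomSignFlip(f, seed = 2)
  m2 <- distortionIndices(g, variant = "frame")
  expect_lt(max(abs(m@twist - m2@twist), na.rm = TRUE), 1e-12)
  resid <- m@total^2 - (m@splay^2 + m@bend^2 + m@twist^2)
  expect_lt(max(abs(resid[m@defined])), 1e-10)
})

test_that("per-voxel units rescale indices by the voxel size", {
  f <- makePatternField("twist", c(13, 7, 5), voxelSize = c(2, 2, 2),
                        twistRate = 0.1)
  mm <- distortionIndices(f)
  pv <- distortionIndices(f, perVoxel = TRUE)
  expect_equal(pv@units, "rad/voxel")
  expect_equal(pv@twist[pv@interior], 2 * mm@twist[mm@interior],
               tolerance = 1e-12)
})
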