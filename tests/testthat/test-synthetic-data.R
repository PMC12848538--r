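test_that("pattern fields realize the canonical geometries", {
  # splay: radial; voxel at offset (+3, 0, 0) from center points along +x
  f <- makePatternField("splay", c(21, 21, 5))
  ctr <- c(11, 11)
  expect_equal(as.numeric(f@vectors[ctr[1] + 3, ctr[2], 1, ]), c(1, 0, 0))
  expect_false(f@mask[ctr[1], ctr[2], 3])        # singular center flagged
  expect_true(all(f@mask[-ctr[1], , ]))
  # bend: tangential, perpendicular to the radius
  b <- makePatternField("bend", c(21, 21, 5))
  expect_equal(as.numeric(b@vectors[ctr[1] + 3, ctr[2], 1, ]), c(0, 1, 0))
  # twist: consecutive voxels along x differ by a rotation of `rate` about x
  tw <- makePatternField("twist", c(11, 7, 5), twistRate = 0.1)
  v1 <- tw@vectors[4, 3, 2, ]
  v2 <- tw@vectors[5, 3, 2, ]
  expect_equal(acos(sum(v1 * v2)), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(tw@vectors[1, 1, 1, ]), c(0, 1, 0))
  # pattern replicated across the out-of-plane axis
  expect_equal(f@vectors[, , 1, ], f@vectors[, , 5, ])
  expect_equal(tw@vectors[, , 1, ], tw@vectors[, , 3, ])
})

test_that("directors are unit-norm in-mask for every pattern", {
  for (p in c("splay", "bend", "twist", "uniform")) {
    f <- makePatternField(p, c(9, 9, 5), twistRate = 0.2)
    v <- matrix(f@vectors, ncol = 3)[as.logical(f@mask), ]
    expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-12)
  }
})

test_that("degenerate pattern grids are rejected", {
  expect_error(makePatternField("splay", c(4, 21, 3)), "degenerate")
  expect_error(makePatternField("twist", c(3, 5, 5)), "degenerate")
  expect_silent(makePatternField("uniform", c(2, 2, 2)))
})

test_that("director-to-tensor realization is spectrally exact", {
  f <- makePatternField("uniform", c(3, 3, 3))
  tf <- directorsToTensors(f, 1.7e-3, 0.3e-3)
  # axis-aligned case: diag(perp, perp, par) for the +z uniform director
  expect_equal(as.numeric(tf@values[1, 1, 1, ]),
               c(0.3e-3, 0, 0, 0.3e-3, 0, 1.7e-3), tolerance = 1e-15)
  # arbitrary directors: eigenvalues exactly {par, perp, perp} and the
  # principal eigenvector collinear with the input director
  rf <- randomDirectorField(c(4, 3, 3), seed = 7)
  tf2 <- directorsToTensors(rf, 1.7e-3, 0.3e-3)
  eig <- tensorEigensystem(tf2)
  lam <- matrix(eig@values, ncol = 3)
  expect_lt(max(abs(lam[, 1] - 1.7e-3)), 1e-17)
  expect_lt(max(abs(lam[, 2] - 0.3e-3)), 1e-17)
  expect_lt(max(abs(lam[, 3] - 0.3e-3)), 1e-17)
  e1 <- matrix(eig@vectors[, , , , 1], ncol = 3)
  n <- matrix(rf@vectors, ncol = 3)
  cosines <- abs(rowSums(e1 * n))
  expect_true(all(cosines >= 1 - 1e-10))
})

test_that("non-unit directors are rejected by the tensor realization", {
  f <- makePatternField("uniform", c(3, 3, 3))
  f@vectors[1, 1, 1, ] <- c(2, 0, 0)
  expect_error(directorsToTensors(f), "unit norm")
  expect_error(directorsToTensors(makePatternField("uniform", c(3, 3, 3)),
                                  lambdaParallel = 1e-4, lambdaPerp = 3e-4),
               "lambdaParallel")
})

test_that("FA of the default tensor matches the closed form", {
  # independent closed-form evaluation for (1.7, 0.3, 0.3)e-3:
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  faRef <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  tf <- directorsToTensors(makePatternField("uniform", c(3, 3, 3)))
  sm <- scalarMaps(tensorEigensystem(tf))
  expect_equal(sm$FA@values[2, 2, 2], faRef, tolerance = 1e-12)
  expect_equal(faRef, 0.7990, tolerance = 1e-4)
  expect_equal(sm$MD@values[2, 2, 2], mean(lam), tolerance = 1e-15)
})

test_that("noiseless diffusion signal follows the single-tensor decay", {
  f <- makePatternField("uniform", c(3, 3, 3))
  v <- f@vectors; v[, , , 3] <- 0; v[, , , 1] <- 1   # director along +x
  f@vectors <- v
  tf <- directorsToTensors(f, 1.7e-3, 0.3e-3)
  gt <- gradientTable(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  dwi <- simulateDWI(tf, gt, s0 = 1000, noiseSigma = 0)
  expect_equal(dwi@data[2, 2, 2, 2], 1000 * exp(-1.7), tolerance = 1e-12)
  expect_equal(1000 * exp(-1.7), 182.684, tolerance = 1e-5)
  expect_equal(dwi@data[2, 2, 2, 1], 1000)            # b=0 volume: exactly S0
})

test_that("Rician simulation is seed-deterministic and validates sigma", {
  tf <- directorsToTensors(makePatternField("uniform", c(4, 4, 3)))
  d1 <- simulateDWI(tf, s0 = 500, noiseSigma = 12, seed = 42)
  d2 <- simulateDWI(tf, s0 = 500, noiseSigma = 12, seed = 42)
  d3 <- simulateDWI(tf, s0 = 500, noiseSigma = 12, seed = 43)
  expect_identical(d1@data, d2@data)
  expect_false(identical(d1@data, d3@data))
  expect_true(all(d1@data > 0))                       # magnitude signal
  expect_error(simulateDWI(tf, noiseSigma = -1), "non-negative")
})

test_that("synthetic atlas has the requested disjoint nonempty regions", {
  atl <- makeAtlasLabels(48, c(24, 24, 12), seed = 1)
  labs <- atl$labels[atl$labels > 0]
  expect_identical(sort(unique(labs)), 1:48)
  expect_true(all(tabulate(labs, 48) >= 8))
  expect_length(atl$names, 48)
  expect_identical(atl$mask, atl$labels > 0L)
  # seeded assignment is reproducible; different nRois work
  atl2 <- makeAtlasLabels(48, c(24, 24, 12), seed = 1)
  expect_identical(atl$labels, atl2$labels)
  atl7 <- makeAtlasLabels(7, c(14, 6, 5), seed = 3)
  expect_identical(sort(unique(as.vector(atl7$labels[atl7$labels > 0]))), 1:7)
  expect_error(makeAtlasLabels(48, c(4, 4, 2)), "too small")
})

test_that("jhu-style tract list has 48 unique names in both forms", {
  expect_length(unique(jhuTractNames()), 48)
  expect_length(unique(jhuTractNames(abbreviated = TRUE)), 48)
})

test_that("cohort generator honours group sizes, labels and covariates", {
  co <- makeCohort(groups = c(HC = 33, FP = 50), nRois = 6,
                   metrics = c("FA", "MD"), seed = 2)
  tab <- table(cohortSubjects(co)$group)
  expect_identical(as.integer(tab[c("HC", "FP")]), c(33L, 50L))
  expect_identical(ncol(cohortFeatures(co)), 12L)
  expect_true(all(cohortSubjects(co)$sex %in% 0:1))
  expect_error(makeCohort(groups = c(A = 1, B = 10)), "at least 2")
  expect_error(makeCohort(groups = c(A = 5, B = 5), nRois = 2,
                          clinicalTargets = list(s = list(roi = 1,
                                                          metric = "FA",
                                                          rho = 1.2))),
               "\\[-1, 1\\]")
})

test_that("clinical-score copula hits the target Spearman association", {
  co <- makeCohort(groups = c(FP = 200), nRois = 2, metrics = c("FA", "MD"),
                   clinicalTargets = list(
                     TFGS = list(roi = 1, metric = "FA", rho = 0.8,
                                 mean = 18.6, sd = 17.2)),
                   seed = 11)
  r <- spearmanTest(cohortFeatures(co)[, "ROI01.FA"],
                    cohortScores(co)[, "TFGS"])
  expect_lt(abs(r$rho - 0.8), 0.1)
  # negative target, different metric
  co2 <- makeCohort(groups = c(FP = 200), nRois = 2, metrics = c("FA", "MD"),
                    clinicalTargets = list(
                      s = list(roi = 2, metric = "MD", rho = -0.6)),
                    seed = 12)
  r2 <- spearmanTest(cohortFeatures(co2)[, "ROI02.MD"],
                     cohortScores(co2)[, "s"])
  expect_lt(abs(r2$rho + 0.6), 0.1)
  # score restricted to one group: others NA
  co3 <- makeCohort(groups = c(FP = 10, HC = 10), nRois = 1,
                    metrics = "FA",
                    clinicalTargets = list(
                      s = list(roi = 1, metric = "FA", rho = 0.5,
                               groups = "FP")),
                    seed = 13)
  expect_identical(sum(is.na(cohortScores(co3)[, "s"])), 10L)
})

test_that("null cohorts give nominal per-ROI type-I error", {
  set.seed(31)
  nRep <- 400
  rej <- mean(replicate(nRep, {
    co <- makeCohort(groups = c(A = 10, B = 10), nRois = 1, metrics = "FA",
                     seed = sample.int(1e6, 1))
    f <- cohortFeatures(co)[, 1]
    g <- cohortSubjects(co)$group
    t.test(f[g == "A"], f[g == "B"])$p.value < 0.05
  }))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nRep)
  expect_gt(rej, ci[1])
  expect_lt(rej, ci[2])
})

test_that("prescribed effects shift group means as specified", {
  eff <- data.frame(group = "B", roi = 2, metric = "FA", delta = 0.8)
  co <- makeCohort(groups = c(A = 500, B = 500), nRois = 3, metrics = "FA",
                   effects = eff, seed = 21)
  f <- cohortFeatures(co)
  g <- cohortSubjects(co)$group
  dObs <- mean(f[g == "B", "ROI02.FA"]) - mean(f[g == "A", "ROI02.FA"])
  se <- sqrt(1 / 500 + 1 / 500)
  expect_lt(abs(dObs - 0.8), 3 * se)
  dNull <- mean(f[g == "B", "ROI01.FA"]) - mean(f[g == "A", "ROI01.FA"])
  expect_lt(abs(dNull), 3 * se)
})
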