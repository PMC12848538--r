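test_that("feature sets have the documented cardinalities", {
  co <- makeCohort(groups = c(HC = 4, FP = 4), nRois = 48, seed = 1)
  expect_identical(ncol(assembleFeatures(co, "FA_MD")@x), 96L)
  expect_identical(ncol(assembleFeatures(co, "DFA")@x), 192L)
  expect_identical(ncol(assembleFeatures(co, "ALL")@x), 288L)
  # column order is ROI-major, metric-minor
  cols <- colnames(assembleFeatures(co, "FA_MD")@x)
  expect_identical(cols[1:4], c("MCP.FA", "MCP.MD", "PCT.FA", "PCT.MD"))
  # a cohort without DFA metrics cannot assemble the DFA set
  co2 <- makeCohort(groups = c(HC = 4, FP = 4), nRois = 3,
                    metrics = c("FA", "MD"), seed = 1)
  expect_error(assembleFeatures(co2, "DFA"), "missing feature columns")
  # group subsetting drops unused levels
  co3 <- makeCohort(groups = c(HC = 4, FP = 4, MS = 4), nRois = 2,
                    metrics = c("FA", "MD"), seed = 2)
  fm <- assembleFeatures(co3, "FA_MD", groups = c("HC", "FP"))
  expect_identical(nlevels(fm@labels), 2L)
  expect_identical(nrow(fm@x), 8L)
})

test_that("stratified folds partition subjects with balanced classes", {
  labels <- factor(rep(c("FP", "HC"), c(50, 33)))
  folds <- cvSplit(labels, k = 10, seed = 5)
  expect_length(folds, 10)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))          # union = everyone
  expect_identical(anyDuplicated(unlist(folds)), 0L)    # pairwise disjoint
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(8, 9)))
  for (f in folds) {
    tab <- table(labels[f])
    expect_true(all(tab >= 1))                          # both classes present
    expect_true(abs(tab["FP"] - 5) <= 1 && abs(tab["HC"] - 3.3) <= 1)
  }
  expect_identical(folds, cvSplit(labels, k = 10, seed = 5))  # seeded
  expect_false(identical(folds, cvSplit(labels, k = 10, seed = 6)))
  expect_error(cvSplit(labels, k = 1), "at least 2")
  expect_warning(cvSplit(factor(rep(c("a", "b"), c(3, 20))), k = 10),
                 "reducing k")
})

test_that("ensemble probabilities are calibrated rows summing to one", {
  set.seed(40)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 4, 0), ncol = 4),
             matrix(rnorm(n / 2 * 4, 6), ncol = 4))   # separable, d = 6
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("A", "B"), each = n / 2))
  tr <- c(1:20, 31:50); te <- c(21:30, 51:60)
  pr <- fitPredictEnsemble(x[tr, ], y[tr], x[te, ])
  expect_true(all(pr >= 0 & pr <= 1))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)
  expect_identical(colnames(pr), c("A", "B"))
  # separable classes: held-out prediction is perfect
  pred <- colnames(pr)[apply(pr, 1, which.max)]
  expect_identical(pred, as.character(y[te]))
  expect_error(fitPredictEnsemble(x[1:10, ], y[1:10], x[te, ]),
               "single class")
})

test_that("feature standardization never uses test-fold information", {
  set.seed(41)
  x <- matrix(rnorm(40 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("A", "B"), each = 20))
  xTest <- matrix(rnorm(6 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  set.seed(100)
  p1 <- fitPredictEnsemble(x, y, xTest)
  xOut <- xTest
  xOut[6, ] <- xOut[6, ] + 1e6              # test-only outlier
  set.seed(100)
  p2 <- fitPredictEnsemble(x, y, xOut)
  # predictions for untouched test rows are identical: scaling statistics
  # came from the training fold only
  expect_equal(p1[1:5, ], p2[1:5, ], tolerance = 1e-12)
})

test_that("separable cohorts reach AUC 1 and ROC averaging is monotone", {
  co <- makeCohort(groups = c(HC = 20, FP = 20), nRois = 4,
                   metrics = c("FA", "MD"),
                   effects = data.frame(group = "FP", roi = 1, metric = "FA",
                                        delta = 6),
                   seed = 42)
  cv <- crossValidate(assembleFeatures(co, "FA_MD"), k = 10, seed = 7)
  expect_length(cv, 10)
  roc <- foldAveragedRoc(cv, "FP")
  expect_equal(roc$auc, 1)
  expect_true(all(roc$foldAuc == 1))
  expect_true(all(diff(roc$meanTpr) >= 0))              # nondecreasing
  expect_length(roc$fprGrid, 101)
  # per-fold AUC cross-check against an independent implementation
  skip_if_not_installed("pROC")
  f1 <- cv[[1]]
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = f1$truth == "FP", predictor = f1$prob[, "FP"], quiet = TRUE)))
  expect_equal(roc$foldAuc[1], as.numeric(ref), tolerance = 1e-12)
})

test_that("the cross-validation chain is bit-reproducible under a seed", {
  co <- makeCohort(groups = c(HC = 12, FP = 12), nRois = 2,
                   metrics = c("FA", "MD"), seed = 3)
  fm <- assembleFeatures(co, "FA_MD")
  cv1 <- crossValidate(fm, k = 4, seed = 11)
  cv2 <- crossValidate(fm, k = 4, seed = 11)
  expect_identical(lapply(cv1, `[[`, "prob"), lapply(cv2, `[[`, "prob"))
  r1 <- foldAveragedRoc(cv1, "FP"); r2 <- foldAveragedRoc(cv2, "FP")
  expect_identical(r1$auc, r2$auc)
})

test_that("label-permuted cohorts score near-chance AUC", {
  set.seed(43)
  aucs <- vapply(1:8, function(s) {
    co <- makeCohort(groups = c(HC = 20, FP = 20), nRois = 3,
                     metrics = c("FA", "MD"), seed = 1000 + s)
    fm <- assembleFeatures(co, "FA_MD")
    fm@labels <- sample(fm@labels)           # break any label-feature link
    foldAveragedRoc(crossValidate(fm, k = 5, seed = s), "FP")$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("confusion matrices pool folds with argmax predictions", {
  co <- makeCohort(groups = c(HC = 12, FP = 12, MS = 12), nRois = 3,
                   metrics = c("FA", "MD"),
                   effects = data.frame(group = c("FP", "MS"),
                                        roi = c(1, 2),
                                        metric = c("FA", "FA"),
                                        delta = c(8, -8)),
                   seed = 44)
  cv <- crossValidate(assembleFeatures(co, "FA_MD"), k = 4, seed = 9)
  cm <- multiclassConfusion(cv, classOrder = c("HC", "FP", "MS"))
  expect_identical(rownames(cm), c("HC", "FP", "MS"))
  expect_identical(as.integer(rowSums(cm)), c(12L, 12L, 12L))
  expect_identical(sum(diag(cm)), 36L)      # fully separable 3-class toy
  # constructed toy: one forced misassignment lands in the known cell
  folds <- list(list(fold = 1L, testIds = c("s1", "s2", "s3"),
                     prob = rbind(c(A = 1, B = 0, C = 0),
                                  c(A = 0, B = 0.2, C = 0.8),
                                  c(A = 0, B = 0, C = 1)),
                     truth = factor(c("A", "B", "C"),
                                    levels = c("A", "B", "C"))))
  cm2 <- multiclassConfusion(folds, classOrder = c("A", "B", "C"))
  expect_identical(cm2["B", "C"], 1L)
  expect_identical(sum(cm2) - sum(diag(cm2)), 1L)
  # argmax ties break toward the lexicographically first class
  foldsTie <- list(list(fold = 1L, testIds = "s1",
                        prob = rbind(c(B = 0.5, A = 0.5)),
                        truth = factor("A", levels = c("A", "B"))))
  cmT <- multiclassConfusion(foldsTie)
  expect_identical(cmT["A", "A"], 1L)
})

test_that("folds lacking a class are skipped with a warning in ROC", {
  folds <- list(
    list(fold = 1L, testIds = c("a", "b"),
         prob = rbind(c(A = 0.9, B = 0.1), c(A = 0.2, B = 0.8)),
         truth = factor(c("A", "B"), levels = c("A", "B"))),
    list(fold = 2L, testIds = c("c", "d"),
         prob = rbind(c(A = 0.9, B = 0.1), c(A = 0.8, B = 0.2)),
         truth = factor(c("A", "A"), levels = c("A", "B"))))
  expect_warning(r <- foldAveragedRoc(folds, "B"), "lacks one class")
  expect_identical(r$nFoldsUsed, 1L)
})
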