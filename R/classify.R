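#' Assemble ROI features for classification
#'
#' Builds the subjects-by-features matrix for one of the three feature sets:
#' `"FA_MD"` (n_rois x 2 features), `"DFA"` (n_rois x 4: splay, bend, twist,
#' total distortion) or `"ALL"` (n_rois x 6). With the default 48-region
#' atlas these are 96, 192 and 288 features. Column order is deterministic:
#' ROI-major, metric-minor.
#'
#' @param cohort a [CohortTable-class].
#' @param featureSet "FA_MD", "DFA" or "ALL".
#' @param groups optional subset of group labels to keep.
#' @return a [FeatureMatrix-class].
#' @examples
#' co <- makeCohort(groups = c(HC = 5, FP = 5), nRois = 48, seed = 1)
#' ncol(assembleFeatures(co, "FA_MD")@x)   # 96
#' @export
assembleFeatures <- function(cohort, featureSet = c("FA_MD", "DFA", "ALL"),
                             groups = NULL) {
  featureSet <- match.arg(featureSet)
  stopifnot(is(cohort, "CohortTable"))
  metrics <- switch(featureSet,
                    FA_MD = c("FA", "MD"),
                    DFA = c("splay", "bend", "twist", "total_distortion"),
                    ALL = c("FA", "MD", "splay", "bend", "twist",
                            "total_distortion"))
  cols <- as.vector(t(outer(cohort@roiNames, metrics, paste, sep = ".")))
  missing <- setdiff(cols, colnames(cohort@features))
  if (length(missing))
    stop("missing feature columns: ", paste(utils::head(missing, 4),
                                            collapse = ", "))
  keep <- if (is.null(groups)) rep(TRUE, nrow(cohort@subjects))
          else cohort@subjects$group %in% groups
  if (!any(keep)) stop("no subjects in the requested groups")
  labels <- factor(cohort@subjects$group[keep])
  new("FeatureMatrix", x = cohort@features[keep, cols, drop = FALSE],
      labels = droplevels(labels),
      subjectIds = cohort@subjects$subject_id[keep],
      featureSet = featureSet)
}

#' Stratified k-fold split
#'
#' Subjects are partitioned into `k` disjoint test folds; within each class,
#' shuffled members are dealt round-robin so per-fold class counts differ by
#' at most one from proportionality. If some class has fewer than `k`
#' members, `k` is reduced to the smallest class size with a warning.
#'
#' @param labels factor (or vector) of class labels.
#' @param k number of folds (default 10).
#' @param seed RNG seed; the same seed yields identical folds.
#' @return list of integer vectors (test indices per fold).
#' @export
cvSplit <- function(labels, k = 10, seed = NULL) {
  labels <- as.factor(labels)
  if (k < 2) stop("k must be at least 2")
  minClass <- min(table(labels))
  if (minClass < k) {
    warning("smallest class has ", minClass, " members; reducing k")
    k <- max(2L, as.integer(minClass))
  }
  withSeed(seed, {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)   # stagger so small classes spread out
    }
    lapply(seq_len(k), function(f) which(fold == f))
  })
}

#' Fit the ensemble on training data and predict class probabilities
#'
#' Features are standardized with training-fold statistics only (no
#' information from the test fold leaks into the scaling). Each roster
#' model produces calibrated class probabilities on the test rows and the
#' ensemble output is their unweighted mean. The default roster is an
#' L2-regularized multinomial logistic regression, a 100-tree random
#' forest, and an RBF-kernel SVM with probability calibration.
#'
#' @param xTrain,xTest numeric matrices with identical column names.
#' @param yTrain factor of training labels (>= 2 classes present).
#' @param roster subset of c("logistic", "forest", "svm").
#' @param decay L2 penalty for the logistic model.
#' @param nTree trees in the forest.
#' @return matrix (test rows x classes) of probabilities; rows sum to 1.
#' @export
fitPredictEnsemble <- function(xTrain, yTrain, xTest,
                               roster = c("logistic", "forest", "svm"),
                               decay = 0.01, nTree = 100) {
  roster <- match.arg(roster, several.ok = TRUE)
  yTrain <- droplevels(as.factor(yTrain))
  if (nlevels(yTrain) < 2) stop("training fold contains a single class")
  if (!identical(colnames(xTrain), colnames(xTest)))
    stop("train/test feature names differ")
  mu <- colMeans(xTrain)
  sdv <- apply(xTrain, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  zTrain <- sweep(sweep(xTrain, 2, mu), 2, sdv, `/`)
  zTest <- sweep(sweep(xTest, 2, mu), 2, sdv, `/`)
  classes <- levels(yTrain)
  probs <- vector("list", length(roster))
  names(probs) <- roster
  dfTrain <- as.data.frame(zTrain)
  colnames(dfTrain) <- paste0("f", seq_len(ncol(zTrain)))
  dfTest <- as.data.frame(zTest)
  colnames(dfTest) <- colnames(dfTrain)
  if ("logistic" %in% roster) {
    fit <- nnet::multinom(y ~ ., data = cbind(y = yTrain, dfTrain),
                          decay = decay, trace = FALSE, maxit = 200,
                          MaxNWts = 100000)
    pr <- stats::predict(fit, dfTest, type = "probs")
    if (is.null(dim(pr)))   # two-class: vector of P(second level)
      pr <- cbind(1 - pr, pr, deparse.level = 0)
    colnames(pr) <- classes
    probs$logistic <- pr
  }
  if ("forest" %in% roster) {
    fit <- randomForest::randomForest(zTrain, yTrain, ntree = nTree)
    probs$forest <- stats::predict(fit, zTest, type = "prob")[, classes,
                                                             drop = FALSE]
  }
  if ("svm" %in% roster) {
    fit <- e1071::svm(zTrain, yTrain, kernel = "radial", probability = TRUE)
    pr <- attr(stats::predict(fit, zTest, probability = TRUE),
               "probabilities")
    probs$svm <- pr[, classes, drop = FALSE]
  }
  out <- Reduce(`+`, probs) / length(probs)
  out <- out / rowSums(out)
  rownames(out) <- NULL
  out
}

#' Stratified cross-validated ensemble classification
#'
#' Runs [cvSplit] + [fitPredictEnsemble] over all folds.
#'
#' @param features a [FeatureMatrix-class].
#' @param k folds (default 10).
#' @param seed RNG seed controlling both the split and the stochastic
#'   models; fixed seeds make the whole chain reproducible.
#' @param roster passed to [fitPredictEnsemble].
#' @return list of fold results, each with `fold`, `testIds`, `prob`
#'   (matrix), `truth` (factor).
#' @export
crossValidate <- function(features, k = 10, seed = NULL,
                          roster = c("logistic", "forest", "svm")) {
  stopifnot(is(features, "FeatureMatrix"))
  folds <- cvSplit(features@labels, k = k, seed = seed)
  withSeed(if (is.null(seed)) NULL else seed + 1L, {
    lapply(seq_along(folds), function(f) {
      test <- folds[[f]]
      train <- setdiff(seq_along(features@labels), test)
      prob <- fitPredictEnsemble(features@x[train, , drop = FALSE],
                                 features@labels[train],
                                 features@x[test, , drop = FALSE],
                                 roster = roster)
      list(fold = f, testIds = features@subjectIds[test], prob = prob,
           truth = droplevels(features@labels[test]))
    })
  })
}

# Empirical ROC points of one fold: step curve through (FPR, TPR) pairs at
# every distinct score threshold, anchored at (0,0) and (1,1).
rocPoints <- function(score, truth, positiveClass) {
  pos <- truth == positiveClass
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  uniq <- !duplicated(score[ord], fromLast = TRUE)  # collapse score ties
  tpr <- c(0, tp[uniq] / sum(pos))
  fpr <- c(0, fp[uniq] / sum(!pos))
  list(fpr = fpr, tpr = tpr)
}

# Trapezoid area under a piecewise-linear curve.
trapezoidAuc <- function(x, y) {
  ord <- order(x)
  sum(diff(x[ord]) * (utils::head(y[ord], -1) + utils::tail(y[ord], -1)) / 2)
}

#' Fold-averaged ROC curve and AUC
#'
#' Computes each fold's empirical ROC from its predicted probabilities,
#' interpolates the true positive rate onto a common 101-point false
#' positive rate grid, and averages vertically across folds. The summary
#' AUC is the trapezoid area under the averaged curve; per-fold AUCs are
#' kept alongside. Folds whose test set lacks one of the classes cannot
#' contribute a curve and are skipped with a warning.
#'
#' @param folds result of [crossValidate] (binary task).
#' @param positiveClass label treated as positive.
#' @param method `"interpolation"` (default): vertical averaging — each
#'   fold's empirical ROC is interpolated onto a fixed 101-point FPR grid
#'   and the TPR is averaged per grid point. `"threshold"`: point-pair
#'   averaging — TPR and FPR are both evaluated at a common 101-point
#'   probability-threshold grid and averaged as (FPR, TPR) pairs.
#' @return list with `fprGrid`, `meanTpr` (and `meanFpr` for the threshold
#'   mode), `auc`, `foldAuc`, `nFoldsUsed`.
#' @export
foldAveragedRoc <- function(folds, positiveClass,
                            method = c("interpolation", "threshold")) {
  method <- match.arg(method)
  grid <- seq(0, 1, length.out = 101)
  curves <- list()
  fprCurves <- list()
  aucs <- numeric(0)
  for (f in folds) {
    if (!positiveClass %in% colnames(f$prob))
      stop("positive class not among predicted classes")
    truth <- as.character(f$truth)
    if (length(unique(truth)) < 2) {
      warning("fold ", f$fold, " lacks one class in its test set; skipped")
      next
    }
    sc <- f$prob[, positiveClass]
    rp <- rocPoints(sc, truth, positiveClass)
    if (method == "interpolation") {
      # the empirical ROC is a right-continuous step curve; constant
      # interpolation from the upper corner of each vertical segment
      # reproduces it exactly on the grid
      tprG <- stats::approx(rp$fpr, rp$tpr, xout = grid, method = "constant",
                            f = 0, ties = max, rule = 2)$y
      curves[[length(curves) + 1L]] <- tprG
    } else {
      pos <- truth == positiveClass
      thr <- rev(grid)
      tprT <- vapply(thr, function(t) mean(sc[pos] >= t), numeric(1))
      fprT <- vapply(thr, function(t) mean(sc[!pos] >= t), numeric(1))
      curves[[length(curves) + 1L]] <- tprT
      fprCurves[[length(fprCurves) + 1L]] <- fprT
    }
    aucs <- c(aucs, trapezoidAuc(rp$fpr, rp$tpr))
  }
  if (!length(curves)) stop("no usable folds for ROC averaging")
  meanTpr <- Reduce(`+`, curves) / length(curves)
  if (method == "interpolation") {
    meanTpr <- cummax(meanTpr)   # guard against interpolation jitter
    out <- list(fprGrid = grid, meanTpr = meanTpr,
                auc = trapezoidAuc(grid, meanTpr))
  } else {
    meanFpr <- Reduce(`+`, fprCurves) / length(fprCurves)
    auc <- trapezoidAuc(c(0, meanFpr, 1), c(0, meanTpr, 1))
    out <- list(fprGrid = meanFpr, meanFpr = meanFpr, meanTpr = meanTpr,
                auc = auc)
  }
  c(out, list(foldAuc = aucs, nFoldsUsed = length(curves)))
}

#' Pooled multiclass confusion matrix
#'
#' Predictions are the argmax of the ensemble probabilities (ties broken
#' toward the lexicographically first class); rows are true classes, columns
#' predicted, pooled over all test folds, so row sums equal per-class test
#' counts.
#'
#' @param folds result of [crossValidate].
#' @param classOrder optional class ordering for rows/columns.
#' @return integer matrix (true x predicted).
#' @export
multiclassConfusion <- function(folds, classOrder = NULL) {
  truth <- unlist(lapply(folds, function(f) as.character(f$truth)))
  pred <- unlist(lapply(folds, function(f) {
    cls <- colnames(f$prob)
    apply(f$prob, 1, function(p) {
      best <- which(p == max(p))
      sort(cls[best])[1]
    })
  }))
  if (is.null(classOrder)) classOrder <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = classOrder),
               factor(pred, levels = classOrder))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("true", "predicted")
  m
}
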