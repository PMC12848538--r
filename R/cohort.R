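# Table-1-style demographics used when the caller does not supply a
# covariate model: per-group age mean/SD and proportion of female subjects.
defaultCovariateModel <- function(groups) {
  known <- data.frame(
    group = c("FP", "HFS", "MS", "HC"),
    ageMean = c(40.9, 51.1, 58.3, 46.6),
    ageSD = c(15.3, 10.4, 9.6, 14.5),
    propFemale = c(32 / 50, 45 / 57, 23 / 31, 20 / 33),
    stringsAsFactors = FALSE)
  out <- data.frame(group = groups, ageMean = 50, ageSD = 10,
                    propFemale = 0.5, stringsAsFactors = FALSE)
  m <- match(groups, known$group)
  hit <- !is.na(m)
  out[hit, c("ageMean", "ageSD", "propFemale")] <-
    known[m[hit], c("ageMean", "ageSD", "propFemale")]
  out
}

#' Generate a synthetic multi-group ROI-feature cohort
#'
#' Draws per-subject (ROI, metric) features as
#' `group shift + standard Gaussian noise`, so prescribed effects are in
#' units of the within-group SD. Age and sex follow a per-group covariate
#' model (defaults emulate a facial-movement-disorder case-control study:
#' FP/HFS/MS patient groups and healthy controls). Clinical scores are
#' generated through a Gaussian copula against the normal scores of the
#' feature they track, followed by a strictly monotone (rank-preserving)
#' affine transform, so the population Spearman correlation equals the
#' requested target: the copula correlation is set to
#' `2 * sin(pi * rho / 6)`, the bivariate-normal inverse of Spearman's rho.
#'
#' @param groups named integer vector: subjects per group, e.g.
#'   `c(FP = 50, HFS = 57, MS = 31, HC = 33)`.
#' @param nRois number of ROI regions (default 48).
#' @param metrics metric names per ROI.
#' @param effects `NULL` (no group differences) or a data.frame with columns
#'   `group`, `roi`, `metric`, `delta` giving mean shifts in within-group SD
#'   units. `roi` may be an index or a name.
#' @param covariates `NULL` or a data.frame with columns `group`, `ageMean`,
#'   `ageSD`, `propFemale`.
#' @param clinicalTargets `NULL` or a named list, one element per clinical
#'   score: `list(roi =, metric =, rho =, groups = NULL, mean =, sd =)`.
#'   `rho` is the target population Spearman association with the tracked
#'   feature; `groups` restricts the score to some groups (others get `NA`).
#' @param roiNames optional ROI names (default [jhuTractNames] codes for 48).
#' @param seed RNG seed.
#' @return a [CohortTable-class].
#' @examples
#' co <- makeCohort(groups = c(HC = 10, FP = 10), nRois = 4,
#'                  metrics = c("FA", "MD"), seed = 1)
#' table(cohortSubjects(co)$group)
#' @export
makeCohort <- function(groups = c(FP = 50, HFS = 57, MS = 31, HC = 33),
                       nRois = 48,
                       metrics = c("FA", "MD", "splay", "bend", "twist",
                                   "total_distortion"),
                       effects = NULL, covariates = NULL,
                       clinicalTargets = NULL, roiNames = NULL,
                       seed = NULL) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named vector of subject counts")
  if (any(groups < 2)) stop("every group needs at least 2 subjects")
  nRois <- as.integer(nRois)
  stopifnot(nRois >= 1, length(metrics) >= 1)
  if (is.null(roiNames)) {
    roiNames <- if (nRois == 48L) jhuTractNames(abbreviated = TRUE)
                else sprintf("ROI%02d", seq_len(nRois))
  }
  stopifnot(length(roiNames) == nRois)
  if (!is.null(clinicalTargets)) {
    bad <- vapply(clinicalTargets, function(t) abs(t$rho) > 1, logical(1))
    if (any(bad)) stop("target Spearman association must lie in [-1, 1]")
  }
  n <- sum(groups)
  group <- factor(rep(names(groups), groups), levels = names(groups))
  cov <- if (is.null(covariates)) defaultCovariateModel(names(groups))
         else covariates
  withSeed(seed, {
    m <- match(as.character(group), cov$group)
    age <- stats::rnorm(n, cov$ageMean[m], cov$ageSD[m])
    sex <- stats::rbinom(n, 1, cov$propFemale[m])   # 1 = female
    featNames <- as.vector(t(outer(roiNames, metrics, paste, sep = ".")))
    X <- matrix(stats::rnorm(n * length(featNames)), n,
                dimnames = list(NULL, featNames))
    if (!is.null(effects)) {
      for (i in seq_len(nrow(effects))) {
        roi <- effects$roi[i]
        roiName <- if (is.numeric(roi)) roiNames[roi] else as.character(roi)
        col <- paste(roiName, effects$metric[i], sep = ".")
        if (!col %in% featNames)
          stop("unknown (roi, metric) in effects: ", col)
        rows <- group == effects$group[i]
        X[rows, col] <- X[rows, col] + effects$delta[i]
      }
    }
    scores <- matrix(NA_real_, n, length(clinicalTargets),
                     dimnames = list(NULL, names(clinicalTargets)))
    for (sc in names(clinicalTargets)) {
      t <- clinicalTargets[[sc]]
      rows <- if (is.null(t$groups)) rep(TRUE, n)
              else group %in% t$groups
      col <- paste(if (is.numeric(t$roi)) roiNames[t$roi] else t$roi,
                   t$metric, sep = ".")
      if (!col %in% featNames)
        stop("unknown tracked feature for score ", sc, ": ", col)
      ns <- sum(rows)
      # Gaussian copula on the normal scores of the tracked feature
      zf <- stats::qnorm((rank(X[rows, col]) - 0.5) / ns)
      rhoP <- 2 * sin(pi * t$rho / 6)
      zs <- rhoP * zf + sqrt(1 - rhoP^2) * stats::rnorm(ns)
      mu <- if (is.null(t$mean)) 0 else t$mean
      sdv <- if (is.null(t$sd)) 1 else t$sd
      scores[rows, sc] <- mu + sdv * zs
    }
    subjects <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = group, age = age, sex = sex,
      stringsAsFactors = FALSE)
    new("CohortTable", subjects = subjects, features = X, scores = scores,
        roiNames = roiNames, metricNames = metrics)
  })
}

setMethod("show", "CohortTable", function(object) {
  tab <- table(object@subjects$group)
  cat("CohortTable:", nrow(object@subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  cat(" ", length(object@roiNames), "ROIs x",
      length(object@metricNames), "metrics =",
      ncol(object@features), "features;",
      ncol(object@scores), "clinical scores\n")
})

#' Write / read a cohort as TSV
#'
#' Flat layout: `subject_id`, `group`, `age`, `sex`, one column per clinical
#' score, then one column per (ROI, metric) feature named `<roi>.<metric>`.
#'
#' @param cohort a [CohortTable-class].
#' @param path output file.
#' @return `writeCohort` invisibly returns `path`; `readCohort` returns a
#'   [CohortTable-class].
#' @export
writeCohort <- function(cohort, path) {
  df <- cbind(cohort@subjects,
              as.data.frame(cohort@scores, optional = TRUE),
              as.data.frame(cohort@features, optional = TRUE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @param metricNames metric names used to recognise feature columns.
#' @export
readCohort <- function(path, metricNames = c("FA", "MD", "splay", "bend",
                                             "twist", "total_distortion")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("subject_id", "group", "age", "sex")
  if (!all(fixed %in% names(df)))
    stop("cohort file must have subject_id, group, age, sex columns")
  pat <- paste0("\\.(", paste(metricNames, collapse = "|"), ")$")
  featCols <- setdiff(grep(pat, names(df), value = TRUE), fixed)
  scoreCols <- setdiff(names(df), c(fixed, featCols))
  rois <- unique(sub(pat, "", featCols))
  metrics <- metricNames[metricNames %in%
                           unique(sub(".*\\.", "", featCols))]
  want <- as.vector(t(outer(rois, metrics, paste, sep = ".")))
  if (!all(want %in% featCols))
    stop("feature columns do not form a complete (ROI, metric) grid")
  subjects <- df[fixed]
  subjects$group <- factor(subjects$group, levels = unique(subjects$group))
  scores <- if (length(scoreCols)) as.matrix(df[scoreCols])
            else matrix(NA_real_, nrow(df), 0)
  new("CohortTable", subjects = subjects,
      features = as.matrix(df[want]),
      scores = scores,
      roiNames = rois, metricNames = metrics)
}
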