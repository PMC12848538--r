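#' Spearman rank correlation with exact small-sample p-values
#'
#' Rho is the Pearson correlation of midranks (average ranks for ties). The
#' p-value is exact for n <= `exactMax` (two-sided, by enumeration of all
#' rank permutations) and uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom
#' otherwise. A constant input vector leaves the correlation undefined: the
#' result is flagged `NA` (with a warning), never reported as rho = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 4, finite).
#' @param exactMax largest n for which the exact permutation null is
#'   enumerated (default 9).
#' @return list with `rho`, `p`, `n`, `method`.
#' @examples
#' spearmanTest(1:5, c(2, 1, 4, 3, 5))$rho   # 0.8
#' @export
spearmanTest <- function(x, y, exactMax = 9) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exactMax) {
    perms <- allPermutations(n)
    ryP <- matrix(ry[perms], nrow(perms), n)
    rhoNull <- as.numeric(stats::cor(rx, t(ryP)))
    p <- mean(abs(rhoNull) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.xmin))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with sorted p-values, q(i) = min over j >= i of
#' m * p(j) / j, capped at 1; a test is rejected when its q-value is at most
#' `alpha`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha target FDR level.
#' @return list with `q` (adjusted p-values, input order) and `reject`
#'   (logical flags).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Feature-score Spearman association table
#'
#' One record per (ROI, metric, clinical score) combination: Spearman rho,
#' raw p, FDR-adjusted q and the number of subjects used. Subjects with a
#' missing score (or feature) are dropped pairwise and the remaining count
#' recorded. FDR correction is applied within each clinical score's family
#' of feature tests by default (`familyBy = "score"`), or across all
#' records at once (`familyBy = "all"`). Records are ordered score-major,
#' then ROI, then metric — deterministic for a given cohort.
#'
#' @param cohort a [CohortTable-class].
#' @param rois ROI names to test (default: all).
#' @param metrics metric names to test (default: all).
#' @param scores clinical score names to test (default: all).
#' @param alpha FDR threshold.
#' @param familyBy "score" or "all".
#' @param minN smallest usable pairwise sample size.
#' @return data.frame with columns `score`, `roi`, `metric`, `rho`, `p`,
#'   `q`, `n`, `significant`.
#' @export
associationTable <- function(cohort, rois = NULL, metrics = NULL,
                             scores = NULL, alpha = 0.05,
                             familyBy = c("score", "all"), minN = 4) {
  familyBy <- match.arg(familyBy)
  stopifnot(is(cohort, "CohortTable"))
  if (is.null(rois)) rois <- cohort@roiNames
  if (is.null(metrics)) metrics <- cohort@metricNames
  if (is.null(scores)) scores <- colnames(cohort@scores)
  if (!length(rois) || !length(metrics) || !length(scores))
    stop("empty ROI, metric or score selection")
  feats <- as.vector(t(outer(rois, metrics, paste, sep = ".")))
  missingF <- setdiff(feats, colnames(cohort@features))
  if (length(missingF)) stop("unknown features: ",
                             paste(missingF, collapse = ", "))
  grid <- expand.grid(metric = metrics, roi = rois, score = scores,
                      stringsAsFactors = FALSE)[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$score[i]
    col <- paste(grid$roi[i], grid$metric[i], sep = ".")
    yv <- cohort@scores[, sc]
    xv <- cohort@features[, col]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < minN)
      return(data.frame(score = sc, roi = grid$roi[i],
                        metric = grid$metric[i], rho = NA_real_,
                        p = NA_real_, n = sum(ok),
                        stringsAsFactors = FALSE))
    r <- suppressWarnings(spearmanTest(xv[ok], yv[ok]))
    data.frame(score = sc, roi = grid$roi[i], metric = grid$metric[i],
               rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$n)) || !nrow(out)) stop("no overlapping subjects")
  out$q <- NA_real_
  out$significant <- FALSE
  famIdx <- if (familyBy == "score") split(seq_len(nrow(out)), out$score)
            else list(seq_len(nrow(out)))
  for (idx in famIdx) {
    usable <- idx[!is.na(out$p[idx])]
    if (!length(usable)) next
    fdr <- bhFdr(out$p[usable], alpha)
    out$q[usable] <- fdr$q
    out$significant[usable] <- fdr$reject
  }
  rownames(out) <- NULL
  out
}
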