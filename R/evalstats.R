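# Evaluation statistics: IoU, ROC/AUC, operating points, the DeLong paired
# test for correlated AUCs, and simple group comparisons.

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("good", "poor"))
    if (length(bad)) stopf("unknown prognosis label(s): %s",
                           paste(bad, collapse = ", "))
    return(as.integer(labels == "poor"))
  }
  if (!all(labels %in% c(0, 1)))
    stopf("labels must be 0/1 or 'good'/'poor'")
  as.integer(labels)
}

#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|` between two equally shaped binary masks
#' (the Jaccard index). Two empty masks give 1 with a warning.
#'
#' @param a,b logical arrays or [lesion_mask()] objects of equal shape.
#' @return Numeric in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (inherits(a, "lesion_mask")) a <- a$data
  if (inherits(b, "lesion_mask")) b <- b$data
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stopf("mask shapes differ: (%s) vs (%s)",
          paste(dim(a) %||% length(a), collapse = "x"),
          paste(dim(b) %||% length(b), collapse = "x"))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) {
    warnf("both masks are empty; IoU defined as 1")
    return(1)
  }
  sum(a & b) / un
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive case
#' outscores a random negative one, counting ties as 1/2. Identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels 0/1 or "good"/"poor" (poor = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Classifies positive when `score >= threshold` and sweeps the threshold
#' over all observed score values. The curve starts at (0, 0) (threshold
#' above every score) and ends at (1, 1).
#'
#' @inheritParams auc
#' @return An object of class `roc_result`: `points` (data.frame with
#'   threshold, fpr, tpr), `auc`, and the positive-class convention.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0L), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  a <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = a, positive = "poor (label 1)"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' ROC operating point
#'
#' Chooses the threshold maximizing Youden's J = sensitivity + specificity
#' - 1. Ties are broken toward higher sensitivity, then toward the lower
#' threshold.
#'
#' @param roc a [roc_curve()] result.
#' @param rule cutoff selection rule; only `"youden"` is implemented.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
operating_point <- function(roc, rule = c("youden")) {
  rule <- match.arg(rule)
  if (!inherits(roc, "roc_result")) stopf("expected a roc_result")
  pts <- roc$points
  sens <- pts$tpr; spec <- 1 - pts$fpr
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[order(-sens[best], pts$threshold[best])][1]
  list(threshold = pts$threshold[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

# Placement values of the Mann-Whitney kernel: for each positive, the
# fraction of negatives it beats (ties 1/2), and vice versa.
placements <- function(scores, y) {
  xs <- scores[y == 1L]; ys <- scores[y == 0L]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores computed on the same cases, using
#' the DeLong structural-component (placement-value) estimate of
#' `var(AUC_A - AUC_B)` and a two-sided normal test.
#'
#' @param scores_a,scores_b paired numeric risk scores on identical cases.
#' @inheritParams auc
#' @return An object of class `delong_result`: `auc_a`, `auc_b`, `delta`,
#'   `variance`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stopf("scores and labels must have identical length (paired cases)")
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stopf("both classes must be present")
  pa <- placements(scores_a, y)
  pb <- placements(scores_b, y)
  m <- sum(y == 1L); n0 <- sum(y == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(1 - pa$v01, 1 - pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (v <= 0 || !is.finite(v)) {
    if (abs(delta) < 1e-12) {
      z <- 0; p <- 1; v <- max(v, 0)
    } else {
      stopf("degenerate DeLong variance (%.3g) with nonzero AUC difference %.3g",
            v, delta)
    }
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 variance = v, z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC_A = %.4f, AUC_B = %.4f, dAUC = %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with one
#' degree of freedom, as used for categorical group comparisons such as
#' gender by prognosis.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `statistic`, `p_value`, `expected`.
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("expected a 2x2 table")
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       expected = ct$expected)
}

#' Two-group summary with Welch's t test
#'
#' Group means with standard deviations plus the Welch (unequal-variance)
#' two-sample t test, for continuous demographic-style comparisons.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`,
#'   `p_value`.
#' @export
two_sample_summary <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
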