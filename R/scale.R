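#' pc-ASPECTS territory definition
#'
#' The posterior circulation Acute Stroke Prognosis Early CT Score allots 10
#' points. One point is subtracted for ischemic involvement of the left or
#' right thalamus, cerebellum, or PCA territory (operationalized here as the
#' occipital-lobe labels), and two points each for involvement of any part
#' of the midbrain or pons. The medulla oblongata is annotated but carries
#' no points (eight scored locations among nine structures), so the weights
#' sum to 10.
#'
#' @param threshold_ml minimum lesion volume (mL) inside a territory for it
#'   to count as involved; the default 0 means any overlap counts.
#' @return An object of class `scale_definition`: data.frame of territory,
#'   structure label, and points, plus the involvement threshold.
#' @export
scale_definition <- function(threshold_ml = 0) {
  if (threshold_ml < 0) stopf("threshold_ml must be nonnegative")
  terr <- data.frame(
    territory = c("left_thalamus", "right_thalamus",
                  "left_cerebellum", "right_cerebellum",
                  "left_pca", "right_pca", "midbrain", "pons", "medulla"),
    label = c(5L, 6L, 1L, 2L, 3L, 4L, 8L, 9L, 7L),
    points = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 0L))
  stopifnot(sum(terr$points) == 10L)
  structure(list(territories = terr, threshold_ml = threshold_ml),
            class = "scale_definition")
}

#' Automated pc-ASPECTS from masks
#'
#' Computes the semiquantitative score directly from a structure label
#' volume and a paired lesion mask: 10 minus the point weights of every
#' involved territory, where a territory is involved when the lesion volume
#' inside it exceeds the scale's threshold (default: any overlap).
#'
#' A score of 10 means no visible posterior-circulation ischemia; 0 means
#' every scored territory is involved. The score is monotone non-increasing
#' under lesion growth.
#'
#' @param labels a [label_volume()] or [build_atlas()] result.
#' @param lesion a paired [lesion_mask()].
#' @param scale_def a [scale_definition()].
#' @return Integer score in 0..10.
#' @export
pc_aspects <- function(labels, lesion, scale_def = scale_definition()) {
  if (!inherits(scale_def, "scale_definition"))
    stopf("expected a scale_definition")
  labels <- check_paired(labels, lesion)
  hit_ml <- tabulate(labels$data[lesion$data & labels$data > 0L], nbins = 9L) *
    voxel_ml(labels$spacing)
  terr <- scale_def$territories
  involved <- hit_ml[terr$label] > scale_def$threshold_ml
  as.integer(10L - sum(terr$points[involved]))
}

#' Dichotomize the modified Rankin Scale
#'
#' mRS 0-2 at discharge is a good prognosis; 3-6 is poor.
#'
#' @param mrs integer vector with values in 0..6.
#' @return Character vector, `"good"` or `"poor"`.
#' @export
prognosis_from_mrs <- function(mrs) {
  if (any(is.na(mrs)) || any(mrs != round(mrs)) || any(mrs < 0 | mrs > 6))
    stopf("mRS values must be integers in 0..6")
  ifelse(mrs <= 2, "good", "poor")
}

# Records input: accept a pc_cohort, its records data.frame, or an (X, y)
# pair; returns list(X = n x 10 matrix, y = 0/1 poor indicator, records).
records_matrix <- function(records) {
  if (inherits(records, "pc_cohort")) records <- records$records
  if (!is.data.frame(records)) stopf("expected a cohort or records data.frame")
  fcols <- paste0("f", 1:10)
  if (!all(fcols %in% colnames(records)))
    stopf("records must contain feature columns f1..f10")
  if (!"prognosis" %in% colnames(records))
    stopf("records must contain a 'prognosis' column")
  X <- as.matrix(records[, fcols])
  y <- as.integer(records$prognosis == "poor")
  list(X = X, y = y, records = records)
}

#' Fit the quantitative integrated score model
#'
#' Ridge-penalized logistic regression of poor prognosis on the ten
#' lesion-proportion features, fitted by Newton (iteratively reweighted
#' least squares). The integrated score of a visit is the linear predictor
#' `b + w . x`, oriented so that higher scores mean higher poor-prognosis
#' risk. The intercept is unpenalized, and the default penalty
#' `lambda = 1e-4 * n` scales with the number of records, which keeps the
#' fit invariant under dataset duplication and guards the small-sample
#' separable case.
#'
#' @param records a cohort, records data.frame (columns f1..f10 and
#'   prognosis), or anything [simulate_cohort()] returns.
#' @param lambda ridge penalty on the weights; default `1e-4 * n`.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `score_model`: weights `w` (length 10),
#'   intercept `b`, `lambda`, and fitting metadata (`converged`,
#'   `iterations`).
#' @export
fit_score_model <- function(records, lambda = NULL, max_iter = 100L,
                            tol = 1e-10) {
  rm_ <- records_matrix(records)
  X <- rm_$X; y <- rm_$y
  n <- length(y)
  if (n < 2L) stopf("need at least 2 records to fit")
  if (length(unique(y)) < 2L)
    stopf("training records contain a single prognosis class; cannot fit")
  if (is.null(lambda)) lambda <- 1e-4 * n
  Z <- cbind(1, X)
  theta <- rep(0, ncol(Z))
  pen <- c(0, rep(lambda, ncol(X)))
  obj <- function(th) {
    eta <- drop(Z %*% th)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * sum(pen * th^2)
  }
  best <- theta; best_obj <- obj(theta)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% theta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(Z, p - y)) + pen * theta
    W <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(Z * W, Z) + diag(pen, ncol(Z))
    step <- solve(H, g)
    # halve the step until the penalized deviance does not increase
    s <- 1
    repeat {
      cand <- theta - s * step
      if (obj(cand) <= best_obj + 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    theta <- cand
    o <- obj(theta)
    if (o < best_obj) { best <- theta; best_obj <- o }
    if (max(abs(s * step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("score model fit did not converge in %d iterations; best iterate returned",
          max_iter)
  theta <- best
  structure(list(w = stats::setNames(theta[-1], paste0("f", 1:10)),
                 b = unname(theta[1]), lambda = lambda,
                 converged = converged, iterations = it),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> integrated score = b + w.x (higher = higher risk)\n")
  cat("  b =", format(x$b, digits = 4), " lambda =", x$lambda,
      if (x$converged) "(converged," else "(NOT converged,",
      x$iterations, "iterations)\n")
  print(round(x$w, 3))
  invisible(x)
}

#' Save / load a fitted score model as JSON
#'
#' Stores the weight vector, intercept, penalty and fitting metadata in a
#' plain JSON file.
#'
#' @param model a [fit_score_model()] result.
#' @param path JSON file path.
#' @return `write_score_model` returns `path` invisibly; `read_score_model`
#'   returns the `score_model`.
#' @export
write_score_model <- function(model, path) {
  if (!inherits(model, "score_model")) stopf("expected a score_model")
  jsonlite::write_json(list(w = as.list(model$w), b = model$b,
                            lambda = model$lambda,
                            converged = model$converged,
                            iterations = model$iterations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = stats::setNames(as.numeric(x$w), names(x$w)),
                 b = x$b, lambda = x$lambda, converged = x$converged,
                 iterations = x$iterations),
            class = "score_model")
}

#' Integrated score for new records
#'
#' @param object a fitted [fit_score_model()].
#' @param newdata records data.frame / cohort with columns f1..f10.
#' @param type `"score"` for the linear predictor (the integrated score) or
#'   `"prob"` for the implied poor-prognosis probability.
#' @param ... unused.
#' @return Numeric vector of scores or probabilities.
#' @export
predict.score_model <- function(object, newdata, type = c("score", "prob"),
                                ...) {
  type <- match.arg(type)
  if (inherits(newdata, "pc_cohort")) newdata <- newdata$records
  X <- as.matrix(newdata[, paste0("f", 1:10)])
  eta <- object$b + drop(X %*% object$w)
  if (type == "prob") stats::plogis(eta) else eta
}

#' Out-of-fold integrated scores by k-fold cross validation
#'
#' Partitions visits into `k` subsets (using the cohort's `subset` column if
#' present, otherwise a seeded random partition), fits the score model on
#' each set of `k - 1` subsets, and scores the held-out subset with it, so
#' every visit is scored exactly once by a model that never saw it.
#'
#' @param records cohort or records data.frame.
#' @param k number of folds; ignored when a `subset` column is present
#'   unless `reassign = TRUE`.
#' @param seed seed for partition assignment when one is needed.
#' @param lambda passed to [fit_score_model()] (default `1e-4 *` training-set
#'   size, per fold).
#' @param reassign force a fresh seeded partition even if `subset` exists.
#' @return data.frame with visit_id (if available), subset, prognosis, and
#'   the out-of-fold integrated `score`, in the input row order.
#' @export
cross_validated_scores <- function(records, k = 5L, seed = 1L, lambda = NULL,
                                   reassign = FALSE) {
  rm_ <- records_matrix(records)
  rec <- rm_$records
  n <- nrow(rec)
  if (!"subset" %in% colnames(rec) || reassign)
    rec$subset <- assign_subsets(n, k, seed)
  folds <- sort(unique(rec$subset))
  score <- rep(NA_real_, n)
  for (f in folds) {
    test <- rec$subset == f
    train <- rec[!test, , drop = FALSE]
    if (length(unique(train$prognosis)) < 2L)
      stopf("training part of fold %s is single-class; re-partition the cohort",
            f)
    fit <- fit_score_model(train, lambda = lambda)
    score[test] <- predict(fit, rec[test, , drop = FALSE])
  }
  stopifnot(!anyNA(score))
  out <- data.frame(subset = rec$subset, prognosis = rec$prognosis,
                    score = score)
  if ("visit_id" %in% colnames(rec))
    out <- cbind(visit_id = rec$visit_id, out)
  out
}
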