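#' Configuration for the synthetic stroke cohort
#'
#' Describes the generative model of the synthetic registry: per-visit lesion
#' burden over the nine structures plus the remaining brain ("other"), and a
#' logistic link from the ten lesion-proportion features to the probability
#' of a poor prognosis, `Pr(poor) = plogis(beta0 + beta . x)`.
#'
#' The default burden model involves each of the ten regions independently
#' with probability `p_involve = 0.5` and draws involved fractions uniformly
#' on (0, 1). This is deliberately heavier and more dispersed than a
#' clinical registry: it maximizes feature spread so that weight-recovery
#' and cross-validation diagnostics are well powered. The default weights
#' `beta` put the largest prognostic load on the brainstem (midbrain, pons,
#' medulla), and `beta0` centers the cohort near a 50/50 good/poor split.
#'
#' @param n number of visits.
#' @param k number of cross-validation subsets (default 5).
#' @param beta length-10 generative weight vector (order: [structure_names()]
#'   then "other").
#' @param beta0 generative intercept.
#' @param p_involve per-region involvement probability.
#' @param frac_shape1,frac_shape2 Beta parameters for involved fractions;
#'   the default (1, 1) is uniform.
#' @param seed integer root seed; a fixed seed reproduces the cohort exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 36, k = 5,
                          beta = c(1.5, 1.5, 0.75, 0.75, 2.25, 2.25,
                                   4.5, 6, 6, 3),
                          beta0 = -7.1,
                          p_involve = 0.5,
                          frac_shape1 = 1, frac_shape2 = 1,
                          seed = 1L) {
  if (n < k) stopf("cohort size n = %d is smaller than subset count k = %d", n, k)
  if (length(beta) != 10L) stopf("beta must have length 10")
  if (p_involve <= 0 || p_involve >= 1)
    stopf("p_involve must lie strictly in (0, 1)")
  structure(list(n = as.integer(n), k = as.integer(k), beta = beta,
                 beta0 = beta0, p_involve = p_involve,
                 frac_shape1 = frac_shape1, frac_shape2 = frac_shape2,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Seeded partition of n visits into k subsets with sizes differing by <= 1.
assign_subsets <- function(n, k, seed) {
  if (n < k) stopf("cannot partition %d visits into %d subsets", n, k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Simulate a synthetic stroke cohort
#'
#' Draws `n` visits from the generative model in [cohort_config()]: a
#' per-visit lesion-burden feature vector `f1..f10`, a poor-prognosis
#' indicator drawn from `Bernoulli(plogis(beta0 + beta . x))`, an mRS score
#' consistent with the prognosis (uniform over 0-2 for good, 3-6 for poor),
#' and a subset id in `1..k` from a seeded random partition whose sizes
#' differ by at most one.
#'
#' With `masks = TRUE` the sampled fractions are additionally realized as
#' voxel masks on `atlas` via [place_lesion()], and the recorded features
#' are re-measured from the masks with [lesion_features()] so that records
#' and masks agree exactly (measured fractions differ from the sampled
#' targets only by voxel quantization).
#'
#' @param config a [cohort_config()].
#' @param masks logical; also generate per-visit lesion masks (default
#'   `FALSE`; feature vectors are then the sampled fractions directly).
#' @param atlas atlas used when `masks = TRUE`; defaults to a compact grid.
#' @return An object of class `pc_cohort`: list with `records` (data.frame
#'   of visit_id, subset, mrs, prognosis, f1..f10, and the generative
#'   linear predictor `lp`), `lesions` (list of [lesion_mask()] or `NULL`),
#'   `atlas` (or `NULL`) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), masks = FALSE,
                            atlas = NULL) {
  if (!inherits(config, "cohort_config")) stopf("expected a cohort_config")
  n <- config$n
  if (masks && is.null(atlas)) atlas <- build_atlas(c(12, 64, 64))
  targets <- c(structure_names(), "other")
  X <- with_seed(derive_seed(config$seed, "burden"), {
    inv <- matrix(stats::runif(n * 10) < config$p_involve, n, 10)
    x <- matrix(0, n, 10)
    x[inv] <- stats::rbeta(sum(inv), config$frac_shape1, config$frac_shape2)
    x
  })
  lesions <- NULL
  if (masks) {
    lesions <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- stats::setNames(X[i, ], targets)
      lesions[[i]] <- place_lesion(atlas, fr[fr > 0],
                                   seed = derive_seed(config$seed, paste0("mask", i)))
      X[i, ] <- lesion_features(atlas, lesions[[i]])
    }
  }
  lp <- config$beta0 + drop(X %*% config$beta)
  poor <- with_seed(derive_seed(config$seed, "outcome"),
                    stats::rbinom(n, 1L, stats::plogis(lp)))
  mrs <- with_seed(derive_seed(config$seed, "mrs"),
                   ifelse(poor == 1L, sample(3:6, n, replace = TRUE),
                          sample(0:2, n, replace = TRUE)))
  subset <- assign_subsets(n, config$k, derive_seed(config$seed, "subset"))
  records <- data.frame(visit_id = sprintf("v%04d", seq_len(n)),
                        subset = subset, mrs = mrs,
                        prognosis = ifelse(poor == 1L, "poor", "good"),
                        lp = lp)
  colnames(X) <- paste0("f", 1:10)
  records <- cbind(records, as.data.frame(X))
  structure(list(records = records, lesions = lesions, atlas = atlas,
                 config = config),
            class = "pc_cohort")
}

#' @export
print.pc_cohort <- function(x, ...) {
  cat("<pc_cohort>", nrow(x$records), "visits,",
      sum(x$records$prognosis == "poor"), "poor /",
      sum(x$records$prognosis == "good"), "good,",
      x$config$k, "subsets", if (!is.null(x$lesions)) "(with masks)" else "",
      "\n")
  invisible(x)
}

#' Write cohort records to CSV
#'
#' Columns: visit_id, subset, mrs, prognosis, f1..f10.
#'
#' @param cohort a [simulate_cohort()] result (or its `records` data.frame).
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  rec <- if (inherits(cohort, "pc_cohort")) cohort$records else cohort
  keep <- c("visit_id", "subset", "mrs", "prognosis", paste0("f", 1:10))
  utils::write.csv(rec[, intersect(keep, colnames(rec))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
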