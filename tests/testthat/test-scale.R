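test_that("pc-ASPECTS reproduces the worked extremes and point rules", {
  atlas <- small_atlas()
  expect_identical(pc_aspects(atlas, empty_lesion(atlas)), 10L)

  scored <- setdiff(structure_names(), "medulla")
  expect_identical(pc_aspects(atlas, point_lesion(atlas, scored)), 0L)

  expect_identical(pc_aspects(atlas, point_lesion(atlas, "midbrain")), 8L)
  expect_identical(pc_aspects(atlas, point_lesion(atlas, "medulla")), 10L)
  expect_identical(pc_aspects(atlas, point_lesion(atlas, "left_thalamus")), 9L)
})

test_that("pc-ASPECTS equals the weight-sum oracle over all involvement patterns", {
  atlas <- small_atlas()
  scored <- setdiff(structure_names(), "medulla")
  weights <- c(1, 1, 1, 1, 1, 1, 2, 2)  # cereb LR, occ LR, thal LR, mid, pons
  names(weights) <- c("left_cerebellum", "right_cerebellum",
                      "left_occipital", "right_occipital",
                      "left_thalamus", "right_thalamus", "midbrain", "pons")
  for (pattern in 0:255) {
    on <- scored[bitwAnd(bitwShiftR(pattern, 0:7), 1L) == 1L]
    les <- if (length(on)) point_lesion(atlas, on) else empty_lesion(atlas)
    expect_identical(pc_aspects(atlas, les),
                     as.integer(10 - sum(weights[on])))
  }
})

test_that("pc-ASPECTS is monotone non-increasing under lesion growth", {
  atlas <- small_atlas()
  grown <- array(FALSE, dim(atlas$labels$data))
  prev <- 10L
  for (nm in c("left_thalamus", "midbrain", "pons", "left_cerebellum",
               "right_occipital")) {
    grown[which(atlas$labels$data == match(nm, structure_names()))[1]] <- TRUE
    cur <- pc_aspects(atlas, lesion_mask(grown, atlas$spacing))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the involvement threshold suppresses sub-threshold overlap", {
  atlas <- small_atlas()
  les <- point_lesion(atlas, "midbrain")  # a single 1.25 mm^3 voxel
  expect_identical(pc_aspects(atlas, les), 8L)
  expect_identical(pc_aspects(atlas, les, scale_definition(threshold_ml = 0.01)),
                   10L)
})

test_that("mRS dichotomization matches the 0-2 / 3-6 cut", {
  expect_identical(prognosis_from_mrs(c(0, 2, 3, 6)),
                   c("good", "good", "poor", "poor"))
  expect_error(prognosis_from_mrs(7), "0..6")
  expect_error(prognosis_from_mrs(-1), "0..6")
})

test_that("score model fitting matches unpenalized logistic regression as lambda -> 0", {
  co <- simulate_cohort(cohort_config(n = 400, seed = 21))
  fit <- fit_score_model(co$records, lambda = 1e-10)
  ref <- stats::glm(I(prognosis == "poor") ~ .,
                    data = co$records[, c("prognosis", paste0("f", 1:10))],
                    family = stats::binomial())
  expect_equal(unname(fit$w), unname(stats::coef(ref)[-1]), tolerance = 1e-5)
  expect_equal(fit$b, unname(stats::coef(ref)[1]), tolerance = 1e-5)
})

test_that("degenerate fits behave as documented", {
  rec <- data.frame(prognosis = rep(c("good", "poor"), each = 20))
  for (i in 1:10) rec[[paste0("f", i)]] <- 0
  fit <- fit_score_model(rec, lambda = 1e-8)
  expect_equal(unname(fit$w), rep(0, 10))
  expect_equal(fit$b, stats::qlogis(0.5), tolerance = 1e-6)

  rec$prognosis <- "good"
  expect_error(fit_score_model(rec), "single prognosis class")
})

test_that("fitting is invariant to dataset duplication under the scaled default penalty", {
  co <- simulate_cohort(cohort_config(n = 120, seed = 22))
  fit1 <- fit_score_model(co$records)
  fit2 <- fit_score_model(rbind(co$records, co$records))
  expect_equal(fit1$w, fit2$w, tolerance = 1e-8)
  expect_equal(fit1$b, fit2$b, tolerance = 1e-8)
})

test_that("integrated scores are invariant to visit relabeling", {
  co <- simulate_cohort(cohort_config(n = 60, seed = 23))
  s1 <- cross_validated_scores(co$records)
  rec2 <- co$records
  rec2$visit_id <- sprintf("renamed%03d", seq_len(nrow(rec2)))
  s2 <- cross_validated_scores(rec2)
  expect_equal(s1$score, s2$score)
})

test_that("cross validation scores every visit out of fold", {
  co <- simulate_cohort(cohort_config(n = 6, k = 6, seed = 31))
  loo <- cross_validated_scores(co$records)
  expect_identical(nrow(loo), 6L)
  expect_false(anyNA(loo$score))

  # manual fold-by-fold recomputation agrees (bookkeeping check)
  co2 <- simulate_cohort(cohort_config(n = 80, k = 4, seed = 32))
  cv <- cross_validated_scores(co2$records)
  for (f in 1:4) {
    test <- co2$records$subset == f
    fit <- fit_score_model(co2$records[!test, ])
    expect_equal(cv$score[test],
                 unname(predict(fit, co2$records[test, ])), tolerance = 1e-12)
  }
})

test_that("a single-class training fold is rejected with advice", {
  rec <- simulate_cohort(cohort_config(n = 20, k = 2, seed = 33))$records
  rec$subset <- rep(1:2, each = 10)
  # subset 2 (the training part of fold 1) carries only good prognoses
  rec$prognosis <- c("poor", rep("good", 19))
  expect_error(cross_validated_scores(rec), "single-class")
})

test_that("out-of-fold scores are null-calibrated under permuted labels", {
  co <- simulate_cohort(cohort_config(n = 2000, seed = 41))
  rec <- co$records
  rec$prognosis <- with_seed(99, sample(rec$prognosis))
  cv <- cross_validated_scores(rec)
  a <- auc(cv$score, cv$prognosis)
  expect_gte(a, 0.45)
  expect_lte(a, 0.55)
})

test_that("score models survive a JSON round trip", {
  co <- simulate_cohort(cohort_config(n = 80, seed = 51))
  fit <- fit_score_model(co$records)
  tmp <- tempfile(fileext = ".json")
  write_score_model(fit, tmp)
  back <- read_score_model(tmp)
  expect_equal(back$w, fit$w)
  expect_equal(back$b, fit$b)
  expect_equal(predict(back, co$records), predict(fit, co$records))
  unlink(tmp)
})
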