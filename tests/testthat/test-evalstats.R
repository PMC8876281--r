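test_that("IoU follows the intersection-over-union definition", {
  a <- array(FALSE, c(2, 4, 4)); a[1, 1:2, 1:2] <- TRUE
  expect_equal(iou(a, a), 1.0)
  b <- array(FALSE, c(2, 4, 4)); b[2, 3:4, 3:4] <- TRUE
  expect_equal(iou(a, b), 0.0)
  c_ <- array(FALSE, c(2, 4, 4)); c_[1, 1:2, 2:3] <- TRUE
  expect_equal(iou(a, c_), 2 / 6)
  expect_equal(iou(c_, a), iou(a, c_))
  expect_warning(v <- iou(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
                 "empty")
  expect_equal(v, 1.0)
  expect_error(iou(a, array(FALSE, c(1, 4, 4))), "shape")
})

test_that("AUC matches brute-force pair counting, including ties", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(auc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  for (seed in 1:25) {
    dat <- with_seed(seed, {
      n <- sample(8:25, 1)
      list(s = round(stats::rnorm(n), 1),  # rounding forces ties
           y = c(0, 1, stats::rbinom(n - 2, 1, 0.5)))
    })
    expect_equal(auc(dat$s, dat$y), pair_count_auc(dat$s, dat$y),
                 tolerance = 1e-12)
  }
})

test_that("AUC invariances hold", {
  dat <- with_seed(5, list(s = stats::rnorm(40),
                           y = c(0, 1, stats::rbinom(38, 1, 0.4))))
  expect_equal(auc(dat$s, dat$y) + auc(-dat$s, dat$y), 1.0)
  expect_equal(auc(exp(2 * dat$s) + 3, dat$y), auc(dat$s, dat$y))
})

test_that("the ROC curve is anchored and consistent with the AUC", {
  dat <- with_seed(6, list(s = round(stats::rnorm(60), 1),
                           y = c(0, 1, stats::rbinom(58, 1, 0.5))))
  roc <- roc_curve(dat$s, dat$y)
  expect_equal(unlist(roc$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_equal(roc$auc, auc(dat$s, dat$y), tolerance = 1e-12)
})

test_that("the Youden operating point matches an exhaustive threshold scan", {
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  op <- operating_point(roc)
  expect_equal(op$sensitivity, 1.0)
  expect_equal(op$specificity, 1.0)

  # worked 4-point example: J is tied; tie resolves to the higher-sensitivity
  # point, the lower threshold
  roc4 <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  op4 <- operating_point(roc4)
  expect_equal(op4$sensitivity, 1.0)
  expect_equal(op4$specificity, 0.5)
  expect_equal(op4$threshold, 0.35)

  # exhaustive scan oracle on random data
  dat <- with_seed(7, list(s = round(stats::rnorm(50), 1),
                           y = c(0, 1, stats::rbinom(48, 1, 0.5))))
  roc_r <- roc_curve(dat$s, dat$y)
  op_r <- operating_point(roc_r)
  best_j <- max(vapply(unique(dat$s), function(t) {
    sens <- sum(dat$s >= t & dat$y == 1) / sum(dat$y == 1)
    spec <- sum(dat$s < t & dat$y == 0) / sum(dat$y == 0)
    sens + spec - 1
  }, numeric(1)))
  expect_equal(op_r$youden, best_j, tolerance = 1e-12)

  flat <- operating_point(roc_curve(rep(1, 8), c(0, 0, 0, 0, 1, 1, 1, 1)))
  expect_equal(flat$youden, 0)
})

test_that("DeLong test is exact under identical or rank-equivalent scores", {
  dat <- with_seed(8, list(s = stats::rnorm(50),
                           y = c(0, 1, stats::rbinom(48, 1, 0.5))))
  same <- delong_test(dat$s, dat$s, dat$y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_test(dat$s, stats::plogis(3 * dat$s) + 2, dat$y)
  expect_equal(mono$delta, 0)
  expect_equal(mono$p_value, 1)
})

test_that("DeLong agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 17, 92)) {
    dat <- with_seed(seed, {
      n <- 120
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      lp <- stats::rnorm(n) + y
      list(y = y, a = lp + stats::rnorm(n, 0, 0.8),
           b = lp + stats::rnorm(n, 0, 1.5))
    })
    mine <- delong_test(dat$a, dat$b, dat$y)
    ref <- pROC::roc.test(pROC::roc(dat$y, dat$a, quiet = TRUE,
                                    direction = "<"),
                          pROC::roc(dat$y, dat$b, quiet = TRUE,
                                    direction = "<"),
                          method = "delong")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("the 2x2 chi-square reproduces the worked gender comparison", {
  # good prognosis: 13 male / 5 female; poor: 7 male / 11 female
  gender <- matrix(c(13, 7, 5, 11), 2, 2)
  res <- chi2_2x2(gender)
  expect_equal(round(res$p_value, 3), 0.044)

  same <- chi2_2x2(matrix(c(10, 10, 4, 4), 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- chi2_2x2(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(sep$statistic, 20)  # direct sum (O-E)^2/E with E = 5

  # equivalence with the squared two-proportion z test
  tab <- matrix(c(18, 11, 7, 14), 2, 2)
  pz <- stats::prop.test(tab, correct = FALSE)
  expect_equal(chi2_2x2(tab)$statistic, unname(pz$statistic), tolerance = 1e-12)

  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(chi2_2x2(matrix(1:6, 2, 3)), "2x2")
})

test_that("two-sample summaries match direct computation and the Welch test", {
  a <- with_seed(9, stats::rnorm(30, 10, 2))
  b <- with_seed(10, stats::rnorm(40, 12, 3))
  s <- two_sample_summary(a, b)
  expect_equal(s$mean_a, sum(a) / length(a), tolerance = 1e-12)
  expect_equal(s$sd_a, sqrt(sum((a - mean(a))^2) / (length(a) - 1)),
               tolerance = 1e-12)
  expect_equal(s$p_value, stats::t.test(a, b)$p.value, tolerance = 1e-12)

  same <- two_sample_summary(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  big <- two_sample_summary(with_seed(1, stats::rnorm(1000, 0, 1)),
                            with_seed(2, stats::rnorm(1000, 1, 1)))
  expect_lt(big$p_value, 1e-6)

  expect_error(two_sample_summary(1, c(2, 3)), "at least 2")
})
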