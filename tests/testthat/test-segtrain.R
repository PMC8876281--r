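test_that("brain-window normalization maps the window to [0, 1]", {
  expect_equal(normalize_ct(matrix(35, 3, 3)), matrix(0.5, 3, 3))
  expect_equal(normalize_ct(matrix(c(-5, 75), 1, 2)), matrix(c(0, 1), 1, 2))
  expect_equal(normalize_ct(matrix(c(-1000, 3000), 1, 2)),
               matrix(c(0, 1), 1, 2))
  img <- with_seed(1, matrix(stats::rnorm(96 * 96, 40, 200), 96, 96))
  nm <- normalize_ct(img)
  expect_gte(min(nm), 0)
  expect_lte(max(nm), 1)
  expect_error(normalize_ct(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("augmentation applies one transform to both image and labels", {
  img <- with_seed(2, matrix(stats::runif(64 * 64), 64, 64))
  lab <- matrix(0L, 64, 64); lab[10:20, 30:40] <- 5L

  idcfg <- train_config(crop_size = 64L, scale_amplitude = 0)
  id_ <- augment_pair(img, lab, idcfg, seed = 1)
  expect_identical(id_$image, img)
  expect_identical(id_$labels, lab)

  cfg <- train_config()
  a <- augment_pair(img, lab, cfg, seed = 3)
  b <- augment_pair(img, lab, cfg, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$image, augment_pair(img, lab, cfg, seed = 4)$image))

  # crop 480 from 512 at the reference resolution
  big <- matrix(0, 512, 512)
  blab <- matrix(0L, 512, 512); blab[1:256, ] <- 4L; blab[400:512, 1:50] <- 7L
  out <- augment_pair(big, blab, train_config(scale_amplitude = 0), seed = 5)
  expect_identical(dim(out$image), c(480L, 480L))
  expect_true(all(unique(as.vector(out$labels)) %in% unique(as.vector(blab))))

  expect_error(augment_pair(img, lab,
                            train_config(crop_size = 128L,
                                         crop_scale_proportional = FALSE),
                            seed = 1),
               "exceeds image size")
})

test_that("augmentation never invents label values", {
  cfg <- train_config()
  for (seed in 1:10) {
    lab <- with_seed(seed, matrix(sample(c(0L, 0L, 0L, 3L, 8L), 96 * 96,
                                         replace = TRUE), 96, 96))
    img <- with_seed(seed + 100, matrix(stats::runif(96 * 96), 96, 96))
    out <- augment_pair(img, lab, cfg, seed = seed)
    expect_true(all(out$labels %in% unique(as.vector(lab))))
  }
})

test_that("network gradients match finite differences", {
  spec <- seg_model_spec(channels = c(3L, 4L), classes = 6L)
  params <- init_seg_params(spec, 1)
  x <- with_seed(2, matrix(stats::runif(64), 8, 8))
  lab <- with_seed(3, matrix(sample(0:5, 64, TRUE), 8, 8))
  valid <- matrix(TRUE, 8, 8)
  cw <- c(1, 2, 0.5, 1, 1.5, 1)
  lossfn <- function(p)
    softmax_ce(seg_forward(p, x, spec)$logits, lab, valid, cw)$loss
  fwd <- seg_forward(params, x, spec)
  gr <- seg_backward(params, fwd,
                     softmax_ce(fwd$logits, lab, valid, cw)$dlogits)
  for (nm in names(params)) {
    i <- with_seed(4, sample(length(params[[nm]]), 1))
    eps <- 1e-5
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + eps; up <- lossfn(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- lossfn(p2)
    expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training degenerates gracefully and follows the lr schedule", {
  fx <- seg_fixture()
  imgs <- fx$images[1:2]; labs <- fx$labels[1:2]

  expect_warning(m0 <- train_segmenter(imgs, labs,
                                       train_config(max_epochs = 0L),
                                       seg_model_spec(), imgs, labs),
                 "untrained")
  expect_identical(nrow(m0$history), 0L)

  expect_error(train_segmenter(imgs, labs, train_config(max_epochs = 2L),
                               seg_model_spec(), list(), list()),
               "tuning set")

  # a permanent plateau (huge min_delta) must decay the lr by exactly the
  # decay factor once per `patience` epochs, monotonically
  cfg <- train_config(max_epochs = 7L, patience = 2L, stop_patience = 100L,
                      min_delta = 1e6, augment = FALSE)
  m <- train_segmenter(imgs, labs, cfg, seg_model_spec(channels = c(2L, 3L)),
                       imgs, labs)
  lr <- m$history$lr
  expect_true(all(diff(lr) <= 0))
  drops <- lr[-1] / lr[-length(lr)]
  expect_true(all(abs(drops[drops < 1] - 0.1) < 1e-12))
  # epoch 1 always improves on the initial Inf, so the first decay lands
  # after `patience` further epochs
  expect_equal(lr, c(1e-3, 1e-3, 1e-3, 1e-4, 1e-4, 1e-5, 1e-5))

  # the selected checkpoint has the lowest recorded tuning loss
  cfg2 <- train_config(max_epochs = 6L, augment = FALSE)
  m2 <- train_segmenter(imgs, labs, cfg2, seg_model_spec(channels = c(2L, 3L)),
                        imgs, labs)
  expect_lte(m2$best_tune_loss, min(m2$history$tune_loss) + 1e-12)
})

test_that("fold evaluation partitions cases and matches the perfect predictor", {
  fx <- seg_fixture()
  cases <- lapply(seq(1, 8, 2), function(i)
    list(images = fx$images[i:(i + 1)], labels = fx$labels[i:(i + 1)]))

  oracle <- local({
    lookup <- cases
    function(images) {
      for (cs in lookup)
        if (identical(cs$images, images)) return(cs$labels)
      stop("unknown case")
    }
  })
  rep_perfect <- evaluate_folds(cases, k = 2, seed = 1, predictor = oracle)
  expect_identical(dim(rep_perfect), c(9L, 3L))
  expect_true(all(rep_perfect == 1.0))

  folds <- attr(rep_perfect, "folds")
  expect_identical(sort(unique(folds)), 1:2)
  expect_identical(length(folds), 4L)
  expect_lte(diff(range(table(folds))), 1)

  # report contract with a real (briefly trained) model
  cfg <- train_config(max_epochs = 2L, augment = FALSE)
  rep_fast <- evaluate_folds(cases, k = 2, seed = 1, config = cfg,
                             spec = seg_model_spec(channels = c(2L, 3L)))
  expect_identical(dim(rep_fast), c(9L, 3L))
  expect_true(all(rep_fast >= 0 & rep_fast <= 1))
  expect_equal(unname(rep_fast[, "mean"]),
               unname(rowMeans(rep_fast[, 1:2])), tolerance = 1e-12)

  expect_error(evaluate_folds(cases, k = 5), "at least")
})
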