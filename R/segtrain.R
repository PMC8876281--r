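# Desk-scale encoder-decoder semantic segmentation of the nine structures
# from synthetic noncontrast-CT slices. The network is a small symmetric
# SegNet-style model (two 2x2 max-pool stages, nearest-neighbor upsampling
# decoder, ~20k parameters) trained with Adam, per-pixel cross-entropy,
# plateau learning-rate decay and checkpoint early stopping.

#' Training configuration for the segmentation model
#'
#' @param batch_size minibatch size (default 4).
#' @param lr initial learning rate (default 0.001).
#' @param decay_factor learning rate is divided by this whenever the tuning
#'   loss plateaus (default 10).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param patience epochs without tuning-loss improvement before the
#'   learning rate is decayed (default 3).
#' @param stop_patience epochs without improvement before training stops
#'   early (default 20).
#' @param max_epochs epoch budget (default 100).
#' @param crop_size random-crop size at the reference resolution (default
#'   480, from 512); scaled proportionally for smaller inputs.
#' @param reference_size resolution at which `crop_size` is defined (512).
#' @param crop_scale_proportional scale the crop down for small inputs; if
#'   `FALSE`, a crop larger than the image is an error.
#' @param scale_amplitude random-scaling amplitude (default 0.10, i.e.
#'   resize factor uniform in 0.9..1.1).
#' @param min_delta minimum tuning-loss improvement that counts against the
#'   plateau counters (default 1e-4).
#' @param augment apply random crop/scale augmentation during training.
#' @param window_level,window_width brain-window parameters (HU) used by
#'   [normalize_ct()] before images enter the network.
#' @param seed root seed for initialization, shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, lr = 0.001, decay_factor = 10,
                         weight_decay = 1e-4, patience = 3L,
                         stop_patience = 20L, max_epochs = 100L,
                         crop_size = 480L, reference_size = 512L,
                         crop_scale_proportional = TRUE,
                         scale_amplitude = 0.10, min_delta = 1e-4,
                         augment = TRUE, window_level = 35,
                         window_width = 80, seed = 1L) {
  if (lr <= 0 || decay_factor <= 1 || weight_decay < 0)
    stopf("rates must be positive (and decay_factor > 1)")
  if (scale_amplitude < 0 || scale_amplitude >= 1)
    stopf("scale_amplitude must lie in [0, 1)")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 decay_factor = decay_factor, weight_decay = weight_decay,
                 patience = as.integer(patience),
                 stop_patience = as.integer(stop_patience),
                 max_epochs = as.integer(max_epochs),
                 crop_size = as.integer(crop_size),
                 reference_size = as.integer(reference_size),
                 crop_scale_proportional = crop_scale_proportional,
                 scale_amplitude = scale_amplitude, min_delta = min_delta,
                 augment = augment, window_level = window_level,
                 window_width = window_width, seed = as.integer(seed)),
            class = "train_config")
}

#' Segmentation model architecture
#'
#' A symmetric encoder-decoder: two conv+ReLU+maxpool encoder stages, a
#' bottleneck conv, and a mirrored decoder with nearest-neighbor
#' upsampling, ending in a 10-way (background + nine structures) per-pixel
#' classifier whose spatial output shape equals the input shape.
#'
#' @param channels length-2 integer, encoder channel widths (default 8, 16).
#' @param classes number of output classes (default 10).
#' @param input_center,input_gain input standardization applied inside the
#'   model: normalized pixels are mapped to `(x - center) * gain` before
#'   the first convolution. The gain spreads the narrow normalized
#'   intensity range so that class-separating decision boundaries are
#'   reachable within a small optimization budget.
#' @param coord_channels append normalized row/column coordinate channels
#'   (in -1..1) to the input. Brain anatomy is spatially stereotyped and
#'   left/right paired structures are otherwise indistinguishable to a
#'   translation-equivariant network; coordinate features resolve the
#'   midline (the CoordConv construction).
#' @return An object of class `seg_model_spec`.
#' @export
seg_model_spec <- function(channels = c(8L, 16L), classes = 10L,
                           input_center = 0.5, input_gain = 10,
                           coord_channels = TRUE) {
  if (length(channels) != 2L || any(channels < 1L))
    stopf("channels must be two positive integers")
  structure(list(channels = as.integer(channels),
                 classes = as.integer(classes),
                 input_center = input_center, input_gain = input_gain,
                 coord_channels = isTRUE(coord_channels)),
            class = "seg_model_spec")
}

#' Brain-window intensity normalization
#'
#' Clamps intensities to the brain window `level +/- width/2` and maps the
#' window linearly to `[0, 1]`, the standard preprocessing before CT slices
#' enter the network.
#'
#' @param image numeric matrix/array of intensities (HU).
#' @param level window center in HU (default 35).
#' @param width window width in HU (default 80).
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_ct <- function(image, level = 35, width = 80) {
  if (any(!is.finite(image))) stopf("image contains non-finite intensities")
  lo <- level - width / 2
  pmin(pmax((image - lo) / width, 0), 1)
}

# --- resampling -------------------------------------------------------------

resize_bilinear <- function(img, new_dim) {
  H <- nrow(img); W <- ncol(img)
  h2 <- new_dim[1]; w2 <- new_dim[2]
  if (h2 == H && w2 == W) return(img)
  # voxel-center alignment
  yi <- (seq_len(h2) - 0.5) * H / h2 + 0.5
  xi <- (seq_len(w2) - 0.5) * W / w2 + 0.5
  y0 <- pmin(pmax(floor(yi), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xi), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * (1 - wy) + img[y1, x0, drop = FALSE] * wy
  b <- img[y0, x1, drop = FALSE] * (1 - wy) + img[y1, x1, drop = FALSE] * wy
  a * rep(1 - wx, each = h2) + b * rep(wx, each = h2)
}

resize_nearest <- function(img, new_dim) {
  H <- nrow(img); W <- ncol(img)
  h2 <- new_dim[1]; w2 <- new_dim[2]
  if (h2 == H && w2 == W) return(img)
  yi <- pmin(pmax(ceiling((seq_len(h2) - 0.5) * H / h2), 1), H)
  xi <- pmin(pmax(ceiling((seq_len(w2) - 0.5) * W / w2), 1), W)
  img[yi, xi, drop = FALSE]
}

effective_crop <- function(config, img_dim) {
  crop <- config$crop_size
  if (crop > min(img_dim)) {
    if (!config$crop_scale_proportional)
      stopf("crop size %d exceeds image size %s", crop,
            paste(img_dim, collapse = "x"))
    crop <- max(4L, as.integer(round(min(img_dim) * config$crop_size /
                                       config$reference_size)))
  }
  crop
}

#' Paired random crop / scale augmentation
#'
#' Applies one identical spatial transform to an image and its label map: a
#' random resize by a factor uniform in `1 +/- scale_amplitude` (bilinear
#' for the image, nearest-neighbor for labels, so no new label values can
#' appear) followed by a random crop to the configured crop size. With
#' amplitude 0 and a full-size crop the transform is the identity.
#' Deterministic under a fixed seed.
#'
#' @param image numeric matrix.
#' @param labels integer matrix of the same shape.
#' @param config a [train_config()].
#' @param seed integer seed.
#' @return List with transformed `image` and `labels`.
#' @export
augment_pair <- function(image, labels, config = train_config(), seed = 1L) {
  if (!identical(dim(image), dim(labels)))
    stopf("image and label shapes differ")
  crop <- effective_crop(config, dim(image))
  with_seed(seed, {
    a <- config$scale_amplitude
    s <- stats::runif(1, max(1 - a, crop / min(dim(image))), 1 + a)
    nd <- pmax(crop, as.integer(round(dim(image) * s)))
    img <- resize_bilinear(image, nd)
    lab <- resize_nearest(labels, nd)
    oy <- if (nd[1] > crop) sample.int(nd[1] - crop + 1L, 1L) else 1L
    ox <- if (nd[2] > crop) sample.int(nd[2] - crop + 1L, 1L) else 1L
    list(image = img[oy:(oy + crop - 1L), ox:(ox + crop - 1L)],
         labels = lab[oy:(oy + crop - 1L), ox:(ox + crop - 1L)])
  })
}

# --- network primitives -----------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- array(0, c(H + 2L, W + 2L, C))
  p[2:(H + 1), 2:(W + 1), ] <- x
  out <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- p[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    out[, k * C + seq_len(C)] <- blk
    k <- k + 1L
  }
  out
}

col2im3 <- function(cols, xdim) {
  H <- xdim[1]; W <- xdim[2]; C <- xdim[3]
  p <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- array(cols[, k * C + seq_len(C)], c(H, W, C))
    p[di + seq_len(H), dj + seq_len(W), ] <-
      p[di + seq_len(H), dj + seq_len(W), , drop = FALSE] + blk
    k <- k + 1L
  }
  array(p[2:(H + 1), 2:(W + 1), , drop = FALSE], xdim)
}

conv_fwd <- function(x, Wm, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% Wm
  y <- sweep(y, 2L, b, "+")
  list(y = array(y, c(d[1], d[2], ncol(Wm))), cols = cols)
}

conv_bwd <- function(dy, cols, Wm, xdim) {
  dym <- matrix(dy, ncol = dim(dy)[3])
  list(dW = crossprod(cols, dym), db = colSums(dym),
       dx = col2im3(dym %*% t(Wm), xdim))
}

pool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  cand <- cbind(as.vector(x[io, jo, , drop = FALSE]),
                as.vector(x[ie, jo, , drop = FALSE]),
                as.vector(x[io, je, , drop = FALSE]),
                as.vector(x[ie, je, , drop = FALSE]))
  mi <- max.col(cand, ties.method = "first")
  y <- array(cand[cbind(seq_len(nrow(cand)), mi)], c(H %/% 2L, W %/% 2L, C))
  list(y = y, mi = mi)
}

pool2_bwd <- function(dy, mi, xdim) {
  H <- xdim[1]; W <- xdim[2]; C <- xdim[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  # linear index of the top-left corner of each 2x2 block in the input
  i2 <- rep(seq(1L, H, 2L), times = W2 * C)
  j2 <- rep(rep(seq(1L, W, 2L), each = H2), times = C)
  c2 <- rep(seq_len(C), each = H2 * W2)
  di <- c(0L, 1L, 0L, 1L)[mi]
  dj <- c(0L, 0L, 1L, 1L)[mi]
  idx <- (i2 + di) + (j2 + dj - 1L) * H + (c2 - 1L) * H * W
  dx <- array(0, xdim)
  dx[idx] <- as.vector(dy)
  dx
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  dy[io, jo, , drop = FALSE] + dy[ie, jo, , drop = FALSE] +
    dy[io, je, , drop = FALSE] + dy[ie, je, , drop = FALSE]
}

init_seg_params <- function(spec, seed) {
  c1 <- spec$channels[1]; c2 <- spec$channels[2]; K <- spec$classes
  with_seed(seed, {
    he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                  sqrt(2 / nin)), nin, nout)
    cin <- if (spec$coord_channels) 3L else 1L
    # classifier reads the upsampled decoder features concatenated with the
    # full-resolution encoder features (skip connection)
    list(W1 = he(9L * cin, c1), b1 = numeric(c1),
         W2 = he(9L * c1, c2), b2 = numeric(c2),
         W3 = he(9L * c2, c2), b3 = numeric(c2),
         W4 = he(9L * c2, c1), b4 = numeric(c1),
         W5 = he(9L * 2L * c1, K), b5 = numeric(K))
  })
}

pad_to4 <- function(m, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  H2 <- as.integer(ceiling(H / 4) * 4); W2 <- as.integer(ceiling(W / 4) * 4)
  if (H2 == H && W2 == W) return(list(m = m, H = H, W = W))
  out <- matrix(fill, H2, W2)
  out[seq_len(H), seq_len(W)] <- m
  list(m = out, H = H, W = W)
}

seg_forward <- function(params, x, spec = NULL) {
  ic <- if (is.null(spec)) 0.5 else spec$input_center
  ig <- if (is.null(spec)) 10 else spec$input_gain
  cc <- if (is.null(spec)) TRUE else spec$coord_channels
  H <- nrow(x); W <- ncol(x)
  xs <- (x - ic) * ig
  if (cc) {
    ry <- matrix(seq(-1, 1, length.out = H), H, W)
    rx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    x <- array(c(xs, ry, rx), c(H, W, 3L))
  } else {
    x <- array(xs, c(H, W, 1L))
  }
  d1 <- dim(x)
  cv1 <- conv_fwd(x, params$W1, params$b1); a1 <- pmax(cv1$y, 0)
  pl1 <- pool2_fwd(a1)
  cv2 <- conv_fwd(pl1$y, params$W2, params$b2); a2 <- pmax(cv2$y, 0)
  pl2 <- pool2_fwd(a2)
  cv3 <- conv_fwd(pl2$y, params$W3, params$b3); a3 <- pmax(cv3$y, 0)
  u3 <- up2_fwd(a3)
  cv4 <- conv_fwd(u3, params$W4, params$b4); a4 <- pmax(cv4$y, 0)
  u4 <- up2_fwd(a4)
  skip <- array(c(u4, a1), c(dim(u4)[1:2], dim(u4)[3] + dim(a1)[3]))
  cv5 <- conv_fwd(skip, params$W5, params$b5)
  list(logits = cv5$y, cache = list(x = x, cv1 = cv1, a1 = a1, pl1 = pl1,
                                    cv2 = cv2, a2 = a2, pl2 = pl2, cv3 = cv3,
                                    a3 = a3, u3 = u3, cv4 = cv4, a4 = a4,
                                    u4 = u4, skip = skip, cv5 = cv5))
}

# Class-weighted cross-entropy over valid pixels and its logit gradient.
# `cw` is a length-K per-class weight vector (median-frequency balancing by
# default); unweighted when NULL.
softmax_ce <- function(logits, labels, valid, cw = NULL) {
  d <- dim(logits)
  lm <- matrix(logits, ncol = d[3])
  lm <- lm - apply(lm, 1L, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  lab <- as.vector(labels) + 1L
  v <- as.vector(valid)
  w <- if (is.null(cw)) as.numeric(v) else cw[lab] * v
  sw <- sum(w)
  loss <- -sum(w * log(pmax(p[cbind(seq_len(nrow(p)), lab)], 1e-12))) / sw
  g <- p
  g[cbind(seq_len(nrow(g)), lab)] <- g[cbind(seq_len(nrow(g)), lab)] - 1
  g <- g * (w / sw)
  list(loss = loss, dlogits = array(g, d))
}

# Softened median-frequency balancing: weight_c = sqrt(median(freq) /
# freq_c) over the classes present in the training labels; absent classes
# get weight 0. The square root lifts the rare structure classes enough to
# be learned without letting false-positive halos into the dominant
# background class go unpenalized.
class_weights <- function(labels, classes) {
  counts <- numeric(classes)
  for (l in labels) {
    tab <- tabulate(as.vector(l) + 1L, nbins = classes)
    counts <- counts + tab
  }
  freq <- counts / sum(counts)
  w <- numeric(classes)
  pres <- freq > 0
  w[pres] <- sqrt(stats::median(freq[pres]) / freq[pres])
  w
}

seg_backward <- function(params, fwd, dlogits) {
  ch <- fwd$cache
  g <- list()
  b5 <- conv_bwd(dlogits, ch$cv5$cols, params$W5, dim(ch$skip))
  g$W5 <- b5$dW; g$b5 <- b5$db
  nc4 <- dim(ch$u4)[3]
  dskip_u4 <- array(b5$dx[, , seq_len(nc4), drop = FALSE], dim(ch$u4))
  dskip_a1 <- array(b5$dx[, , -seq_len(nc4), drop = FALSE], dim(ch$a1))
  da4 <- up2_bwd(dskip_u4) * (ch$cv4$y > 0)
  b4 <- conv_bwd(da4, ch$cv4$cols, params$W4, dim(ch$u3))
  g$W4 <- b4$dW; g$b4 <- b4$db
  da3 <- up2_bwd(b4$dx) * (ch$cv3$y > 0)
  b3 <- conv_bwd(da3, ch$cv3$cols, params$W3, dim(ch$pl2$y))
  g$W3 <- b3$dW; g$b3 <- b3$db
  dp2 <- pool2_bwd(b3$dx, ch$pl2$mi, dim(ch$a2)) * (ch$cv2$y > 0)
  b2 <- conv_bwd(dp2, ch$cv2$cols, params$W2, dim(ch$pl1$y))
  g$W2 <- b2$dW; g$b2 <- b2$db
  dp1 <- (pool2_bwd(b2$dx, ch$pl1$mi, dim(ch$a1)) + dskip_a1) *
    (ch$cv1$y > 0)
  b1 <- conv_bwd(dp1, ch$cv1$cols, params$W1, dim(ch$x))
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (grepl("^W", nm)) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

sample_loss <- function(params, image, labels, config, cw = NULL, spec = NULL) {
  img <- normalize_ct(image, config$window_level, config$window_width)
  pi_ <- pad_to4(img)
  pl_ <- pad_to4(labels)
  valid <- matrix(FALSE, nrow(pi_$m), ncol(pi_$m))
  valid[seq_len(pi_$H), seq_len(pi_$W)] <- TRUE
  fwd <- seg_forward(params, pi_$m, spec)
  ce <- softmax_ce(fwd$logits, pl_$m, valid, cw)
  list(fwd = fwd, loss = ce$loss, dlogits = ce$dlogits)
}

#' Train the segmentation network
#'
#' Minibatch Adam training with per-pixel cross-entropy over the ten
#' classes, random crop/scale augmentation, a plateau learning-rate
#' schedule (the rate is divided by `decay_factor` whenever the tuning loss
#' fails to improve by more than `min_delta` for `patience` epochs), and
#' early stopping by checkpointing: the parameters after every epoch are
#' scored on the tuning set and the checkpoint with the lowest tuning loss
#' is returned.
#'
#' @param images list of raw intensity matrices (HU); [normalize_ct()] is
#'   applied internally.
#' @param labels list of integer label matrices (0..classes-1), parallel to
#'   `images`.
#' @param config a [train_config()].
#' @param spec a [seg_model_spec()].
#' @param tune_images,tune_labels the tuning set used for the schedule and
#'   checkpoint selection; must be nonempty. Normally disjoint from the
#'   training slices (passing the training set itself is only meaningful
#'   for deliberate overfitting checks).
#' @return An object of class `seg_model`: best parameters, spec, config,
#'   per-epoch `history` (train loss, tuning loss, learning rate) and the
#'   selected `best_epoch`.
#' @export
train_segmenter <- function(images, labels, config = train_config(),
                            spec = seg_model_spec(),
                            tune_images, tune_labels) {
  if (length(images) != length(labels) || !length(images))
    stopf("images and labels must be nonempty parallel lists")
  if (missing(tune_images) || missing(tune_labels) || !length(tune_images))
    stopf("tuning set must be nonempty")
  params <- init_seg_params(spec, derive_seed(config$seed, "init"))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        tune_loss = numeric(), lr = numeric())
  model <- structure(list(params = params, spec = spec, config = config,
                          history = history, best_epoch = NA_integer_,
                          best_tune_loss = NA_real_),
                     class = "seg_model")
  if (config$max_epochs < 1L) {
    warnf("max_epochs = %d: returning untrained model", config$max_epochs)
    return(model)
  }
  cw <- class_weights(labels, spec$classes)
  tune_loss <- function(p) {
    mean(vapply(seq_along(tune_images), function(i)
      sample_loss(p, tune_images[[i]], tune_labels[[i]], config, cw, spec)$loss,
      numeric(1)))
  }
  st <- adam_init(params)
  lr <- config$lr
  best <- params; best_loss <- Inf; best_epoch <- 0L
  since_improve <- 0L; since_event <- 0L
  n <- length(images)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle", epoch)),
                     sample.int(n))
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      grads <- NULL
      bl <- 0
      for (i in b) {
        img <- images[[i]]; lab <- labels[[i]]
        if (config$augment) {
          aug <- augment_pair(img, lab, config,
                              derive_seed(config$seed,
                                          paste0("aug", epoch, "_", i)))
          img <- aug$image; lab <- aug$labels
        }
        sl <- sample_loss(params, img, lab, config, cw, spec)
        gr <- seg_backward(params, sl$fwd, sl$dlogits)
        bl <- bl + sl$loss
        grads <- if (is.null(grads)) gr
                 else Map(`+`, grads, gr)
      }
      grads <- lapply(grads, function(g) g / length(b))
      upd <- adam_step(params, grads, st, lr, config$weight_decay)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + bl / length(b)
    }
    tl <- tune_loss(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / length(batches),
                                         tune_loss = tl, lr = lr))
    if (tl < best_loss - config$min_delta) {
      best <- params; best_loss <- tl; best_epoch <- epoch
      since_improve <- 0L; since_event <- 0L
    } else {
      if (tl < best_loss) { best <- params; best_loss <- tl; best_epoch <- epoch }
      since_improve <- since_improve + 1L
      since_event <- since_event + 1L
      # one x(1/decay_factor) drop per detected plateau
      if (since_event >= config$patience) {
        lr <- lr / config$decay_factor
        since_event <- 0L
      }
      if (since_improve >= config$stop_patience) break
    }
  }
  model$params <- best
  model$history <- history
  model$best_epoch <- best_epoch
  model$best_tune_loss <- best_loss
  model
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<seg_model>", np, "parameters,", nrow(x$history), "epochs trained,",
      "best epoch", x$best_epoch, "(tune loss",
      format(x$best_tune_loss, digits = 4), ")\n")
  invisible(x)
}

#' Predict structure labels for slices
#'
#' @param model a trained [train_segmenter()] model.
#' @param images list of raw intensity matrices (HU).
#' @return List of integer label matrices (0..classes-1).
#' @export
predict_segmenter <- function(model, images) {
  lapply(images, function(img) {
    nm <- normalize_ct(img, model$config$window_level,
                       model$config$window_width)
    pi_ <- pad_to4(nm)
    lg <- seg_forward(model$params, pi_$m, model$spec)$logits
    pred <- apply(lg, c(1, 2), which.max) - 1L
    pred[seq_len(pi_$H), seq_len(pi_$W), drop = FALSE]
  })
}

# Per-structure IoU between predicted and reference label slices of one
# case, computed on the voxel union of the case's slices.
case_structure_iou <- function(pred_slices, ref_slices, n_struct = 9L) {
  vapply(seq_len(n_struct), function(s) {
    inter <- 0L; un <- 0L
    for (i in seq_along(pred_slices)) {
      p <- pred_slices[[i]] == s
      r <- ref_slices[[i]] == s
      inter <- inter + sum(p & r)
      un <- un + sum(p | r)
    }
    if (un == 0L) 1 else inter / un
  }, numeric(1))
}

#' Cross-validated per-structure IoU report
#'
#' Runs the k-fold protocol over cases (one case = one visit's slice
#' stack): each fold's cases are predicted by a model trained only on the
#' other folds, so every case is predicted exactly once by a model that
#' never saw it. Within the training folds one case is held out as the
#' tuning set. Emits a 9 x (k + 1) report: per-structure IoU per fold
#' (averaged over the fold's cases, each case pooled over its slices) plus
#' the mean across folds.
#'
#' @param cases list of cases; each case is `list(images = <list of HU
#'   matrices>, labels = <list of label matrices>)`.
#' @param k number of folds.
#' @param seed partition seed.
#' @param config,spec training settings.
#' @param predictor optional function `(images) -> list of label matrices`
#'   used instead of training a model (e.g. an oracle for protocol tests).
#' @return Matrix with 9 structure rows and columns `fold1..foldk, mean`,
#'   with the fold assignment in attribute `"folds"`.
#' @export
evaluate_folds <- function(cases, k = 5L, seed = 1L,
                           config = train_config(), spec = seg_model_spec(),
                           predictor = NULL) {
  n <- length(cases)
  if (n < k) stopf("need at least k = %d cases, got %d", k, n)
  fold_of <- assign_subsets(n, k, derive_seed(seed, "folds"))
  res <- matrix(NA_real_, 9L, k,
                dimnames = list(structure_names(), paste0("fold", seq_len(k))))
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (is.null(predictor)) {
      tune_idx <- train_idx[1]
      fit_idx <- if (length(train_idx) > 1L) train_idx[-1] else train_idx
      imgs <- unlist(lapply(cases[fit_idx], `[[`, "images"), recursive = FALSE)
      labs <- unlist(lapply(cases[fit_idx], `[[`, "labels"), recursive = FALSE)
      timgs <- unlist(lapply(cases[tune_idx], `[[`, "images"), recursive = FALSE)
      tlabs <- unlist(lapply(cases[tune_idx], `[[`, "labels"), recursive = FALSE)
      model <- train_segmenter(imgs, labs, config, spec, timgs, tlabs)
      pred_fun <- function(images) predict_segmenter(model, images)
    } else pred_fun <- predictor
    ious <- vapply(test_idx, function(ci) {
      case_structure_iou(pred_fun(cases[[ci]]$images), cases[[ci]]$labels)
    }, numeric(9))
    res[, f] <- rowMeans(matrix(ious, nrow = 9L))
  }
  out <- cbind(res, mean = rowMeans(res))
  attr(out, "folds") <- fold_of
  out
}
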