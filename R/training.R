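#' Pixel-wise cross-entropy loss for segmentation
#'
#' Softmax over the two class channels at every pixel, then the negative
#' log-likelihood of the true class, numerically stabilized via log-sum-exp.
#' The default reduction averages over pixels and batch so the loss is
#' comparable across image sizes; `reduction = "sum"` gives the unnormalized
#' total.
#'
#' @param logits Array `dim = c(2, H, W)` or `c(2, H, W, N)` of class scores.
#' @param gt Integer matrix `H x W` (or array `H x W x N`) over \{0, 1\}.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Nonnegative scalar loss; 0 iff the prediction puts probability 1
#'   on the true class at every pixel.
#' @export
cross_entropy_loss <- function(logits, gt, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  ce_seg(logits, gt)$loss * (if (reduction == "sum") ce_count(logits) else 1)
}

ce_count <- function(logits) {
  d <- dim(logits)
  prod(d[-1])
}

# loss + gradient; logits (2,H,W[,N]), gt same spatial dims
ce_seg <- function(logits, gt) {
  d <- dim(logits)
  if (is.null(d) || d[1] != 2L) stop_shape("logits must have 2 class channels")
  if (length(d) == 3L) dim(logits) <- c(d, 1L)
  d <- dim(logits)
  if (!identical(as.integer(dim(gt)[1:2]), as.integer(d[2:3])))
    stop_shape("logits and ground truth disagree on height/width")
  g <- as.double(gt)
  l0 <- logits[1, , , ]; l1 <- logits[2, , , ]
  m <- pmax(l0, l1)
  lse <- m + log(exp(l0 - m) + exp(l1 - m))
  lt <- ifelse(g == 1, l1, l0)
  M <- length(l0)
  loss <- sum(lse - lt) / M
  p1 <- exp(l1 - lse)
  dl <- array(0, d)
  dl[1, , , ] <- ((1 - p1) - (1 - g)) / M  # p0 - (1 - ygt)
  dl[2, , , ] <- (p1 - g) / M
  list(loss = loss, dlogits = dl)
}

# image-level (classifier) cross entropy: logits (2,N), labels in {0,1}
ce_cls <- function(logits, labels) {
  N <- ncol(logits)
  m <- pmax(logits[1, ], logits[2, ])
  lse <- m + log(exp(logits[1, ] - m) + exp(logits[2, ] - m))
  lt <- ifelse(labels == 1, logits[2, ], logits[1, ])
  loss <- sum(lse - lt) / N
  p1 <- exp(logits[2, ] - lse)
  dl <- rbind((1 - p1) - (1 - labels), p1 - labels) / N
  list(loss = loss, dlogits = dl)
}

#' Exponentially decayed learning rate
#'
#' The rate at (0-based) epoch `j` is `alpha^j * v0`, so epoch 0 uses the
#' initial rate exactly and consecutive epochs decay by the constant factor
#' `alpha`.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param v0 Initial learning rate (default `1e-4`).
#' @param alpha Per-epoch decay coefficient in (0, 1\] (default 0.99).
#' @return The learning rate(s) at `epoch`.
#' @export
lr_at_epoch <- function(epoch, v0 = 1e-4, alpha = 0.99) {
  if (v0 <= 0) stop_config("v0 must be positive")
  if (alpha <= 0 || alpha > 1) stop_config("alpha must be in (0, 1]")
  if (any(epoch < 0)) stop_config("epoch must be >= 0")
  alpha^epoch * v0
}

#' Training configuration
#'
#' Reference-scale defaults: backbone pre-training runs 200 epochs at batch
#' size 32; segmentation training runs 150 epochs at batch size 16; both use
#' Adam with initial learning rate `1e-4` decayed by 0.99 per epoch. Desk
#' scale overrides `epochs`/`batch_size` downwards.
#'
#' @param phase `"segment"` or `"pretrain"`.
#' @param epochs,batch_size Override the phase defaults.
#' @param v0,alpha Learning-rate schedule, see [lr_at_epoch()].
#' @param seed Integer RNG seed for the run (weights, shuffling, augmentation).
#' @param augment Apply random augmentation to the training split.
#' @return A `coralseg_train_config` list.
#' @export
train_config <- function(phase = c("segment", "pretrain"), epochs = NULL,
                         batch_size = NULL, v0 = 1e-4, alpha = 0.99,
                         seed = 1L, augment = TRUE) {
  phase <- match.arg(phase)
  cfg <- list(
    phase = phase,
    epochs = as.integer(epochs %||% if (phase == "pretrain") 200L else 150L),
    batch_size = as.integer(batch_size %||% if (phase == "pretrain") 32L else 16L),
    v0 = v0, alpha = alpha, seed = as.integer(seed), augment = isTRUE(augment)
  )
  class(cfg) <- "coralseg_train_config"
  cfg
}

# Load images (and masks) for manifest rows into batch arrays.
load_arrays <- function(rows, need_masks = FALSE) {
  n <- nrow(rows)
  if (n == 0) stop_data("empty data split")
  img1 <- load_gray_image(rows$image_path[1])
  side <- nrow(img1)
  x <- array(0, c(1L, side, side, n))
  msk <- if (need_masks) array(0L, c(side, side, n)) else NULL
  for (i in seq_len(n)) {
    im <- if (i == 1) img1 else load_gray_image(rows$image_path[i])
    if (nrow(im) != side || ncol(im) != side)
      im <- resize_to_canonical(pad_to_square(im), side)
    x[1, , , i] <- im
    if (need_masks) {
      if (is.na(rows$mask_path[i]))
        stop_data(sprintf("record '%s' has no mask", rows$image_path[i]))
      mk <- load_mask(rows$mask_path[i])
      if (nrow(mk) != side || ncol(mk) != side)
        mk <- binarize_mask(resize_to_canonical(pad_to_square(mk), side, "nearest"))
      msk[, , i] <- mk
    }
  }
  list(x = x, masks = msk, labels = as.integer(rows$image_label), side = side)
}

# Precise batch-norm refresh: recompute every layer's normalization
# statistics in one training-mode pass over the (unaugmented) training set
# with momentum 1, so evaluation-mode forward passes see converged moments
# even after short desk-scale runs.
refresh_bn_backbone <- function(P, Bf, model_cfg, x) {
  ctx <- new_ctx(P, Bf, training = TRUE, bn_momentum = 1)
  backbone_fwd(ctx, x, model_cfg)
  ctx$B
}

refresh_bn_model <- function(P, Bf, model_cfg, x) {
  ctx <- new_ctx(P, Bf, training = TRUE, bn_momentum = 1)
  model_fwd(ctx, x, model_cfg)
  ctx$B
}

split_rows <- function(manifest) {
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0) stop_data("training split is empty")
  list(train = tr, val = va)
}

augment_batch <- function(xb, maskb = NULL) {
  n <- dim(xb)[4]
  for (i in seq_len(n)) {
    im <- matrix(xb[1, , , i], dim(xb)[2], dim(xb)[3])
    mk <- if (!is.null(maskb)) maskb[, , i] else
      matrix(0L, dim(xb)[2], dim(xb)[3])
    a <- augment_pair(im, mk)
    xb[1, , , i] <- a$image
    if (!is.null(maskb)) maskb[, , i] <- a$mask
  }
  list(x = xb, masks = maskb)
}

#' Pre-train the backbone as an image-level coral classifier
#'
#' Attaches global average pooling and a 2-class linear head to the backbone
#' and trains on image-level labels (1 = contains coral) with Adam and the
#' exponential learning-rate schedule. Training-split images are randomly
#' augmented (when `config$augment`); the validation split never is.
#'
#' @param manifest Data.frame from [read_manifest()] (or [generate_dataset()]):
#'   needs `image_path`, `image_label`, `split`.
#' @param config A [train_config()] (phase `"pretrain"`).
#' @param model_cfg A [model_config()].
#' @return A `coralseg_backbone` with classifier head, plus `$history`, a
#'   data.frame of per-epoch `epoch`, `lr`, `train_loss`, `val_loss`,
#'   `val_accuracy`.
#' @export
pretrain_backbone <- function(manifest, config = train_config("pretrain"),
                              model_cfg = model_config()) {
  set.seed(config$seed)
  sp <- split_rows(manifest)
  tr <- load_arrays(sp$train)
  va <- if (nrow(sp$val) > 0) load_arrays(sp$val) else NULL
  bb <- build_backbone(model_cfg)
  P <- bb$params
  P <- init_linear_params(P, "clf", model_cfg$stage_channels[3], 2L)
  Bf <- bb$buffers
  opt <- adam_init(P, lr = config$v0)
  ntr <- dim(tr$x)[4]
  hist <- data.frame()
  for (ep in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(ep, config$v0, config$alpha)
    ord <- sample.int(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      xb <- tr$x[, , , bi, drop = FALSE]
      if (config$augment) xb <- augment_batch(xb)$x
      ctx <- new_ctx(P, Bf, training = TRUE)
      high <- backbone_fwd(ctx, xb, model_cfg)$high
      g <- fwd_gap(ctx, high, "clf.gap")
      logit <- fwd_linear(ctx, g, "clf")
      ce <- ce_cls(logit, tr$labels[bi])
      dg <- bwd_linear(ctx, ce$dlogits, "clf")
      dhigh <- bwd_gap(ctx, dg, "clf.gap")
      backbone_bwd(ctx, dhigh, NULL, model_cfg)
      Bf <- ctx$B
      st <- adam_step(opt, P, ctx$grad, lr = lr)
      opt <- st$state; P <- st$params
      tl <- tl + ce$loss * length(bi)
    }
    tl <- tl / ntr
    Bf <- refresh_bn_backbone(P, Bf, model_cfg, tr$x)
    vl <- NA_real_; vacc <- NA_real_
    if (!is.null(va)) {
      ev <- classify_images(P, Bf, model_cfg, va$x)
      vl <- ce_cls(ev, va$labels)$loss
      vacc <- mean((ev[2, ] > ev[1, ]) == (va$labels == 1))
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl,
                                   val_loss = vl, val_accuracy = vacc))
  }
  structure(list(params = P, buffers = Bf, config = model_cfg,
                 history = hist, seed = config$seed),
            class = "coralseg_backbone")
}

classify_images <- function(P, Bf, model_cfg, x) {
  ctx <- new_ctx(P, Bf, training = FALSE)
  high <- backbone_fwd(ctx, x, model_cfg)$high
  g <- fwd_gap(ctx, high, "clf.gap")
  fwd_linear(ctx, g, "clf")
}

#' Predict image-level coral presence with a pre-trained backbone
#'
#' @param backbone A `coralseg_backbone` from [pretrain_backbone()].
#' @param x Batch array `dim = c(1, S, S, N)` or a single `S x S` matrix.
#' @return Integer vector of predicted labels (1 = coral present).
#' @export
classify_backbone <- function(backbone, x) {
  if (is.matrix(x)) x <- array(as.double(x), c(1L, nrow(x), ncol(x), 1L))
  logit <- classify_images(backbone$params, backbone$buffers, backbone$config, x)
  as.integer(logit[2, ] > logit[1, ])
}

#' Train the full segmentation network
#'
#' Trains the encoder-decoder with pixel-wise cross entropy, Adam, and the
#' exponential learning-rate schedule; shuffled mini-batches each epoch (last
#' partial batch kept), paired random augmentation of the training split only.
#' Optionally starts from a pre-trained backbone and saves a checkpoint per
#' epoch so segmentation snapshots across training are reproducible.
#'
#' @param manifest Data.frame with `image_path`, `mask_path`, `split`.
#' @param config A [train_config()] (phase `"segment"`).
#' @param model_cfg A [model_config()].
#' @param backbone_init Optional `coralseg_backbone` from [pretrain_backbone()].
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @return A `coralseg_model` with `$history` (per-epoch `epoch`, `lr`,
#'   `train_loss`, `val_loss`).
#' @export
train_segmentation <- function(manifest, config = train_config("segment"),
                               model_cfg = model_config(),
                               backbone_init = NULL, checkpoint_dir = NULL) {
  set.seed(config$seed)
  sp <- split_rows(manifest)
  tr <- load_arrays(sp$train, need_masks = TRUE)
  va <- if (nrow(sp$val) > 0) load_arrays(sp$val, need_masks = TRUE) else NULL
  model <- build_model(model_cfg, backbone_init = backbone_init)
  P <- model$params; Bf <- model$buffers
  opt <- adam_init(P, lr = config$v0)
  ntr <- dim(tr$x)[4]
  hist <- data.frame()
  for (ep in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(ep, config$v0, config$alpha)
    ord <- sample.int(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      xb <- tr$x[, , , bi, drop = FALSE]
      mb <- tr$masks[, , bi, drop = FALSE]
      if (config$augment) {
        a <- augment_batch(xb, mb)
        xb <- a$x; mb <- a$masks
      }
      ctx <- new_ctx(P, Bf, training = TRUE)
      logits <- model_fwd(ctx, xb, model_cfg)
      ce <- ce_seg(logits, mb)
      model_bwd(ctx, ce$dlogits, model_cfg)
      Bf <- ctx$B
      st <- adam_step(opt, P, ctx$grad, lr = lr)
      opt <- st$state; P <- st$params
      tl <- tl + ce$loss * length(bi)
    }
    tl <- tl / ntr
    Bf <- refresh_bn_model(P, Bf, model_cfg, tr$x)
    vl <- NA_real_
    if (!is.null(va)) {
      ctx <- new_ctx(P, Bf, training = FALSE)
      vlogits <- model_fwd(ctx, va$x, model_cfg)
      vl <- ce_seg(vlogits, va$masks)$loss
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl,
                                   val_loss = vl))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      m <- structure(list(params = P, buffers = Bf, config = model_cfg),
                     class = "coralseg_model")
      save_checkpoint(m, file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep)),
                      seed = config$seed)
    }
  }
  structure(list(params = P, buffers = Bf, config = model_cfg,
                 history = hist, seed = config$seed),
            class = "coralseg_model")
}
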