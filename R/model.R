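#' Model configuration for the coral segmentation network
#'
#' The network is an encoder-decoder: a ResNet34 backbone pruned of its last
#' residual stage (stem + three stages with 3/4/6 basic blocks, i.e. 26
#' convolutions inside the residual stages) feeding an atrous spatial pyramid
#' pooling (ASPP) head, fused with a space-to-depth compressed low-level path,
#' decoded through large-kernel convolutions, a depth-to-space expansion and
#' bilinear interpolation back to input resolution. All widths scale with a
#' single `width_multiplier` so the same architecture trains on a CPU at desk
#' scale (`width_multiplier = 0.25`, 64-pixel inputs) or at full scale
#' (`width_multiplier = 1`, 512-pixel inputs).
#'
#' @param input_side Input image side in pixels; must be divisible by 16.
#' @param width_multiplier Scales every channel width (default 1 = full size:
#'   stem 64, stages 64/128/256, ASPP 256).
#' @param num_classes Number of output classes (2: background, coral).
#' @param aspp_rates Four dilation coefficients for the parallel atrous
#'   branches (rate 1 is realized as a 1x1 convolution).
#' @param s2d_block Space-to-depth / depth-to-space block factor.
#' @param fusion_kernel Kernel size of the two fusion convolutions applied
#'   after concatenating low- and high-level features (odd).
#' @param in_channels Input channels (1: single-band imagery).
#' @return A `coralseg_config` list of resolved architecture hyperparameters.
#' @export
model_config <- function(input_side = 512L, width_multiplier = 1,
                         num_classes = 2L, aspp_rates = c(1L, 6L, 12L, 18L),
                         s2d_block = 4L, fusion_kernel = 7L, in_channels = 1L) {
  if (input_side %% 16L != 0L)
    stop_config("input_side must be divisible by 16")
  if (length(aspp_rates) != 4L) stop_config("aspp_rates must have 4 elements")
  if (fusion_kernel %% 2L != 1L) stop_config("fusion_kernel must be odd")
  wm <- function(x) max(4L, as.integer(round(x * width_multiplier)))
  cfg <- list(
    input_side = as.integer(input_side),
    in_channels = as.integer(in_channels),
    width_multiplier = width_multiplier,
    stem_channels = wm(64),
    stage_blocks = c(3L, 4L, 6L),
    stage_channels = c(wm(64), wm(128), wm(256)),
    aspp_rates = as.integer(aspp_rates),
    aspp_out_channels = wm(256),
    lowlevel_reduced_channels = wm(32),
    s2d_block = as.integer(s2d_block),
    fusion_kernel = as.integer(fusion_kernel),
    fusion_channels = wm(256),
    num_classes = as.integer(num_classes)
  )
  class(cfg) <- "coralseg_config"
  cfg
}

#' Count the convolutions inside the backbone's residual stages
#'
#' Each basic residual block holds two 3x3 convolutions; with the pruned
#' stage plan of 3 + 4 + 6 blocks this census is 26. Stem and 1x1 shortcut
#' projections are excluded from the count.
#'
#' @param config A [model_config()].
#' @return Integer convolution count.
#' @export
count_residual_convs <- function(config) {
  sum(2L * config$stage_blocks)
}

## ---- parameter construction ------------------------------------------------

init_block <- function(P, Bf, name, cin, cout, stride) {
  P <- init_conv_params(P, paste0(name, ".conv1"), cin, cout, 3L)
  P <- init_bn_params(P, paste0(name, ".bn1"), cout)
  P <- init_conv_params(P, paste0(name, ".conv2"), cout, cout, 3L)
  P <- init_bn_params(P, paste0(name, ".bn2"), cout)
  Bf <- init_bn_buffers(Bf, paste0(name, ".bn1"), cout)
  Bf <- init_bn_buffers(Bf, paste0(name, ".bn2"), cout)
  if (cin != cout || stride != 1L) {
    P <- init_conv_params(P, paste0(name, ".proj"), cin, cout, 1L)
    P <- init_bn_params(P, paste0(name, ".projbn"), cout)
    Bf <- init_bn_buffers(Bf, paste0(name, ".projbn"), cout)
  }
  list(P = P, B = Bf)
}

#' Build the pruned ResNet34 backbone
#'
#' Stem: 7x7 stride-2 convolution, batch normalization, ReLU, then 3x3
#' stride-2 max pooling, producing low-level features at output stride 4.
#' Three residual stages of basic blocks (`y = F(x) + x`) follow with block
#' counts 3/4/6; stages 2 and 3 halve resolution, so the high-level output
#' sits at stride 16 with `stage_channels[3]` channels (256 at full width).
#'
#' Parameters are drawn from the current RNG state (He fan-in scaling); seed
#' before calling for reproducible builds.
#'
#' @param config A [model_config()].
#' @param zero_init_residual If `TRUE`, the scale of each block's last batch
#'   normalization starts at 0 so every block initially computes the identity
#'   (its residual branch F(x) contributes nothing).
#' @return A `coralseg_backbone` list with `params`, `buffers`, `config`.
#' @export
build_backbone <- function(config, zero_init_residual = FALSE) {
  P <- list(); Bf <- list()
  P <- init_conv_params(P, "stem.conv", config$in_channels, config$stem_channels, 7L)
  P <- init_bn_params(P, "stem.bn", config$stem_channels)
  Bf <- init_bn_buffers(Bf, "stem.bn", config$stem_channels)
  cin <- config$stem_channels
  for (s in 1:3) {
    cout <- config$stage_channels[s]
    for (b in seq_len(config$stage_blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      nm <- sprintf("s%d.b%d", s, b)
      r <- init_block(P, Bf, nm, cin, cout, stride)
      P <- r$P; Bf <- r$B
      if (zero_init_residual)
        P[[paste0(nm, ".bn2.gamma")]] <- numeric(cout)
      cin <- cout
    }
  }
  structure(list(params = P, buffers = Bf, config = config),
            class = "coralseg_backbone")
}

block_fwd <- function(ctx, x, name, stride) {
  h <- fwd_conv(ctx, x, paste0(name, ".conv1"), stride = stride)
  h <- fwd_bn(ctx, h, paste0(name, ".bn1"))
  h <- fwd_relu(ctx, h, paste0(name, ".relu1"))
  h <- fwd_conv(ctx, h, paste0(name, ".conv2"))
  h <- fwd_bn(ctx, h, paste0(name, ".bn2"))
  if (!is.null(ctx$P[[paste0(name, ".proj.w")]])) {
    sc <- fwd_conv(ctx, x, paste0(name, ".proj"), stride = stride, pad = 0L)
    sc <- fwd_bn(ctx, sc, paste0(name, ".projbn"))
  } else sc <- x
  fwd_relu(ctx, h + sc, paste0(name, ".reluout"))
}

block_bwd <- function(ctx, dy, name) {
  dy <- bwd_relu(ctx, dy, paste0(name, ".reluout"))
  # residual branch
  dh <- bwd_bn(ctx, dy, paste0(name, ".bn2"))
  dh <- bwd_conv(ctx, dh, paste0(name, ".conv2"))
  dh <- bwd_relu(ctx, dh, paste0(name, ".relu1"))
  dh <- bwd_bn(ctx, dh, paste0(name, ".bn1"))
  dx <- bwd_conv(ctx, dh, paste0(name, ".conv1"))
  # shortcut
  if (!is.null(ctx$P[[paste0(name, ".proj.w")]])) {
    ds <- bwd_bn(ctx, dy, paste0(name, ".projbn"))
    dx <- dx + bwd_conv(ctx, ds, paste0(name, ".proj"))
  } else dx <- dx + dy
  dx
}

# Forward through the backbone; returns list(low, high) feature maps at
# strides 4 and 16.
backbone_fwd <- function(ctx, x, config) {
  h <- fwd_conv(ctx, x, "stem.conv", stride = 2L, pad = 3L)
  h <- fwd_bn(ctx, h, "stem.bn")
  h <- fwd_relu(ctx, h, "stem.relu")
  low <- fwd_maxpool(ctx, h, "stem.pool")
  h <- low
  for (s in 1:3)
    for (b in seq_len(config$stage_blocks[s]))
      h <- block_fwd(ctx, h, sprintf("s%d.b%d", s, b),
                     stride = if (s > 1 && b == 1) 2L else 1L)
  list(low = low, high = h)
}

backbone_bwd <- function(ctx, dhigh, dlow, config) {
  dh <- dhigh
  for (s in 3:1)
    for (b in rev(seq_len(config$stage_blocks[s])))
      dh <- block_bwd(ctx, dh, sprintf("s%d.b%d", s, b))
  if (!is.null(dlow)) dh <- dh + dlow
  dh <- bwd_maxpool(ctx, dh, "stem.pool")
  dh <- bwd_relu(ctx, dh, "stem.relu")
  dh <- bwd_bn(ctx, dh, "stem.bn")
  bwd_conv(ctx, dh, "stem.conv")
}

## ---- ASPP ------------------------------------------------------------------

init_aspp <- function(P, Bf, cin, cout, rates) {
  for (i in seq_along(rates)) {
    k <- if (rates[i] == 1L) 1L else 3L
    P <- init_conv_params(P, sprintf("aspp.b%d.conv", i), cin, cout, k)
    P <- init_bn_params(P, sprintf("aspp.b%d.bn", i), cout)
    Bf <- init_bn_buffers(Bf, sprintf("aspp.b%d.bn", i), cout)
  }
  P <- init_conv_params(P, "aspp.gap.conv", cin, cout, 1L)
  P <- init_bn_params(P, "aspp.gap.bn", cout)
  Bf <- init_bn_buffers(Bf, "aspp.gap.bn", cout)
  P <- init_conv_params(P, "aspp.proj.conv", cout * 5L, cout, 1L)
  P <- init_bn_params(P, "aspp.proj.bn", cout)
  Bf <- init_bn_buffers(Bf, "aspp.proj.bn", cout)
  list(P = P, B = Bf)
}

aspp_fwd <- function(ctx, x, rates) {
  d <- dim(x)
  branches <- vector("list", 5L)
  for (i in seq_along(rates)) {
    dil <- rates[i]
    h <- fwd_conv(ctx, x, sprintf("aspp.b%d.conv", i), dil = if (dil == 1L) 1L else dil)
    h <- fwd_bn(ctx, h, sprintf("aspp.b%d.bn", i))
    branches[[i]] <- fwd_relu(ctx, h, sprintf("aspp.b%d.relu", i))
  }
  # global-average-pooling branch: pool, 1x1 conv + BN + ReLU on the 1x1 map,
  # then bilinear enlargement back to the grid (constant broadcast)
  g <- fwd_gap(ctx, x, "aspp.gap.pool")            # (C,N)
  g4 <- array(g, c(d[1], 1L, 1L, d[4]))
  h <- fwd_conv(ctx, g4, "aspp.gap.conv", pad = 0L)
  h <- fwd_bn(ctx, h, "aspp.gap.bn")
  h <- fwd_relu(ctx, h, "aspp.gap.relu")
  ctx$cache[["aspp.gap.bcast"]] <- c(d[2], d[3])
  hb <- array(0, c(dim(h)[1], d[2], d[3], d[4]))
  for (n in seq_len(d[4]))
    hb[, , , n] <- array(rep(h[, 1, 1, n], d[2] * d[3]), c(dim(h)[1], d[2], d[3]))
  branches[[5]] <- hb
  cat_ch <- vapply(branches, function(b) dim(b)[1], integer(1))
  ctx$cache[["aspp.cat"]] <- cat_ch
  out <- array(0, c(sum(cat_ch), d[2], d[3], d[4]))
  off <- 0L
  for (b in branches) {
    out[off + seq_len(dim(b)[1]), , , ] <- b
    off <- off + dim(b)[1]
  }
  h <- fwd_conv(ctx, out, "aspp.proj.conv", pad = 0L)
  h <- fwd_bn(ctx, h, "aspp.proj.bn")
  fwd_relu(ctx, h, "aspp.proj.relu")
}

aspp_bwd <- function(ctx, dy, rates) {
  dy <- bwd_relu(ctx, dy, "aspp.proj.relu")
  dy <- bwd_bn(ctx, dy, "aspp.proj.bn")
  dcat <- bwd_conv(ctx, dy, "aspp.proj.conv")
  cat_ch <- ctx$cache[["aspp.cat"]]
  off <- 0L
  dx <- NULL
  for (i in seq_along(rates)) {
    db <- dcat[off + seq_len(cat_ch[i]), , , , drop = FALSE]
    off <- off + cat_ch[i]
    db <- bwd_relu(ctx, db, sprintf("aspp.b%d.relu", i))
    db <- bwd_bn(ctx, db, sprintf("aspp.b%d.bn", i))
    db <- bwd_conv(ctx, db, sprintf("aspp.b%d.conv", i))
    dx <- if (is.null(dx)) db else dx + db
  }
  # GAP branch: broadcast gradient sums over the grid
  db <- dcat[off + seq_len(cat_ch[5]), , , , drop = FALSE]
  dn <- dim(db)
  dh <- array(0, c(dn[1], 1L, 1L, dn[4]))
  for (n in seq_len(dn[4]))
    dh[, 1, 1, n] <- rowSums(matrix(db[, , , n], nrow = dn[1]))
  dh <- bwd_relu(ctx, dh, "aspp.gap.relu")
  dh <- bwd_bn(ctx, dh, "aspp.gap.bn")
  dg4 <- bwd_conv(ctx, dh, "aspp.gap.conv")
  dg <- matrix(dg4, nrow = dim(dg4)[1])
  dx + bwd_gap(ctx, dg, "aspp.gap.pool")
}

## ---- full model ------------------------------------------------------------

#' Build the full coral segmentation network
#'
#' Assembles backbone, ASPP, the space-to-depth low-level path, the
#' large-kernel fusion decoder, the depth-to-space + bilinear up-sampling
#' prediction head, and the class-activation-map (CAM) head.
#'
#' @inheritParams build_backbone
#' @param backbone_init Optional `coralseg_backbone` (e.g. pre-trained with
#'   [pretrain_backbone()]) whose parameters seed the encoder.
#' @return A `coralseg_model` list with `params`, `buffers`, `config`.
#' @export
build_model <- function(config, backbone_init = NULL, zero_init_residual = FALSE) {
  bb <- build_backbone(config, zero_init_residual = zero_init_residual)
  P <- bb$params; Bf <- bb$buffers
  if (!is.null(backbone_init)) {
    # adopt only backbone parameters (drop e.g. the pre-training classifier head)
    for (nm in intersect(names(backbone_init$params), names(P)))
      P[[nm]] <- backbone_init$params[[nm]]
    for (nm in intersect(names(backbone_init$buffers), names(Bf)))
      Bf[[nm]] <- backbone_init$buffers[[nm]]
  }
  r <- init_aspp(P, Bf, config$stage_channels[3], config$aspp_out_channels,
                 config$aspp_rates)
  P <- r$P; Bf <- r$B
  # low-level path: 1x1 reduction then space-to-depth to stride 16
  P <- init_conv_params(P, "low.conv", config$stem_channels,
                        config$lowlevel_reduced_channels, 1L)
  P <- init_bn_params(P, "low.bn", config$lowlevel_reduced_channels)
  Bf <- init_bn_buffers(Bf, "low.bn", config$lowlevel_reduced_channels)
  fused_in <- config$aspp_out_channels +
    config$lowlevel_reduced_channels * config$s2d_block^2
  P <- init_conv_params(P, "fuse.conv1", fused_in, config$fusion_channels,
                        config$fusion_kernel)
  P <- init_bn_params(P, "fuse.bn1", config$fusion_channels)
  Bf <- init_bn_buffers(Bf, "fuse.bn1", config$fusion_channels)
  P <- init_conv_params(P, "fuse.conv2", config$fusion_channels,
                        config$fusion_channels, config$fusion_kernel)
  P <- init_bn_params(P, "fuse.bn2", config$fusion_channels)
  Bf <- init_bn_buffers(Bf, "fuse.bn2", config$fusion_channels)
  # prediction head: 1x1 to num_classes * s2d_block^2, depth-to-space,
  # then bilinear x4 to full resolution
  P <- init_conv_params(P, "pred.conv", config$fusion_channels,
                        config$num_classes * config$s2d_block^2, 1L)
  # CAM head: 1x1 conv to two response maps + scalar class weights and bias
  P <- init_conv_params(P, "cam.conv", config$fusion_channels, 2L, 1L)
  P[["cam.w"]] <- c(1, 1)
  P[["cam.bias"]] <- 0
  structure(list(params = P, buffers = Bf, config = config),
            class = "coralseg_model")
}

# Forward to the fused decoder features (stride 16). Returns the fused map.
fused_features_fwd <- function(ctx, x, config) {
  bb <- backbone_fwd(ctx, x, config)
  high <- aspp_fwd(ctx, bb$high, config$aspp_rates)
  lowr <- fwd_conv(ctx, bb$low, "low.conv", pad = 0L)
  lowr <- fwd_bn(ctx, lowr, "low.bn")
  lowr <- fwd_relu(ctx, lowr, "low.relu")
  lows <- fwd_s2d(ctx, lowr, "low.s2d", config$s2d_block)
  h <- fwd_concat(ctx, lows, high, "fuse.cat")
  h <- fwd_conv(ctx, h, "fuse.conv1")
  h <- fwd_bn(ctx, h, "fuse.bn1")
  h <- fwd_relu(ctx, h, "fuse.relu1")
  h <- fwd_conv(ctx, h, "fuse.conv2")
  h <- fwd_bn(ctx, h, "fuse.bn2")
  fwd_relu(ctx, h, "fuse.relu2")
}

fused_features_bwd <- function(ctx, dy, config) {
  dy <- bwd_relu(ctx, dy, "fuse.relu2")
  dy <- bwd_bn(ctx, dy, "fuse.bn2")
  dy <- bwd_conv(ctx, dy, "fuse.conv2")
  dy <- bwd_relu(ctx, dy, "fuse.relu1")
  dy <- bwd_bn(ctx, dy, "fuse.bn1")
  dy <- bwd_conv(ctx, dy, "fuse.conv1")
  sp <- bwd_concat(ctx, dy, "fuse.cat")
  dlow <- bwd_s2d(ctx, sp$da, "low.s2d")
  dlow <- bwd_relu(ctx, dlow, "low.relu")
  dlow <- bwd_bn(ctx, dlow, "low.bn")
  dlow <- bwd_conv(ctx, dlow, "low.conv")
  dhigh <- aspp_bwd(ctx, sp$db, config$aspp_rates)
  backbone_bwd(ctx, dhigh, dlow, config)
}

# Full forward: returns logits (num_classes, S, S, N)
model_fwd <- function(ctx, x, config) {
  fused <- fused_features_fwd(ctx, x, config)
  h <- fwd_conv(ctx, fused, "pred.conv", pad = 0L)
  h <- fwd_d2s(ctx, h, "pred.d2s", config$s2d_block)
  side <- dim(x)[2]
  fwd_bilinear(ctx, h, "pred.up", side, side)
}

model_bwd <- function(ctx, dlogits, config) {
  dy <- bwd_bilinear(ctx, dlogits, "pred.up")
  dy <- bwd_d2s(ctx, dy, "pred.d2s")
  dy <- bwd_conv(ctx, dy, "pred.conv")
  fused_features_bwd(ctx, dy, config)
}

#' Run the segmentation network on a gray image
#'
#' @param model A `coralseg_model` (see [build_model()], [train_segmentation()]).
#' @param img Numeric `H x W` matrix in `[0, 1]` with side divisible by 16,
#'   or a batch array `dim = c(1, H, W, N)`.
#' @return Logits array `dim = c(num_classes, H, W)` (or batched with N).
#' @export
deeperlabc_forward <- function(model, img) {
  if (is.matrix(img)) {
    d <- dim(img)
    x <- array(as.double(img), c(1L, d[1], d[2], 1L))
    single <- TRUE
  } else {
    x <- as_batch(img)
    single <- FALSE
  }
  d <- dim(x)
  if (d[2] %% 16L != 0L || d[3] %% 16L != 0L)
    stop_shape("input side must be divisible by 16")
  ctx <- new_ctx(model$params, model$buffers, training = FALSE)
  y <- model_fwd(ctx, x, model$config)
  if (single) {
    dn <- dim(y)
    dim(y) <- dn[1:3]
  }
  y
}

#' Decide a binary coral mask from per-pixel class logits
#'
#' Per-pixel argmax over the two class channels; ties go to background.
#'
#' @param logits Array `dim = c(2, H, W)` of class scores.
#' @return Integer `H x W` matrix over \{0, 1\}.
#' @export
predict_mask <- function(logits) {
  d <- dim(logits)
  if (is.null(d) || d[1] != 2L) stop_shape("logits must be a (2, H, W) array")
  m <- (logits[2, , ] > logits[1, , ]) + 0L
  dim(m) <- d[2:3]
  m
}

## ---- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a single serialized parameter archive plus a JSON sidecar
#' (`<path>.json`) recording the architecture configuration and seed.
#'
#' @param model A `coralseg_model` or `coralseg_backbone`.
#' @param path Checkpoint file path (`.rds`).
#' @param seed Optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, seed = NULL) {
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config), seed = seed,
                  class = class(model)[1], n_params = length(model$params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint file path.
#' @return The stored model object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("checkpoint '%s' not found", path))
  readRDS(path)
}
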