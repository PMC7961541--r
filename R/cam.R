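# Class-activation-map head: weak localization of coral evidence from
# image-level labels only. A 1x1 convolution at the decoder tail produces two
# response maps (non-coral, coral); global average pooling reduces each to a
# scalar mean G_j, and the scalar class weights form a single coral score
# s = w0*G0 + w1*G1 (+ bias), trained with image-level cross entropy
# (sigmoid). Because averaging commutes with the weighted sum, the weighted
# map w0*N0 + w1*N1 is exactly the spatial decomposition of the score (minus
# bias): pixels that push the image toward "coral" carry high activation.
# The raw map is normalized to [0, 100] percent for display.

#' Run the CAM head on decoder features
#'
#' Maps the fused decoder features through the CAM 1x1 convolution to the two
#' response maps `N0` (non-coral) and `N1` (coral), reduces each to its
#' spatial mean `G_j` by global average pooling, and forms the image-level
#' coral score `w0*G0 + w1*G1 + bias` from the scalar class weights. The
#' two-class scores are reported as `(-s, s)/2`, whose softmax equals the
#' sigmoid of the score `s`.
#'
#' @param model A `coralseg_model` (holds the CAM parameters).
#' @param features Fused decoder feature map `dim = c(C, h, w)` for one image
#'   (see [cam_for_image()] for the image-level wrapper).
#' @return List with `N0`, `N1` (`h x w` matrices), `G` (length-2 means),
#'   `score` (scalar coral evidence), `scores` (length-2 class scores),
#'   `weights` (w0, w1).
#' @export
cam_head_forward <- function(model, features) {
  d <- dim(features)
  if (length(d) == 3L) dim(features) <- c(d, 1L)
  maps <- .conv2d_fwd(features, model$params[["cam.conv.w"]],
                      model$params[["cam.conv.b"]], 1L, 0L, 1L)
  N0 <- matrix(maps[1, , , 1], dim(maps)[2], dim(maps)[3])
  N1 <- matrix(maps[2, , , 1], dim(maps)[2], dim(maps)[3])
  G <- c(mean(N0), mean(N1))
  w <- model$params[["cam.w"]]
  s <- sum(w * G) + model$params[["cam.bias"]]
  list(N0 = N0, N1 = N1, G = G, score = s, scores = c(-s, s) / 2, weights = w)
}

#' Weighted combination of the two activation maps
#'
#' The raw class activation map is the elementwise weighted sum
#' `w0 * N0 + w1 * N1`; its spatial mean equals `w0 * G0 + w1 * G1` exactly
#' (averaging commutes with the weighted sum).
#'
#' @param pair List with equal-sized matrices `N0` and `N1` (e.g. from
#'   [cam_head_forward()]).
#' @param weights Numeric length-2 vector `(w0, w1)`.
#' @return Matrix of raw activation values.
#' @export
compute_cam <- function(pair, weights) {
  if (!identical(dim(pair$N0), dim(pair$N1)))
    stop_shape("N0 and N1 must share a shape")
  weights[1] * pair$N0 + weights[2] * pair$N1
}

#' Normalize a raw activation map to \[0, 100\] percent
#'
#' Min-max normalization: `(x - min) / (max - min) * 100`, so any
#' non-constant map attains exactly 0 and 100. A constant map (max = min)
#' maps to all zeros by convention. The result is invariant to positive
#' affine transforms of the raw map.
#'
#' @param raw Numeric matrix of raw activation values.
#' @return Matrix with values in `[0, 100]`.
#' @export
normalize_cam <- function(raw) {
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) return(raw * 0)
  (raw - lo) / (hi - lo) * 100
}

#' Compute the normalized CAM for one image
#'
#' Runs the network trunk in evaluation mode up to the fused decoder
#' features, applies the CAM head, and returns raw and normalized maps plus
#' the image-level score.
#'
#' @param model A `coralseg_model` (CAM head trained via [train_cam()]).
#' @param img Numeric `S x S` matrix in `[0, 1]`.
#' @return List with `raw` (feature-resolution matrix), `normalized`
#'   (`[0, 100]`), `score`, `scores`, `label` (1 = coral present).
#' @export
cam_for_image <- function(model, img) {
  x <- array(as.double(img), c(1L, nrow(img), ncol(img), 1L))
  ctx <- new_ctx(model$params, model$buffers, training = FALSE)
  fused <- fused_features_fwd(ctx, x, model$config)
  head <- cam_head_forward(model, array(fused, dim(fused)[1:3]))
  raw <- compute_cam(head, head$weights)
  list(raw = raw, normalized = normalize_cam(raw), score = head$score,
       scores = head$scores, label = as.integer(head$score > 0))
}

#' Train the CAM head on image-level labels
#'
#' Fine-tunes only the CAM parameters (the 1x1 convolution, the scalar class
#' weights and the score bias) with image-level cross entropy on the same
#' kind of labelled data used for backbone pre-training; the segmentation
#' trunk is frozen and evaluated in inference mode.
#'
#' @param model A trained `coralseg_model`.
#' @param manifest Data.frame with `image_path`, `image_label`, `split`.
#' @param config A [train_config()] (phase `"pretrain"` schedule).
#' @return The model with updated CAM parameters and `$cam_history`.
#' @export
train_cam <- function(model, manifest, config = train_config("pretrain")) {
  set.seed(config$seed)
  sp <- split_rows(manifest)
  tr <- load_arrays(sp$train)
  cfg <- model$config
  cam_names <- c("cam.conv.w", "cam.conv.b", "cam.w", "cam.bias")
  P <- model$params
  sub <- P[cam_names]
  opt <- adam_init(sub, lr = config$v0)
  ntr <- dim(tr$x)[4]
  hist <- data.frame()
  # frozen trunk: precompute fused features once (inference mode, no augment)
  ctx <- new_ctx(P, model$buffers, training = FALSE)
  fused_all <- fused_features_fwd(ctx, tr$x, cfg)
  hw <- prod(dim(fused_all)[2:3])
  for (ep in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(ep, config$v0, config$alpha)
    ord <- sample.int(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      fb <- fused_all[, , , bi, drop = FALSE]
      maps <- .conv2d_fwd(fb, sub[["cam.conv.w"]], sub[["cam.conv.b"]], 1L, 0L, 1L)
      n <- length(bi)
      G <- matrix(0, 2L, n)
      for (k in seq_len(n)) G[, k] <- rowMeans(matrix(maps[, , , k], nrow = 2L))
      s <- drop(sub[["cam.w"]] %*% G) + sub[["cam.bias"]]
      y <- tr$labels[bi]
      p <- 1 / (1 + exp(-s))
      loss <- -mean(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))
      ds <- (p - y) / n
      dG <- sub[["cam.w"]] %o% ds            # 2 x n
      dmaps <- maps * 0
      for (k in seq_len(n))
        dmaps[, , , k] <- array(rep(dG[, k] / hw, hw), dim(maps)[1:3])
      gconv <- .conv2d_bwd(fb, sub[["cam.conv.w"]], dmaps, 1L, 0L, 1L)
      grads <- list("cam.conv.w" = gconv$dw, "cam.conv.b" = gconv$db,
                    "cam.w" = drop(G %*% ds), "cam.bias" = sum(ds))
      st <- adam_step(opt, sub, grads, lr = lr)
      opt <- st$state; sub <- st$params
      tl <- tl + loss * n
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl / ntr))
  }
  model$params[cam_names] <- sub
  model$cam_history <- hist
  model
}

#' Render a normalized CAM as a heat map over the source image
#'
#' The map is resized bilinearly to the image size and composited at fixed
#' opacity with a blue-to-red colormap: red marks pixels with high coral
#' evidence, blue low.
#'
#' @param cam Matrix in `[0, 100]` from [normalize_cam()].
#' @param base Gray image `H x W` matrix in `[0, 1]`.
#' @param alpha Overlay opacity in `[0, 1]` (default 0.5).
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_heatmap <- function(cam, base, alpha = 0.5) {
  h <- nrow(base); w <- ncol(base)
  if (!identical(dim(cam), c(h, w))) {
    x <- array(as.double(cam), c(1L, nrow(cam), ncol(cam)))
    cam <- matrix(.bilinear_fwd(x, h, w), h, w)
  }
  t <- pmin(pmax(cam / 100, 0), 1)
  out <- array(0, c(h, w, 3L))
  out[, , 1] <- (1 - alpha) * base + alpha * t        # red ramps up
  out[, , 2] <- (1 - alpha) * base
  out[, , 3] <- (1 - alpha) * base + alpha * (1 - t)  # blue ramps down
  out
}
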