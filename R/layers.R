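# Layer framework.
#
# A network is a flat named list of parameter arrays (`params`) plus a flat
# named list of batch-norm running statistics (`buffers`). Forward passes run
# inside a context environment `ctx` that records per-layer caches; backward
# passes consume the caches and accumulate gradients into `ctx$grad`, keyed
# like `params`. Feature maps are arrays dim = c(C, H, W, N), channel fastest.

new_ctx <- function(params, buffers, training = TRUE, bn_momentum = 0.1) {
  ctx <- new.env(parent = emptyenv())
  ctx$P <- params
  ctx$B <- buffers
  ctx$training <- training
  ctx$bn_momentum <- bn_momentum
  ctx$cache <- list()
  ctx$grad <- list()
  ctx
}

acc_grad <- function(ctx, name, g) {
  old <- ctx$grad[[name]]
  ctx$grad[[name]] <- if (is.null(old)) g else old + g
  invisible(NULL)
}

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

## ---- parameter initializers (He fan-in scaling, draws from the global RNG)

init_conv_params <- function(params, name, cin, cout, k) {
  sd <- sqrt(2 / (cin * k * k))
  params[[paste0(name, ".w")]] <- array(rnorm(cout * cin * k * k, sd = sd),
                                        dim = c(cout, cin, k, k))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_bn_params <- function(params, name, c, gamma_init = 1) {
  params[[paste0(name, ".gamma")]] <- rep(gamma_init, c)
  params[[paste0(name, ".beta")]]  <- numeric(c)
  params
}

init_bn_buffers <- function(buffers, name, c) {
  buffers[[paste0(name, ".mean")]] <- numeric(c)
  buffers[[paste0(name, ".var")]]  <- rep(1, c)
  buffers
}

init_linear_params <- function(params, name, cin, cout) {
  sd <- sqrt(2 / cin)
  params[[paste0(name, ".w")]] <- matrix(rnorm(cout * cin, sd = sd), cout, cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

## ---- convolution

fwd_conv <- function(ctx, x, name, stride = 1L, pad = NULL, dil = 1L) {
  w <- ctx$P[[paste0(name, ".w")]]
  if (is.null(w)) stop_config(sprintf("no parameters for layer '%s'", name))
  if (is.null(pad)) pad <- dil * (dim(w)[3] - 1L) %/% 2L  # 'same' for odd k
  y <- .conv2d_fwd(x, w, ctx$P[[paste0(name, ".b")]],
                   as.integer(stride), as.integer(pad), as.integer(dil))
  ctx$cache[[name]] <- list(x = x, stride = stride, pad = pad, dil = dil)
  y
}

bwd_conv <- function(ctx, dy, name) {
  cc <- ctx$cache[[name]]
  g <- .conv2d_bwd(cc$x, ctx$P[[paste0(name, ".w")]], dy,
                   as.integer(cc$stride), as.integer(cc$pad), as.integer(cc$dil))
  acc_grad(ctx, paste0(name, ".w"), g$dw)
  acc_grad(ctx, paste0(name, ".b"), g$db)
  g$dx
}

## ---- batch normalization (running stats updated with momentum 0.1)

fwd_bn <- function(ctx, x, name, momentum = ctx$bn_momentum, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  g <- ctx$P[[paste0(name, ".gamma")]]
  b <- ctx$P[[paste0(name, ".beta")]]
  xm <- matrix(x, nrow = C)
  if (ctx$training) {
    mu <- rowMeans(xm)
    v  <- rowMeans((xm - mu)^2)
    ctx$B[[paste0(name, ".mean")]] <-
      (1 - momentum) * ctx$B[[paste0(name, ".mean")]] + momentum * mu
    m <- ncol(xm)
    unbias <- if (m > 1) m / (m - 1) else 1
    ctx$B[[paste0(name, ".var")]] <-
      (1 - momentum) * ctx$B[[paste0(name, ".var")]] + momentum * v * unbias
  } else {
    mu <- ctx$B[[paste0(name, ".mean")]]
    v  <- ctx$B[[paste0(name, ".var")]]
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- g * xhat + b
  dim(y) <- d
  if (ctx$training) ctx$cache[[name]] <- list(xhat = xhat, inv = inv, dim = d)
  y
}

bwd_bn <- function(ctx, dy, name) {
  cc <- ctx$cache[[name]]
  C <- cc$dim[1]
  g <- ctx$P[[paste0(name, ".gamma")]]
  dym <- matrix(dy, nrow = C)
  acc_grad(ctx, paste0(name, ".gamma"), rowSums(dym * cc$xhat))
  acc_grad(ctx, paste0(name, ".beta"), rowSums(dym))
  dxhat <- dym * g
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cc$xhat)
  dx <- cc$inv * (dxhat - m1 - cc$xhat * m2)
  dim(dx) <- cc$dim
  dx
}

## ---- relu

fwd_relu <- function(ctx, x, name) {
  mask <- x > 0
  if (ctx$training) ctx$cache[[name]] <- mask
  x * mask
}

bwd_relu <- function(ctx, dy, name) dy * ctx$cache[[name]]

## ---- max pooling

fwd_maxpool <- function(ctx, x, name, k = 3L, stride = 2L, pad = 1L) {
  r <- .maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
  ctx$cache[[name]] <- list(idx = r$idx, dim = dim(x))
  r$y
}

bwd_maxpool <- function(ctx, dy, name) {
  cc <- ctx$cache[[name]]
  .maxpool_bwd(dy, cc$idx, cc$dim[1], cc$dim[2], cc$dim[3])
}

## ---- bilinear resize

fwd_bilinear <- function(ctx, x, name, ho, wo) {
  ctx$cache[[name]] <- dim(x)
  .bilinear_fwd(x, as.integer(ho), as.integer(wo))
}

bwd_bilinear <- function(ctx, dy, name) {
  d <- ctx$cache[[name]]
  .bilinear_bwd(dy, d[2], d[3])
}

## ---- global average pooling: (C,H,W,N) -> (C,N)

fwd_gap <- function(ctx, x, name) {
  d <- dim(x)
  xr <- array(x, c(d[1], d[2] * d[3], d[4]))
  y <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) y[, n] <- rowMeans(xr[, , n, drop = FALSE])
  ctx$cache[[name]] <- d
  y
}

bwd_gap <- function(ctx, dy, name) {
  d <- ctx$cache[[name]]
  scale <- 1 / (d[2] * d[3])
  dx <- array(0, d)
  for (n in seq_len(d[4]))
    dx[, , , n] <- array(rep(dy[, n] * scale, d[2] * d[3]), d[1:3])
  dx
}

## ---- linear head: x (C,N) -> y (K,N)

fwd_linear <- function(ctx, x, name) {
  w <- ctx$P[[paste0(name, ".w")]]
  ctx$cache[[name]] <- x
  w %*% x + ctx$P[[paste0(name, ".b")]]
}

bwd_linear <- function(ctx, dy, name) {
  x <- ctx$cache[[name]]
  acc_grad(ctx, paste0(name, ".w"), dy %*% t(x))
  acc_grad(ctx, paste0(name, ".b"), rowSums(dy))
  t(ctx$P[[paste0(name, ".w")]]) %*% dy
}

## ---- channel concatenation

fwd_concat <- function(ctx, a, b, name) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  ctx$cache[[name]] <- c(da[1], db[1])
  out
}

bwd_concat <- function(ctx, dy, name) {
  cs <- ctx$cache[[name]]
  list(da = dy[seq_len(cs[1]), , , , drop = FALSE],
       db = dy[cs[1] + seq_len(cs[2]), , , , drop = FALSE])
}

## ---- space-to-depth / depth-to-space --------------------------------------

#' Space-to-depth rearrangement of a feature map
#'
#' Rearranges non-overlapping `r x r` spatial blocks into channels:
#' `(C, H, W) -> (C*r^2, H/r, W/r)`. The mapping is a bijection on values, so
#' the feature volume `C*H*W` is conserved; block positions are ordered
#' row-major within each block and fill channels fastest, and
#' [depth_to_space()] with the same `r` is the exact inverse. Used to
#' down-sample the low-level feature path to the encoder's output stride
#' without discarding information.
#'
#' @param fm Numeric array `dim = c(C, H, W)` or batched `c(C, H, W, N)`.
#' @param r Integer block size; `H` and `W` must be divisible by `r`.
#' @return The rearranged array.
#' @export
space_to_depth <- function(fm, r) {
  r <- as.integer(r)
  d <- dim(fm)
  batched <- length(d) == 4
  if (!batched && length(d) != 3) stop_shape("feature map must have 3 or 4 dims")
  C <- d[1]; H <- d[2]; W <- d[3]; N <- if (batched) d[4] else 1L
  if (r < 1) stop_config("r must be >= 1")
  if (H %% r != 0 || W %% r != 0)
    stop_shape(sprintf("spatial dims (%d x %d) not divisible by r = %d", H, W, r))
  if (r == 1L) return(fm)
  x <- array(fm, c(C, r, H %/% r, r, W %/% r, N))
  y <- aperm(x, c(1, 4, 2, 3, 5, 6)) # (C, j, i, hb, wb, n): channel block p = i*r + j
  dim(y) <- c(C * r * r, H %/% r, W %/% r, N)
  if (!batched) dim(y) <- dim(y)[1:3]
  y
}

#' Depth-to-space rearrangement of a feature map
#'
#' Inverse of [space_to_depth()]: `(C, H, W) -> (C/r^2, H*r, W*r)` under the
#' same row-major block convention. Used with bilinear interpolation to
#' up-sample decoder features back to image resolution.
#'
#' @inheritParams space_to_depth
#' @export
depth_to_space <- function(fm, r) {
  r <- as.integer(r)
  d <- dim(fm)
  batched <- length(d) == 4
  if (!batched && length(d) != 3) stop_shape("feature map must have 3 or 4 dims")
  C <- d[1]; H <- d[2]; W <- d[3]; N <- if (batched) d[4] else 1L
  if (r < 1) stop_config("r must be >= 1")
  if (C %% (r * r) != 0)
    stop_shape(sprintf("channel count %d not divisible by r^2 = %d", C, r * r))
  if (r == 1L) return(fm)
  Co <- C %/% (r * r)
  x <- array(fm, c(Co, r, r, H, W, N)) # (C, j, i, hb, wb, n)
  y <- aperm(x, c(1, 3, 4, 2, 5, 6))   # (C, i, hb, j, wb, n)
  dim(y) <- c(Co, H * r, W * r, N)
  if (!batched) dim(y) <- dim(y)[1:3]
  y
}

fwd_s2d <- function(ctx, x, name, r) { ctx$cache[[name]] <- r; space_to_depth(x, r) }
bwd_s2d <- function(ctx, dy, name) depth_to_space(dy, ctx$cache[[name]])
fwd_d2s <- function(ctx, x, name, r) { ctx$cache[[name]] <- r; depth_to_space(x, r) }
bwd_d2s <- function(ctx, dy, name) space_to_depth(dy, ctx$cache[[name]])

## ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads, lr = NULL) {
  state$t <- state$t + 1L
  lr <- lr %||% state$lr
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
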