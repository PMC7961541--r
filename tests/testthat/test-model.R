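test_that("the pruned backbone has 26 residual-stage convolutions and stride-16 output", {
  cfg <- model_config()
  expect_identical(count_residual_convs(cfg), 26L)
  # census directly from the parameter census: 3x3 conv weights inside blocks
  set.seed(20)
  bb <- build_backbone(desk_config())
  conv33 <- grep("^s[0-9]+\\.b[0-9]+\\.conv[12]\\.w$", names(bb$params))
  expect_length(conv33, 26L)
  # stride algebra: stem x2, pool x2, stage2 x2, stage3 x2 = 16
  x <- array(runif(64 * 64), c(1, 64, 64, 1))
  ctx <- coralseg:::new_ctx(bb$params, bb$buffers, training = FALSE)
  out <- coralseg:::backbone_fwd(ctx, x, bb$config)
  expect_equal(dim(out$low)[2:3], c(16, 16))    # stride 4
  expect_equal(dim(out$high)[2:3], c(4, 4))     # stride 16
  expect_equal(dim(out$high)[1], bb$config$stage_channels[3])
})

test_that("full-width backbone maps 64x64 input to a 256-channel stride-16 map", {
  set.seed(21)
  cfg <- model_config(input_side = 64L, width_multiplier = 1)
  bb <- build_backbone(cfg)
  x <- array(runif(64 * 64), c(1, 64, 64, 1))
  ctx <- coralseg:::new_ctx(bb$params, bb$buffers, training = FALSE)
  high <- coralseg:::backbone_fwd(ctx, x, cfg)$high
  expect_equal(dim(high)[1:3], c(256L, 4L, 4L))
  expect_error(model_config(input_side = 100L), class = "coralseg_config_error")
})

test_that("residual blocks compute F(x) + x with a working identity branch", {
  set.seed(22)
  # zero-initialized last BN scale forces F(x) = 0: block reduces to ReLU(x),
  # the identity on nonnegative inputs
  bb <- build_backbone(desk_config(), zero_init_residual = TRUE)
  ctx <- coralseg:::new_ctx(bb$params, bb$buffers, training = FALSE)
  x <- array(abs(rnorm(bb$config$stem_channels * 6 * 6)),
             c(bb$config$stem_channels, 6, 6, 1))
  y <- coralseg:::block_fwd(ctx, x, "s1.b1", stride = 1L)
  expect_equal(y, x, tolerance = 1e-12)
  # with all F-branches zeroed the whole backbone still produces the
  # correctly shaped output (shortcut-only degenerate network)
  xin <- array(runif(64 * 64), c(1, 64, 64, 1))
  ctx2 <- coralseg:::new_ctx(bb$params, bb$buffers, training = FALSE)
  high <- coralseg:::backbone_fwd(ctx2, xin, bb$config)$high
  expect_equal(dim(high)[1:3], c(bb$config$stage_channels[3], 4L, 4L))
  # stepwise oracle: replicate one block with naive convolution + BN algebra
  set.seed(23)
  bb2 <- build_backbone(desk_config())
  P <- bb2$params
  C <- bb2$config$stem_channels
  x1 <- array(rnorm(C * 5 * 5), c(C, 5, 5))
  ctx3 <- coralseg:::new_ctx(P, bb2$buffers, training = FALSE)
  got <- coralseg:::block_fwd(ctx3, array(x1, c(C, 5, 5, 1)), "s1.b1", 1L)
  bn_eval <- function(z, g, b, mu, v) {
    zm <- matrix(z, nrow = length(g))
    out <- g * (zm - mu) / sqrt(v + 1e-5) + b
    array(out, dim(z))
  }
  h <- ref_conv2d(x1, P[["s1.b1.conv1.w"]], P[["s1.b1.conv1.b"]])
  h <- bn_eval(h, P[["s1.b1.bn1.gamma"]], P[["s1.b1.bn1.beta"]],
               bb2$buffers[["s1.b1.bn1.mean"]], bb2$buffers[["s1.b1.bn1.var"]])
  h <- pmax(h, 0)
  h <- ref_conv2d(h, P[["s1.b1.conv2.w"]], P[["s1.b1.conv2.b"]])
  h <- bn_eval(h, P[["s1.b1.bn2.gamma"]], P[["s1.b1.bn2.beta"]],
               bb2$buffers[["s1.b1.bn2.mean"]], bb2$buffers[["s1.b1.bn2.var"]])
  ref <- pmax(h + x1, 0)
  expect_equal(array(got, dim(got)[1:3]), ref, tolerance = 1e-5)
})

test_that("ASPP reduces its five branches to the configured channel count", {
  set.seed(24)
  cfg <- model_config(input_side = 64L, width_multiplier = 1)
  m <- build_model(cfg)
  ctx <- coralseg:::new_ctx(m$params, m$buffers, training = FALSE)
  fm <- array(rnorm(256 * 4 * 4), c(256, 4, 4, 1))
  out <- coralseg:::aspp_fwd(ctx, fm, cfg$aspp_rates)
  expect_equal(dim(out)[1], 256L)
  expect_equal(dim(out)[2:3], c(4L, 4L))        # spatial size unchanged
  # spatially constant input: every output column identical (the dilated
  # branches are translation invariant on constant fields and the GAP branch
  # is constant by construction)
  const <- array(rep(rnorm(256), 16), c(256, 4, 4, 1))
  outc <- coralseg:::aspp_fwd(ctx, const, cfg$aspp_rates)
  flat <- matrix(outc, nrow = 256)
  expect_lt(max(abs(flat - flat[, 1])), 1e-8)
})

test_that("dilated convolutions reach exactly the taps a rate-d kernel spans", {
  # impulse response: a unit impulse influences outputs only at offsets
  # {-d, 0, d} in each axis for a 3x3 kernel with dilation d
  for (d in c(6L, 12L)) {
    side <- 2L * d + 5L
    x <- array(0, c(1, side, side))
    mid <- (side + 1L) %/% 2L
    x[1, mid, mid] <- 1
    w <- array(1, c(1, 1, 3, 3))
    y <- coralseg:::.conv2d_fwd(x, w, 0, 1L, d, d)
    hit <- which(array(y, dim(y)[1:3])[1, , ] != 0, arr.ind = TRUE)
    offs <- hit - mid
    expect_true(all(offs %in% c(-d, 0L, d)))
    expect_equal(nrow(hit), 9L)
    expect_lte(max(abs(offs)), d)  # Chebyshev radius d
  }
})

test_that("the full network maps any side divisible by 16 to 2-channel logits", {
  set.seed(25)
  for (side in c(32L, 64L)) {
    cfg <- model_config(input_side = side, width_multiplier = 0.1)
    m <- build_model(cfg)
    img <- matrix(runif(side * side), side, side)
    lg <- deeperlabc_forward(m, img)
    expect_equal(dim(lg), c(2L, side, side))
  }
  cfg <- desk_config()
  m <- build_model(cfg)
  expect_error(deeperlabc_forward(m, matrix(0.5, 40, 40)),
               class = "coralseg_shape_error")
})

test_that("model parameter count matches layer-by-layer arithmetic", {
  set.seed(26)
  cfg <- desk_config()
  m <- build_model(cfg)
  conv_n <- function(cin, cout, k) cout * cin * k * k + cout
  bn_n <- function(c) 2 * c
  s <- cfg$stage_channels; stem <- cfg$stem_channels
  n <- conv_n(1, stem, 7) + bn_n(stem)
  cin <- stem
  for (st in 1:3) for (b in seq_len(cfg$stage_blocks[st])) {
    n <- n + conv_n(cin, s[st], 3) + bn_n(s[st]) +
      conv_n(s[st], s[st], 3) + bn_n(s[st])
    if (cin != s[st] || (st > 1 && b == 1))
      n <- n + conv_n(cin, s[st], 1) + bn_n(s[st])
    cin <- s[st]
  }
  a <- cfg$aspp_out_channels
  n <- n + conv_n(s[3], a, 1) + bn_n(a) +            # rate-1 branch
    3 * (conv_n(s[3], a, 3) + bn_n(a)) +             # dilated branches
    conv_n(s[3], a, 1) + bn_n(a) +                   # GAP branch
    conv_n(5 * a, a, 1) + bn_n(a)                    # projection
  lo <- cfg$lowlevel_reduced_channels
  n <- n + conv_n(stem, lo, 1) + bn_n(lo)
  fi <- a + lo * cfg$s2d_block^2
  fu <- cfg$fusion_channels; k <- cfg$fusion_kernel
  n <- n + conv_n(fi, fu, k) + bn_n(fu) + conv_n(fu, fu, k) + bn_n(fu)
  n <- n + conv_n(fu, cfg$num_classes * cfg$s2d_block^2, 1)
  n <- n + conv_n(fu, 2, 1) + 2 + 1                  # CAM head + weights + bias
  expect_identical(sum(vapply(m$params, length, integer(1))), as.integer(n))
})

test_that("mask decisions take the per-pixel argmax with ties to background", {
  lg <- array(0, c(2, 3, 3))
  lg[2, , ] <- 1
  expect_equal(predict_mask(lg), matrix(1L, 3, 3))
  expect_equal(predict_mask(array(0.3, c(2, 3, 3))), matrix(0L, 3, 3))  # ties
  set.seed(27)
  lg <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  got <- predict_mask(lg)
  for (h in 1:5) for (w in 1:5)
    expect_identical(got[h, w], as.integer(lg[2, h, w] - lg[1, h, w] > 0))
})

test_that("checkpoints round-trip with a JSON sidecar", {
  d <- withr::local_tempdir()
  set.seed(28)
  cfg <- model_config(input_side = 16L, width_multiplier = 0.1)
  m <- build_model(cfg)
  p <- file.path(d, "m.rds")
  save_checkpoint(m, p, seed = 28L)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$config$input_side, 16L)
  expect_equal(side$seed, 28L)
})
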