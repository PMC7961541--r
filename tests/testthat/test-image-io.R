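test_that("gray image loading scales 8-bit values to [0,1] and rejects color", {
  d <- withr::local_tempdir()
  white <- file.path(d, "white.png")
  png::writePNG(matrix(1, 5, 7), white)
  expect_equal(load_gray_image(white), matrix(1, 5, 7))
  black <- file.path(d, "black.png")
  png::writePNG(matrix(0, 5, 7), black)
  expect_equal(load_gray_image(black), matrix(0, 5, 7))
  rgbf <- file.path(d, "rgb.png")
  png::writePNG(array(runif(4 * 4 * 3), c(4, 4, 3)), rgbf)
  expect_error(load_gray_image(rgbf), class = "coralseg_channel_error")
  expect_error(load_gray_image(file.path(d, "missing.png")),
               class = "coralseg_io_error")
})

test_that("image writing round-trips pixel values within 8-bit precision", {
  d <- withr::local_tempdir()
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- file.path(d, "rt.png")
  save_gray_image(img, p)
  expect_lt(max(abs(load_gray_image(p) - img)), 1 / 255)
})

test_that("RGB channel splitting returns R,G,B and restacking is the identity", {
  red <- array(0, c(3, 4, 3)); red[, , 1] <- 1
  ch <- split_rgb_channels(red)
  expect_equal(ch$R, matrix(1, 3, 4))
  expect_equal(ch$G, matrix(0, 3, 4))
  expect_equal(ch$B, matrix(0, 3, 4))
  gray <- array(rep(0.4, 2 * 2 * 3), c(2, 2, 3))
  chg <- split_rgb_channels(gray)
  expect_identical(chg$R, chg$G)
  expect_identical(chg$G, chg$B)
  set.seed(2)
  any3 <- array(runif(5 * 6 * 3), c(5, 6, 3))
  ch3 <- split_rgb_channels(any3)
  restacked <- array(c(ch3$R, ch3$G, ch3$B), dim(any3))
  expect_identical(restacked, any3)
  expect_error(split_rgb_channels(array(0, c(4, 4, 2))),
               class = "coralseg_channel_error")
})

test_that("padding to square centers content in black bands", {
  img <- matrix(0.5, 400, 512)
  out <- pad_to_square(img)
  expect_equal(dim(out), c(512, 512))
  expect_equal(out[1:56, ], matrix(0, 56, 512))          # upper band
  expect_equal(out[457:512, ], matrix(0, 56, 512))       # lower band
  expect_equal(out[57:456, ], img)
  sq <- matrix(runif(16), 4, 4)
  expect_identical(pad_to_square(sq), sq)
  tall <- matrix(1, 512, 400)
  padded <- pad_to_square(tall)
  expect_equal(dim(padded), c(512, 512))
  expect_equal(sum(padded) , sum(tall))                  # padding adds zeros
  expect_equal(sum(padded == 0), 512 * 512 - 512 * 400)  # brute-force count
})

test_that("canonical resizing honours side, interpolation and constancy", {
  const <- matrix(0.3, 1024, 1024)
  out <- resize_to_canonical(const, 512)
  expect_equal(dim(out), c(512, 512))
  expect_equal(out, matrix(0.3, 512, 512), tolerance = 1e-12)
  # nearest-neighbor index map enumerated by hand for 2 -> 4 upscaling
  m <- matrix(c(0, 0, 1, 1), 2, 2)
  up <- resize_to_canonical(m, 4, "nearest")
  expect_equal(up, cbind(matrix(0, 4, 2), matrix(1, 4, 2)))
  expect_error(resize_to_canonical(matrix(0, 3, 4), 4),
               class = "coralseg_shape_error")
})

test_that("mask binarization thresholds at 0.5", {
  expect_equal(binarize_mask(matrix(1, 3, 3)), matrix(1L, 3, 3))
  expect_equal(binarize_mask(matrix(0, 3, 3)), matrix(0L, 3, 3))
  edge <- matrix(c(0.49, 0.51), 1, 2)
  expect_equal(binarize_mask(edge), matrix(c(0L, 1L), 1, 2))
})

test_that("paired augmentation applies identical transforms and keeps masks binary", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- random_mask(64, 64)
  noop <- augment_pair(img, mask, draws = list(rotate = FALSE, angle = 0,
                                               hflip = FALSE, vflip = FALSE))
  expect_identical(noop$image, img)
  expect_identical(noop$mask, mask)
  hf <- augment_pair(img, mask, draws = list(rotate = FALSE, angle = 0,
                                             hflip = TRUE, vflip = FALSE))
  expect_equal(hf$image, img[, 64:1])
  # involution: flipping twice restores the input
  hf2 <- augment_pair(hf$image, hf$mask,
                      draws = list(rotate = FALSE, angle = 0,
                                   hflip = TRUE, vflip = FALSE))
  expect_identical(hf2$image, img)
  expect_identical(hf2$mask, mask)
  # flips preserve the coral-pixel count exactly
  vf <- augment_pair(img, mask, draws = list(rotate = FALSE, angle = 0,
                                             hflip = TRUE, vflip = TRUE))
  expect_identical(sum(vf$mask), sum(mask))
  expect_true(all(vf$mask %in% c(0L, 1L)))
  expect_error(augment_pair(img, random_mask(32, 32)),
               class = "coralseg_shape_error")
})

test_that("each augmentation transform fires with probability one half", {
  set.seed(4)
  img <- matrix(0.5, 2, 2); mask <- matrix(0L, 2, 2)
  n <- 10000
  fires <- matrix(FALSE, n, 3)
  for (i in seq_len(n)) {
    a <- augment_pair(img, mask)
    fires[i, ] <- c(a$draws$rotate, a$draws$hflip, a$draws$vflip)
  }
  tol <- 3 * sqrt(n * 0.25)  # binomial 3 sigma
  expect_true(all(abs(colSums(fires) - n / 2) <= tol))
})

test_that("rotation changes foreground count only by boundary resampling", {
  set.seed(5)
  # disc blob occupying well over 5% of the frame
  side <- 64
  yy <- row(matrix(0, side, side)) - 32.5
  xx <- col(matrix(0, side, side)) - 32.5
  mask <- (yy^2 + xx^2 <= 14^2) + 0L
  dim(mask) <- c(side, side)
  img <- 0.2 + 0.5 * mask
  expect_gt(sum(mask) / side^2, 0.05)
  for (ang in c(20, 45, 90, 133)) {
    a <- augment_pair(img, mask, draws = list(rotate = TRUE, angle = ang,
                                              hflip = FALSE, vflip = FALSE))
    expect_lte(abs(sum(a$mask) - sum(mask)) / sum(mask), 0.10)
  }
})

test_that("manifests round-trip through CSV with resolved paths", {
  d <- withr::local_tempdir()
  m <- data.frame(image_path = c("a.png", "b.png"),
                  mask_path = c("am.png", ""),
                  image_label = c(1L, 0L), split = c("train", "val"))
  p <- file.path(d, "manifest.csv")
  write_manifest(m, p)
  r <- read_manifest(p)
  expect_equal(basename(r$image_path), c("a.png", "b.png"))
  expect_true(startsWith(r$image_path[1], normalizePath(d)))
  expect_true(is.na(r$mask_path[2]))
  expect_equal(r$image_label, c(1L, 0L))
  bad <- data.frame(image_path = "x.png", image_label = 7L)
  pb <- file.path(d, "bad.csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_manifest(pb), class = "coralseg_data_error")
})
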