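# Synthetic coral-scene generator.
#
# Stands in for a real annotated dataset at desk scale: single-channel
# scenes with smooth elliptical coral-like blobs (unions of 1-4 overlapping
# ellipses with sinusoidal texture) offset in intensity from a noisy
# background, paired pixel masks, and image-level presence labels. The
# default positive share follows the real collection's class balance
# (2672/4131 ~ 0.65 positive).

#' Configuration for the synthetic coral-scene generator
#'
#' @param side Image side in pixels (>= 16; desk-scale default 64, full
#'   scale 512).
#' @param n_blobs Integer range `c(min, max)` of ellipses per positive scene.
#' @param blob_scale Largest ellipse semi-axis as a fraction of `side`
#'   (axes are drawn uniformly from 0.5-1 times `blob_scale * side / 2`).
#' @param blob_offset Intensity offset of coral over background (default 0.4).
#' @param texture_amplitude Amplitude of the sinusoidal texture inside blobs.
#' @param background_noise_sd Gaussian pixel noise standard deviation.
#' @param illumination_gradient If `TRUE`, add a vertical illumination ramp
#'   mimicking unevenly lit single-band frames.
#' @param positive_fraction Probability a scene contains coral (default
#'   2672/4131, the empirical positive share of the reference collection).
#' @param seed Integer seed driving dataset generation.
#' @return A `coralseg_scene_config` list.
#' @export
scene_config <- function(side = 64L, n_blobs = c(1L, 4L), blob_scale = 0.25,
                         blob_offset = 0.4, texture_amplitude = 0.05,
                         background_noise_sd = 0.1,
                         illumination_gradient = FALSE,
                         positive_fraction = 2672 / 4131, seed = 1L) {
  if (side < 16L) stop_config("side must be >= 16")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop_config("positive_fraction must be in [0, 1]")
  cfg <- list(side = as.integer(side), n_blobs = as.integer(n_blobs),
              blob_scale = blob_scale, blob_offset = blob_offset,
              texture_amplitude = texture_amplitude,
              background_noise_sd = background_noise_sd,
              illumination_gradient = isTRUE(illumination_gradient),
              positive_fraction = positive_fraction, seed = as.integer(seed))
  class(cfg) <- "coralseg_scene_config"
  cfg
}

# Pixel membership of an ellipse union; ellipses is a data.frame with
# columns cx, cy, a, b, theta (pixel units, angle in radians).
ellipse_union_mask <- function(side, ellipses) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)  # column index
  ys <- matrix(seq_len(side), side, side)                    # row index
  m <- matrix(FALSE, side, side)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    dx <- xs - e$cx; dy <- ys - e$cy
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / e$b
    m <- m | (u^2 + v^2 <= 1)
  }
  m
}

#' Generate one synthetic coral scene
#'
#' With probability `positive_fraction` the scene contains a coral-like blob
#' (union of random ellipses with sinusoidal texture, intensity offset from
#' the background); otherwise a background-only scene. The image-level label
#' is 1 exactly when the mask has at least one coral pixel.
#'
#' @param cfg A [scene_config()].
#' @param seed Optional integer; when given, the sample is a pure function
#'   of `(cfg, seed)`.
#' @return List with `image` (`side x side` matrix in `[0, 1]`), `mask`
#'   (integer 0/1 matrix), `image_label`, `blobs` (ellipse parameters,
#'   `NULL` for negatives) and the generating `noise_sd`.
#' @export
generate_sample <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- cfg$side
  positive <- runif(1) < cfg$positive_fraction
  mask <- matrix(0L, side, side)
  blobs <- NULL
  if (positive) {
    k <- if (cfg$n_blobs[1] == cfg$n_blobs[2]) cfg$n_blobs[1] else
      sample(seq(cfg$n_blobs[1], cfg$n_blobs[2]), 1L)
    rmax <- cfg$blob_scale * side / 2
    blobs <- data.frame(
      cx = runif(k, 0.2 * side, 0.8 * side),
      cy = runif(k, 0.2 * side, 0.8 * side),
      a = runif(k, 0.5 * rmax, rmax),
      b = runif(k, 0.5 * rmax, rmax),
      theta = runif(k, 0, pi))
    mm <- ellipse_union_mask(side, blobs)
    mask <- mm + 0L
    dim(mask) <- c(side, side)
  }
  base <- 0.25
  img <- matrix(base, side, side)
  if (cfg$illumination_gradient)
    img <- img + 0.15 * (2 * (row(img) - 1) / (side - 1) - 1)
  if (positive) {
    fx <- runif(1, 2, 6) / side; fy <- runif(1, 2, 6) / side
    ph <- runif(1, 0, 2 * pi)
    tex <- cfg$texture_amplitude *
      sin(2 * pi * (fx * row(img) + fy * col(img)) + ph)
    img <- img + (cfg$blob_offset + tex) * (mask == 1L)
  }
  img <- img + matrix(rnorm(side * side, sd = cfg$background_noise_sd), side, side)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, image_label = as.integer(sum(mask) > 0),
       blobs = blobs, noise_sd = cfg$background_noise_sd)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` scenes as 8-bit grayscale PNG image/mask pairs, a manifest CSV
#' (columns `image_path`, `mask_path`, `image_label`, `split`) with a
#' train/validation split, and a JSON descriptor of the generator
#' configuration so the dataset can be reproduced exactly.
#'
#' @param cfg A [scene_config()].
#' @param n Number of scenes (>= 2).
#' @param dir Output directory.
#' @param split_fraction Training share (default 0.9, i.e. a 90/10 split).
#' @return The manifest data.frame (with absolute paths), invisibly carrying
#'   attribute `dir`.
#' @export
generate_dataset <- function(cfg, n, dir, split_fraction = 0.9) {
  if (n < 2) stop_data("n must be >= 2")
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create directory '%s'", dir))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, n)
  n_train <- max(1L, round(n * split_fraction))
  split <- rep("val", n)
  split[sample.int(n, n_train)] <- "train"
  rows <- data.frame(image_path = character(n), mask_path = character(n),
                     image_label = integer(n), split = split,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- generate_sample(cfg, seed = seeds[i])
    ip <- sprintf("img_%04d.png", i)
    mp <- sprintf("mask_%04d.png", i)
    save_gray_image(s$image, file.path(dir, ip))
    save_gray_image(s$mask, file.path(dir, mp))
    rows$image_path[i] <- ip
    rows$mask_path[i] <- mp
    rows$image_label[i] <- s$image_label
  }
  write_manifest(rows, file.path(dir, "manifest.csv"))
  jsonlite::write_json(c(unclass(cfg), list(n = n, split_fraction = split_fraction)),
                       file.path(dir, "scene_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  attr(m, "dir") <- dir
  invisible(m)
}

#' Read back a dataset descriptor written by [generate_dataset()]
#'
#' @param path Path to `scene_config.json` (or the dataset directory).
#' @return List with `cfg` (a [scene_config()]), `n`, `split_fraction`;
#'   calling [generate_dataset()] with these reproduces the dataset exactly.
#' @export
read_scene_config <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "scene_config.json")
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- scene_config(side = d$side, n_blobs = d$n_blobs,
                      blob_scale = d$blob_scale, blob_offset = d$blob_offset,
                      texture_amplitude = d$texture_amplitude,
                      background_noise_sd = d$background_noise_sd,
                      illumination_gradient = d$illumination_gradient,
                      positive_fraction = d$positive_fraction, seed = d$seed)
  list(cfg = cfg, n = d$n, split_fraction = d$split_fraction)
}

#' Contrast score of a positive synthetic scene
#'
#' Returns `|mean intensity inside the mask - mean outside| / noise sd`, a
#' separability gate for fixture quality: the generator defaults keep this
#' at roughly `blob_offset / background_noise_sd` (~4), comfortably above
#' the score of 2 needed for desk-scale training to succeed.
#'
#' @param sample A positive sample from [generate_sample()].
#' @return Nonnegative contrast score.
#' @export
foreground_separability <- function(sample) {
  if (sample$image_label != 1L)
    stop_data("separability is defined for positive samples only")
  inside <- mean(sample$image[sample$mask == 1L])
  outside <- mean(sample$image[sample$mask == 0L])
  abs(inside - outside) / sample$noise_sd
}
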