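#' Read a single-channel image
#'
#' Loads an 8-bit grayscale raster (PNG primary; JPEG and TIFF accepted) and
#' returns it as a numeric matrix with intensities scaled to `[0, 1]`.
#' Multi-channel rasters are rejected: RGB photographs must be split into
#' single-channel images first (see [split_rgb_channels()]), matching the
#' single-band representation the segmentation network consumes.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return A numeric `H x W` matrix in `[0, 1]` (a gray image).
#' @seealso [save_gray_image()], [split_rgb_channels()], [binarize_mask()]
#' @export
load_gray_image <- function(path) {
  raster <- read_raster(path)
  if (length(dim(raster)) == 3) {
    if (dim(raster)[3] == 1) {
      raster <- raster[, , 1, drop = TRUE]
    } else {
      stop_channel(sprintf(
        "'%s' has %d channels; expected a single-channel image (split RGB inputs first)",
        path, dim(raster)[3]))
    }
  }
  storage.mode(raster) <- "double"
  pmin(pmax(raster, 0), 1)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  out <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE))
          stop_io("JPEG support requires the 'jpeg' package")
        jpeg::readJPEG(path)
      },
      tif  = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop_io("TIFF support requires the 'tiff' package")
        tiff::readTIFF(path)
      },
      stop_io(sprintf("unsupported image format '.%s' (use PNG, JPEG or TIFF)", ext))
    ),
    error = function(e) {
      if (inherits(e, "coralseg_error")) stop(e)
      stop_io(sprintf("failed to decode '%s': %s", path, conditionMessage(e)))
    })
  out
}

#' Write a gray image or mask as 8-bit grayscale PNG
#'
#' @param img Numeric `H x W` matrix in `[0, 1]`, or a binary mask (0/1).
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
save_gray_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  storage.mode(img) <- "double"
  png::writePNG(img, target = path)
  invisible(path)
}

#' Split a 3-channel raster into R, G and B gray images
#'
#' RGB photographs enter the pipeline one channel at a time, keeping the
#' channel dimension consistent with single-band spectral frames.
#'
#' @param rgb An `H x W x 3` numeric array in `[0, 1]` (e.g. from
#'   `png::readPNG()` on a color file).
#' @return Named list with elements `R`, `G`, `B`, each an `H x W` matrix.
#' @export
split_rgb_channels <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop_channel("input must be an H x W x 3 array")
  list(R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3])
}

#' Pad an image with black borders to a 1:1 aspect ratio
#'
#' Adds zero-valued (black) bands so the output is square with side
#' `max(H, W)`; the original content is centered on both axes. A square
#' input is returned unchanged. Bands land on the top/bottom for landscape
#' frames and on the left/right for portrait frames.
#'
#' @param img Numeric `H x W` matrix (image or mask).
#' @param fill Padding value; 0 (black) by default.
#' @return A square matrix of side `max(H, W)`.
#' @export
pad_to_square <- function(img, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  if (h == w) return(img)
  side <- max(h, w)
  out <- matrix(fill, side, side)
  top  <- (side - h) %/% 2
  left <- (side - w) %/% 2
  out[top + seq_len(h), left + seq_len(w)] <- img
  out
}

#' Resize a square image to the canonical network side
#'
#' Intensity images are resampled bilinearly; masks must use
#' `method = "nearest"` so they stay binary. Both methods use half-pixel
#' sample centers. The canonical side for full-scale work is 512; smaller
#' sides (divisible by 16) are used for desk-scale experiments.
#'
#' @param img Square numeric matrix (pad first, see [pad_to_square()]).
#' @param side Target side length in pixels.
#' @param method `"bilinear"` (images) or `"nearest"` (masks).
#' @return A `side x side` matrix.
#' @export
resize_to_canonical <- function(img, side = 512L, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) != ncol(img))
    stop_shape("input must be square; apply pad_to_square() first")
  if (side < 1) stop_config("side must be >= 1")
  n <- nrow(img)
  if (n == side) return(img)
  if (method == "bilinear") {
    x <- array(as.double(img), dim = c(1L, n, n))
    out <- .bilinear_fwd(x, side, side)
    matrix(out, side, side)
  } else {
    idx <- pmin(pmax(floor((seq_len(side) - 0.5) * n / side) + 1, 1), n)
    img[idx, idx, drop = FALSE]
  }
}

#' Threshold a grayscale annotation into a binary mask
#'
#' Annotation masks are nominally pure black/white (white = coral,
#' black = background); thresholding at 0.5 absorbs anti-aliasing and
#' compression artifacts.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @return Integer matrix over \{0, 1\} (1 = coral).
#' @export
binarize_mask <- function(img) {
  m <- (img > 0.5) + 0L
  dim(m) <- dim(img)
  m
}

#' Load a binary annotation mask from file
#'
#' @param path Path to a grayscale mask file (white = coral).
#' @return Integer matrix over \{0, 1\}.
#' @export
load_mask <- function(path) binarize_mask(load_gray_image(path))

# Rotate by `angle` degrees counter-clockwise about the image center,
# zero fill outside the source frame. Inverse mapping with either bilinear
# or nearest-neighbor sampling.
rotate_image <- function(img, angle, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # output pixel grid (row y, col x), pull from source via rotation by -angle
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  # counter-clockwise on screen (y down): inverse transform
  sx <- cos(th) * xx - sin(th) * yy + cx
  sy <- sin(th) * xx + cos(th) * yy + cy
  if (method == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
    out <- matrix(0, h, w)
    out[ok] <- img[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    ax <- sx - x0; ay <- sy - y0
    out <- matrix(0, h, w)
    gather <- function(r, c) {
      ok <- r >= 1 & r <= h & c >= 1 & c <= w
      v <- matrix(0, h, w)
      v[ok] <- img[cbind(r[ok], c[ok])]
      v
    }
    out <- (1 - ax) * (1 - ay) * gather(y0, x0) +
           (1 - ax) * ay       * gather(y0 + 1, x0) +
           ax * (1 - ay)       * gather(y0, x0 + 1) +
           ax * ay             * gather(y0 + 1, x0 + 1)
  }
  if (!is.matrix(out)) dim(out) <- c(h, w)
  out
}

#' Random paired augmentation of an image and its mask
#'
#' Applies, each independently with probability 0.5: a random rotation with
#' angle uniform on \[0, 180\] degrees, a horizontal flip, and a vertical
#' flip. The identical geometric transform is applied to image and mask;
#' the image is resampled bilinearly and the mask by nearest neighbor so it
#' stays binary. Rotation is counter-clockwise about the image center with
#' zero (black) fill in exposed corners.
#'
#' Randomness comes from R's global RNG; the draw order is fixed and
#' replayable: rotate? (uniform < 0.5), angle (uniform on \[0, 180\]),
#' hflip? (uniform < 0.5), vflip? (uniform < 0.5). The angle is drawn even
#' when rotation does not fire, so the stream stays aligned. `draws` can
#' force a specific transform (used in tests and replay).
#'
#' @param img Numeric `H x W` matrix in `[0, 1]`.
#' @param mask Integer `H x W` matrix over \{0, 1\}.
#' @param draws Optional list with elements `rotate` (logical), `angle`
#'   (degrees), `hflip`, `vflip` (logical); any missing element is drawn.
#' @return List with elements `image` and `mask`.
#' @export
augment_pair <- function(img, mask, draws = NULL) {
  assert_same_shape(img, mask)
  d <- list(
    rotate = draws$rotate %||% (runif(1) < 0.5),
    angle  = draws$angle  %||% runif(1, 0, 180),
    hflip  = draws$hflip  %||% (runif(1) < 0.5),
    vflip  = draws$vflip  %||% (runif(1) < 0.5)
  )
  if (d$rotate) {
    img  <- rotate_image(img, d$angle, "bilinear")
    img  <- pmin(pmax(img, 0), 1)
    mask <- rotate_image(mask, d$angle, "nearest")
  }
  if (d$hflip) {
    img  <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (d$vflip) {
    img  <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  storage.mode(mask) <- "integer"
  list(image = img, mask = mask, draws = d)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV/TSV with columns `image_path`, `mask_path`
#' (optional, may be empty), `image_label` (1 = contains coral, 0 = no
#' coral) and `split` (`train`/`val`). Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("manifest '%s' not found", path))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  m <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!"image_path" %in% names(m)) stop_data("manifest must have an image_path column")
  if (!"image_label" %in% names(m)) stop_data("manifest must have an image_label column")
  if (!all(m$image_label %in% c(0L, 1L))) stop_data("image_label must be 0 or 1")
  base <- dirname(normalizePath(path))
  absify <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                               ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  m$image_path <- absify(m$image_path)
  if ("mask_path" %in% names(m)) m$mask_path <- absify(m$mask_path) else m$mask_path <- NA_character_
  if (!"split" %in% names(m)) m$split <- "train"
  m
}

#' Write a dataset manifest
#'
#' @param manifest Data.frame with columns `image_path`, `mask_path`,
#'   `image_label`, `split`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
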