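# Classed conditions so callers/tests can distinguish failure modes.
cs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "coralseg_error"), call = call))
}

stop_io      <- function(msg) cs_stop(msg, "coralseg_io_error")
stop_channel <- function(msg) cs_stop(msg, "coralseg_channel_error")
stop_shape   <- function(msg) cs_stop(msg, "coralseg_shape_error")
stop_config  <- function(msg) cs_stop(msg, "coralseg_config_error")
stop_data    <- function(msg) cs_stop(msg, "coralseg_data_error")

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_shape(sprintf("`%s` must be a numeric H x W matrix", arg))
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop_shape(sprintf("`%s` must have values in [0, 1]", arg))
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop_shape(sprintf("`%s` must be an H x W matrix", arg))
  if (!all(mask %in% c(0L, 1L)))
    stop_shape(sprintf("`%s` must contain only 0 and 1", arg))
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "image and mask") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop_shape(sprintf("%s must share the same height and width", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
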