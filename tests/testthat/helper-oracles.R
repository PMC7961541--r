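# Independent scalar-loop oracles, kept deliberately naive so they cannot
# share bugs with the vectorized/C++ implementations they check.

# Naive 2-D convolution on (C,H,W) arrays, weights (Cout,Cin,kh,kw),
# zero padding, stride, dilation.
ref_conv2d <- function(x, w, b, stride = 1, pad = 1, dil = 1) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Cout <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  Ho <- (H + 2 * pad - ((kh - 1) * dil + 1)) %/% stride + 1
  Wo <- (W + 2 * pad - ((kw - 1) * dil + 1)) %/% stride + 1
  y <- array(0, c(Cout, Ho, Wo))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (i in 1:kh) for (j in 1:kw) {
      hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[ci, hi, wi] * w[co, ci, i, j]
    }
    y[co, ho, wo] <- acc
  }
  y
}

# Scalar-loop mean cross entropy over a (2,H,W) logit grid.
ref_ce <- function(logits, gt) {
  H <- dim(logits)[2]; W <- dim(logits)[3]
  tot <- 0
  for (h in 1:H) for (w in 1:W) {
    l <- logits[, h, w]
    p <- exp(l) / sum(exp(l))
    tot <- tot - log(p[gt[h, w] + 1])
  }
  tot / (H * W)
}

# Nested-loop confusion counts.
ref_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (h in seq_len(nrow(pred))) for (w in seq_len(ncol(pred))) {
    if (pred[h, w] == 1 && gt[h, w] == 1) tp <- tp + 1L
    else if (pred[h, w] == 1 && gt[h, w] == 0) fp <- fp + 1L
    else if (pred[h, w] == 0 && gt[h, w] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

random_mask <- function(h, w) {
  m <- matrix(sample(0:1, h * w, replace = TRUE), h, w)
  storage.mode(m) <- "integer"
  m
}

desk_config <- function(side = 64L) model_config(input_side = side,
                                                 width_multiplier = 0.25)
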