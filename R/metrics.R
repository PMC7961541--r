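#' Pixel confusion counts between a predicted and a true mask
#'
#' @param pred,gt Integer `H x W` matrices over \{0, 1\} (1 = coral).
#' @return Named list with `TP`, `FP`, `FN`, `TN` pixel counts
#'   (`TP + FP + FN + TN` equals the number of pixels).
#' @export
confusion_counts <- function(pred, gt) {
  assert_mask(pred, "pred"); assert_mask(gt, "gt")
  assert_same_shape(pred, gt, "pred and gt")
  list(TP = sum(pred == 1L & gt == 1L),
       FP = sum(pred == 1L & gt == 0L),
       FN = sum(pred == 0L & gt == 1L),
       TN = sum(pred == 0L & gt == 0L))
}

#' Precision: TP / (TP + FP)
#'
#' Returns `NA` when no pixel was predicted positive (undefined); such
#' degenerate values are excluded from dataset averages rather than forced
#' to 0 or 1.
#'
#' @param counts A [confusion_counts()] list.
#' @return Value in `[0, 1]`, or `NA` when `TP + FP = 0`.
#' @export
precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) NA_real_ else counts$TP / d
}

#' Recall: TP / (TP + FN)
#'
#' `NA` when the ground truth has no positive pixel (undefined).
#'
#' @inheritParams precision
#' @export
recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) NA_real_ else counts$TP / d
}

#' F1 score: harmonic mean of precision and recall
#'
#' @param pr,re Precision and recall in `[0, 1]`; 0 is returned when both are
#'   0, `NA` propagates.
#' @return `2 * pr * re / (pr + re)`.
#' @export
f1_score <- function(pr, re) {
  if (is.na(pr) || is.na(re)) return(NA_real_)
  if (pr + re == 0) return(0)
  2 * pr * re / (pr + re)
}

#' Mean intersection-over-union of a binary segmentation
#'
#' Per-class IoU (`TP_k / (TP_k + FP_k + FN_k)`) for background and coral,
#' averaged over the classes. A class absent from both prediction and ground
#' truth is skipped from the average (its IoU is undefined, not perfect).
#'
#' @param pred,gt Integer `H x W` matrices over \{0, 1\}.
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(pred, gt) {
  assert_mask(pred, "pred"); assert_mask(gt, "gt")
  assert_same_shape(pred, gt, "pred and gt")
  ious <- vapply(c(0L, 1L), function(k) {
    inter <- sum(pred == k & gt == k)
    uni <- sum(pred == k | gt == k)
    if (uni == 0) NA_real_ else inter / uni
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

image_metrics <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  pr <- precision(cc); re <- recall(cc)
  c(precision = pr, recall = re, f1 = f1_score(pr, re),
    mean_iou = mean_iou(pred, gt))
}

#' Evaluate a segmentation model over a validation manifest
#'
#' Computes precision, recall, F1 and mean IoU per image (macro aggregation),
#' then the mean and population standard deviation of each metric across
#' images; undefined (`NA`) per-image values are excluded from aggregates.
#' A pixel-pooled micro aggregation over the whole split is also reported.
#'
#' @param model A `coralseg_model`.
#' @param manifest Data.frame of records with masks; all rows are evaluated,
#'   so pass the validation subset (e.g. `manifest[manifest$split == "val", ]`).
#' @return A `coralseg_metrics` list: `per_image` (data.frame with the four
#'   metrics per image), `aggregate` (data.frame metric/mean/sd), `micro`
#'   (pixel-pooled metrics).
#' @export
evaluate_dataset <- function(model, manifest) {
  if (nrow(manifest) == 0) stop_data("empty evaluation manifest")
  if (any(is.na(manifest$mask_path)))
    stop_data("all evaluation records must have masks")
  per <- data.frame()
  pool <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  inter <- c(0, 0); uni <- c(0, 0)
  for (i in seq_len(nrow(manifest))) {
    img <- load_gray_image(manifest$image_path[i])
    gt <- load_mask(manifest$mask_path[i])
    pred <- predict_mask(deeperlabc_forward(model, img))
    m <- image_metrics(pred, gt)
    per <- rbind(per, data.frame(image = basename(manifest$image_path[i]),
                                 precision = m["precision"], recall = m["recall"],
                                 f1 = m["f1"], mean_iou = m["mean_iou"],
                                 row.names = NULL))
    cc <- confusion_counts(pred, gt)
    for (nm in names(pool)) pool[[nm]] <- pool[[nm]] + cc[[nm]]
    for (k in 1:2) {
      kk <- k - 1L
      inter[k] <- inter[k] + sum(pred == kk & gt == kk)
      uni[k] <- uni[k] + sum(pred == kk | gt == kk)
    }
  }
  sd_pop <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  agg <- data.frame(
    metric = c("precision", "recall", "f1", "mean_iou"),
    mean = vapply(c("precision", "recall", "f1", "mean_iou"),
                  function(nm) mean(per[[nm]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("precision", "recall", "f1", "mean_iou"),
                function(nm) sd_pop(per[[nm]]), numeric(1)),
    row.names = NULL)
  mpr <- precision(pool); mre <- recall(pool)
  micro <- c(precision = mpr, recall = mre, f1 = f1_score(mpr, mre),
             mean_iou = mean(ifelse(uni == 0, NA, inter / uni), na.rm = TRUE))
  structure(list(per_image = per, aggregate = agg, micro = micro),
            class = "coralseg_metrics")
}

#' Write a metrics report as JSON and CSV (values in percent)
#'
#' @param report A `coralseg_metrics` from [evaluate_dataset()].
#' @param dir Output directory; writes `metrics.json` and
#'   `metrics_per_image.csv`.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- report$per_image
  for (nm in c("precision", "recall", "f1", "mean_iou")) per[[nm]] <- 100 * per[[nm]]
  utils::write.csv(per, file.path(dir, "metrics_per_image.csv"), row.names = FALSE)
  agg <- report$aggregate
  out <- list(
    aggregate = lapply(seq_len(nrow(agg)), function(i)
      list(metric = agg$metric[i], mean_pct = 100 * agg$mean[i],
           sd_pct = 100 * agg$sd[i])),
    micro_pct = as.list(100 * report$micro),
    n_images = nrow(per))
  jsonlite::write_json(out, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.coralseg_metrics <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "images (mean +- sd, %):\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-9s %6.2f +- %5.2f\n", a$metric[i], 100 * a$mean[i],
                100 * a$sd[i]))
  invisible(x)
}
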