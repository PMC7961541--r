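# Desk-scale trained artifacts are expensive (tens of seconds), so they are
# built once per test session and shared across test files.

.trained_cache <- new.env(parent = emptyenv())

# Full pipeline: 80 synthetic 64-pixel scenes (64 train / 16 val),
# quarter-width model, backbone pre-training, segmentation training, CAM
# fine-tuning. Fixed seed.
get_smoke <- function() {
  if (is.null(.trained_cache$smoke))
    .trained_cache$smoke <- cmd_pipeline_smoke(seed = 1L)
  .trained_cache$smoke
}

# Overfit regime: 8 positive scenes memorized with 200 steps.
get_overfit <- function() {
  if (is.null(.trained_cache$overfit)) {
    dir <- tempfile("overfit")
    cfg <- scene_config(side = 64L, seed = 11L, positive_fraction = 1)
    man <- generate_dataset(cfg, 8L, dir, split_fraction = 1)
    mcfg <- desk_config()
    model <- train_segmentation(
      man, train_config("segment", epochs = 200L, batch_size = 8L,
                        v0 = 2e-3, seed = 3L, augment = FALSE), mcfg)
    mious <- vapply(seq_len(nrow(man)), function(i) {
      img <- load_gray_image(man$image_path[i])
      gt <- load_mask(man$mask_path[i])
      mean_iou(predict_mask(deeperlabc_forward(model, img)), gt)
    }, numeric(1))
    .trained_cache$overfit <- list(model = model, manifest = man,
                                   train_mious = mious)
  }
  .trained_cache$overfit
}
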