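test_that("cross entropy matches its analytic limits and a scalar-loop oracle", {
  gt <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  # probability 1 on the true class everywhere -> loss 0
  perfect <- array(0, c(2, 2, 2))
  perfect[1, , ] <- ifelse(gt == 0, 50, -50)
  perfect[2, , ] <- ifelse(gt == 1, 50, -50)
  expect_equal(cross_entropy_loss(perfect, gt), 0, tolerance = 1e-12)
  # uniform logits -> ln 2 per pixel, the maximum-entropy binary case
  expect_equal(cross_entropy_loss(array(0.7, c(2, 4, 4)), random_mask(4, 4)),
               log(2), tolerance = 1e-12)
  # random 3x3 case vs the per-pixel hand computation
  set.seed(30)
  lg <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  g3 <- random_mask(3, 3)
  expect_equal(cross_entropy_loss(lg, g3), ref_ce(lg, g3), tolerance = 1e-10)
  expect_equal(cross_entropy_loss(lg, g3, reduction = "sum"),
               ref_ce(lg, g3) * 9, tolerance = 1e-9)
  expect_gte(cross_entropy_loss(lg, g3), 0)
  expect_error(cross_entropy_loss(lg, random_mask(4, 4)),
               class = "coralseg_shape_error")
})

test_that("loss gradients match finite differences on a 2x2 case", {
  set.seed(31)
  lg <- array(rnorm(2 * 2 * 2), c(2, 2, 2, 1))
  gt <- array(random_mask(2, 2), c(2, 2, 1))
  ce <- coralseg:::ce_seg(lg, gt)
  eps <- 1e-6
  for (i in seq_along(lg)) {
    lp <- lg; lp[i] <- lp[i] + eps
    lm <- lg; lm[i] <- lm[i] - eps
    fd <- (coralseg:::ce_seg(lp, gt)$loss - coralseg:::ce_seg(lm, gt)$loss) /
      (2 * eps)
    expect_equal(ce$dlogits[i], fd, tolerance = 1e-4)
  }
})

test_that("the learning rate decays exponentially from its reference constants", {
  expect_identical(lr_at_epoch(0), 1e-4)
  expect_equal(lr_at_epoch(1) / lr_at_epoch(0), 0.99, tolerance = 1e-12)
  expect_equal(lr_at_epoch(2), 9.801e-5, tolerance = 1e-12)
  # strictly decreasing for alpha < 1, constant for alpha = 1
  rates <- lr_at_epoch(0:50)
  expect_true(all(diff(rates) < 0))
  expect_true(all(lr_at_epoch(0:50, alpha = 1) == 1e-4))
  expect_error(lr_at_epoch(-1), class = "coralseg_config_error")
  expect_error(lr_at_epoch(0, alpha = 1.5), class = "coralseg_config_error")
})

test_that("training configurations carry the reference-scale defaults", {
  p <- train_config("pretrain")
  expect_equal(c(p$epochs, p$batch_size), c(200L, 32L))
  s <- train_config("segment")
  expect_equal(c(s$epochs, s$batch_size), c(150L, 16L))
  expect_equal(s$v0, 1e-4)
  expect_equal(s$alpha, 0.99)
})

test_that("backbone pre-training learns separable classes and replays exactly", {
  d <- withr::local_tempdir()
  cfg <- scene_config(side = 64L, seed = 41L)
  man <- generate_dataset(cfg, 48L, d, split_fraction = 0.75)
  mcfg <- desk_config()
  tcfg <- train_config("pretrain", epochs = 6L, batch_size = 16L,
                       v0 = 1e-3, seed = 42L)
  bb <- pretrain_backbone(man, tcfg, mcfg)
  h <- bb$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])     # learning progress
  # bright-blob positives vs background negatives are linearly separable in
  # intensity: the image-level classifier should get nearly all of them
  expect_gte(h$val_accuracy[nrow(h)], 0.9)
  # deterministic replay: identical loss curves from the same seed
  bb2 <- pretrain_backbone(man, tcfg, mcfg)
  expect_identical(bb$history, bb2$history)
  expect_identical(bb$params, bb2$params)
  empty <- man[man$split == "none", ]
  expect_error(pretrain_backbone(empty, tcfg, mcfg),
               class = "coralseg_data_error")
})

test_that("segmentation training is seeded-deterministic and uses pretraining", {
  d <- withr::local_tempdir()
  cfg <- scene_config(side = 64L, seed = 43L, positive_fraction = 1)
  man <- generate_dataset(cfg, 6L, d, split_fraction = 1)
  mcfg <- desk_config()
  tcfg <- train_config("segment", epochs = 3L, batch_size = 6L,
                       v0 = 1e-3, seed = 44L, augment = FALSE)
  m1 <- train_segmentation(man, tcfg, mcfg)
  m2 <- train_segmentation(man, tcfg, mcfg)
  expect_identical(m1$params, m2$params)                # bit-identical replay
  expect_identical(m1$history, m2$history)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  # a pre-trained backbone changes the epoch-0 loss on the same seed
  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(scene_config(side = 64L, seed = 45L), 12L, d2,
                           split_fraction = 1)
  bb <- pretrain_backbone(man2, train_config("pretrain", epochs = 1L,
                                             batch_size = 12L, v0 = 1e-3,
                                             seed = 46L), mcfg)
  m3 <- train_segmentation(man, tcfg, mcfg, backbone_init = bb)
  expect_false(isTRUE(all.equal(m3$history$train_loss[1],
                                m1$history$train_loss[1])))
  # missing masks are a data error
  man_nomask <- man
  man_nomask$mask_path <- NA_character_
  expect_error(train_segmentation(man_nomask, tcfg, mcfg),
               class = "coralseg_data_error")
})

test_that("per-epoch checkpoints reproduce the training trajectory", {
  d <- withr::local_tempdir()
  ck <- file.path(d, "ckpt")
  man <- generate_dataset(scene_config(side = 64L, seed = 47L,
                                       positive_fraction = 1), 4L, d,
                          split_fraction = 1)
  tcfg <- train_config("segment", epochs = 2L, batch_size = 4L, v0 = 1e-3,
                       seed = 48L, augment = FALSE)
  m <- train_segmentation(man, tcfg, desk_config(), checkpoint_dir = ck)
  files <- list.files(ck, pattern = "^epoch_.*rds$")
  expect_length(files, 2L)
  last <- load_checkpoint(file.path(ck, "epoch_0001.rds"))
  expect_identical(last$params, m$params)
})
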