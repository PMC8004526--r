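test_that("training descends and is reproducible under a seed", {
  samples <- toy_samples(12, w = 8, o = 3, seed = 3)
  cfg <- train_config(epochs = 8L, batch_size = 4L, learning_rate = 2e-3,
                      step = 8L, seed = 9L, val_fraction = 0.25)
  res1 <- pretrain(samples, cfg, net = tiny_net(seed = 2))
  expect_lt(utils::tail(res1$history$train_loss, 1),
            res1$history$train_loss[1])
  expect_equal(nrow(res1$history), 8L)
  expect_true(all(is.finite(res1$history$val_loss)))

  res2 <- pretrain(samples, cfg, net = tiny_net(seed = 2))
  expect_identical(res1$history, res2$history)
  expect_identical(res1$model$par, res2$model$par)

  expect_error(pretrain(list(), cfg, net = tiny_net()), "non-empty")
})

test_that("feedback with zero budget reduces exactly to continued training", {
  tr <- toy_triple(c(24, 24, 24), max_mag = 1.5, seed = 12)
  net <- network_config(window = 8, output = 3, base_features = 1,
                        n_encoders = 1, dropout_rate = 0.3, seed = 3)
  cfg <- train_config(epochs = 2L, batch_size = 8L, learning_rate = 1e-3,
                      step = 8L, seed = 21L,
                      feedback = list(extra_per_volume = 0L,
                                      retain_old = TRUE))
  samples <- build_training_set(list(tr), w = 8, o = 3, step = 8)
  pre <- pretrain(samples, cfg, net = net)

  fb <- self_feedback_finetune(pre$model, list(tr), samples, cfg)
  plain <- continue_training(pre$model, samples, cfg)
  expect_identical(fb$model$par, plain$model$par)
  expect_identical(fb$history, plain$history)
  expect_equal(fb$report$n_new, 0L)
})

test_that("a perfect predictor yields an empty feedback set", {
  tr <- toy_triple(c(24, 24, 24), max_mag = 1.5, seed = 4)
  net <- tiny_net(seed = 1)
  cfg <- train_config(epochs = 1L, batch_size = 8L, learning_rate = 1e-3,
                      step = 8L, seed = 5L,
                      feedback = list(extra_per_volume = 40L,
                                      retain_old = TRUE))
  samples <- build_training_set(list(tr), w = 8, o = 3, step = 8)
  pre <- pretrain(samples, cfg, net = net)
  fb <- self_feedback_finetune(pre$model, list(tr), samples, cfg,
                               predict_fn = function(fixed, moving)
                                 tr$gt_field)
  expect_equal(fb$report$n_new, 0L)
  expect_length(fb$report$volumes[[1]]$n_per_bin, 0L)
})

test_that("feedback draws extra samples from high-error regions", {
  tr <- toy_triple(c(24, 24, 24), max_mag = 2.5, seed = 6)
  net <- tiny_net(seed = 2)
  cfg <- train_config(epochs = 1L, batch_size = 8L, learning_rate = 1e-3,
                      step = 8L, seed = 6L,
                      feedback = list(extra_per_volume = 30L, alpha = 1 / 4,
                                      retain_old = TRUE))
  samples <- build_training_set(list(tr), w = 8, o = 3, step = 8)
  pre <- pretrain(samples, cfg, net = net)
  # a deliberately wrong predictor: all errors land in bins >= 1
  fb <- suppressMessages(
    self_feedback_finetune(pre$model, list(tr), samples, cfg,
                           predict_fn = function(fixed, moving)
                             zero_field(c(24, 24, 24))))
  # bins whose voxels all sit too close to the border are skipped (logged),
  # so the drawn count equals the post-skip allocation, not necessarily A
  rep1 <- fb$report$volumes[[1]]
  expect_gt(fb$report$n_new, 0L)
  expect_equal(fb$report$n_new, sum(rep1$s_per_bin))
  expect_gt(length(rep1$n_per_bin), 0L)
  # retain_old = FALSE trains on the new samples alone
  cfg2 <- cfg
  cfg2$feedback$retain_old <- FALSE
  fb2 <- suppressMessages(
    self_feedback_finetune(pre$model, list(tr), samples, cfg2,
                           predict_fn = function(fixed, moving)
                             zero_field(c(24, 24, 24))))
  expect_false(fb2$report$retain_old)
  expect_false(identical(fb$model$par, fb2$model$par))
})

test_that("residual_field composes the coarse prediction toward the truth", {
  sh <- c(24, 24, 24)
  gt <- toy_field(sh, max_mag = 2, sigma = 6, seed = 31)
  # perfect level 1: residual ~ 0
  r0 <- dhreg:::residual_field(gt, gt)
  nrm <- sqrt(r0$vectors[, , , 1]^2 + r0$vectors[, , , 2]^2 +
                r0$vectors[, , , 3]^2)
  expect_lt(max(nrm), 1e-6)
  # imperfect level 1: warping sequentially with (p1, residual) ~ gt warp
  p1 <- scale_field(gt, 0.6)
  r <- dhreg:::residual_field(gt, p1)
  vol <- toy_volume(sh, seed = 2)
  vol$data <- dhreg:::gaussian_smooth3d(vol$data, 1.5)
  seq_w <- warp_volume(warp_volume(vol, p1), r)
  ref_w <- warp_volume(vol, gt)
  expect_lt(mean(abs(seq_w$data[5:20, 5:20, 5:20] -
                       ref_w$data[5:20, 5:20, 5:20])), 0.01)
})

test_that("train_level2 learns residuals of a stubbed coarse stage", {
  sh <- c(24, 24, 24)
  tr <- toy_triple(sh, max_mag = 1.5, seed = 8)
  net <- tiny_net(seed = 4)
  cfg <- train_config(epochs = 1L, batch_size = 8L, learning_rate = 1e-3,
                      step = 8L, seed = 7L, augment_factors_l2 = c(1, 0.5),
                      feedback = list(enabled = FALSE))
  samples1 <- build_training_set(list(tr), w = 8, o = 3, step = 8)
  l1 <- pretrain(samples1, cfg, net = net)$model
  res <- train_level2(l1, list(tr), cfg)
  expect_s3_class(res$model, "dh_model")
  expect_gt(nrow(res$history), 0L)
  expect_length(res$volumes2w, 1L)
  # residual targets are smaller than the original deformation on average
  res_gt <- res$volumes2w[[1]]$gt_field
  expect_lt(mean(abs(res_gt$vectors)), mean(abs(tr$gt_field$vectors)) + 0.5)
})
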