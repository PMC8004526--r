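test_that("phantoms are deterministic, labelled, and normalised", {
  spec <- phantom_spec(c(48, 48, 48), n_regions = 5, texture_scale = 3,
                       seed = 21)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$labels$labels, p2$labels$labels)
  expect_setequal(unique(as.vector(p1$labels$labels)), 0:5)
  expect_gte(min(p1$volume$data), 0)
  expect_lte(max(p1$volume$data), 1)
  # texture carries local detail inside the brain mask
  inside <- p1$labels$labels == 0 & p1$volume$data > 0
  expect_gt(stats::sd(p1$volume$data[inside]), 0.02)
  expect_error(phantom_spec(c(48, 48), 5), "shape")
  expect_error(phantom_spec(c(48, 48, 48), 1), "n_regions")
})

test_that("smooth fields honour magnitude, smoothness and fold-freedom", {
  sh <- c(32, 32, 32)
  f0 <- make_smooth_field(sh, field_spec(0, 8, seed = 1))
  expect_true(all(f0$vectors == 0))

  f <- make_smooth_field(sh, field_spec(3, 8, seed = 2))
  nrm <- sqrt(f$vectors[, , , 1]^2 + f$vectors[, , , 2]^2 +
                f$vectors[, , , 3]^2)
  expect_equal(max(nrm), 3, tolerance = 1e-6)
  expect_equal(jacobian_report(f)$n_nonpositive, 0L)
  # determinism
  expect_identical(f$vectors,
                   make_smooth_field(sh, field_spec(3, 8, seed = 2))$vectors)
  # a rough, large field violates the diffeomorphism bound
  expect_error(make_smooth_field(c(16, 16, 16),
                                 field_spec(10, 0.5, seed = 3)),
               "fold-free")
})

test_that("generated fields are invertible in practice", {
  sh <- c(32, 32, 32)
  ph <- make_phantom(phantom_spec(sh, 3, 2, seed = 5))
  for (s in 1:3) {
    f <- make_smooth_field(sh, field_spec(3, 8, seed = s))
    fwd <- warp_volume(ph$volume, f)
    back <- warp_volume(fwd, dhreg:::invert_field(f))
    err <- abs(back$data - ph$volume$data)
    expect_lt(mean(err[8:24, 8:24, 8:24]), 0.03)
  }
})

test_that("make_dataset writes a consistent corpus", {
  dir <- withr::local_tempdir()
  corpus <- make_dataset(2, 2, 1,
                         phantom = phantom_spec(c(24, 24, 24), 3, 2),
                         large = field_spec(2, 6),
                         small = field_spec(0.7, 6),
                         out_dir = dir, seed = 3)
  expect_length(corpus$train1, 2L)
  expect_length(corpus$train2, 2L)
  expect_length(corpus$val, 1L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  dirs <- list.dirs(dir, recursive = FALSE)
  expect_length(dirs, 5L)
  for (f in c("fixed.nii.gz", "moving.nii.gz", "gt_field.nii.gz",
              "labels_fixed.nii.gz", "labels_moving.nii.gz"))
    expect_true(file.exists(file.path(dirs[1], f)))

  # round trip through disk reproduces the in-memory corpus
  loaded <- load_dataset(dir)
  expect_equal(loaded$train1[[1]]$moving$data, corpus$train1[[1]]$moving$data)
  expect_equal(loaded$train2[[2]]$gt_field$vectors,
               corpus$train2[[2]]$gt_field$vectors)

  # warping the moving volume by the ground truth recovers the fixed one
  s <- corpus$train1[[1]]
  rec <- warp_volume(s$moving, s$gt_field)
  expect_lt(mean(abs(rec$data - s$fixed$data)[5:20, 5:20, 5:20]), 0.05)

  # reproducibility under the top-level seed
  corpus2 <- make_dataset(2, 2, 1,
                          phantom = phantom_spec(c(24, 24, 24), 3, 2),
                          large = field_spec(2, 6),
                          small = field_spec(0.7, 6), seed = 3)
  expect_identical(corpus2$train1[[2]]$gt_field$vectors,
                   corpus$train1[[2]]$gt_field$vectors)
  expect_identical(corpus2$val[[1]]$moving$data, corpus$val[[1]]$moving$data)

  # difficulty ordering: labels move less under the small residual fields
  d_large <- dice_score(corpus$train1[[1]]$labels_fixed,
                        corpus$train1[[1]]$labels_moving)
  expect_lt(d_large$mean, 1)
  expect_error(make_dataset(1, 1, 1, large = field_spec(1, 8),
                            small = field_spec(2, 8)), "exceed")
})

test_that("pre-registration Dice is lower for larger deformations", {
  sh <- c(32, 32, 32)
  ph <- make_phantom(phantom_spec(sh, 4, 2, seed = 9))
  dice_for <- function(mag) {
    f <- make_smooth_field(sh, field_spec(mag, 8, seed = 11))
    lw <- warp_volume(ph$labels, dhreg:::invert_field(f))
    dice_score(ph$labels, lw)$mean
  }
  expect_lt(dice_for(3), dice_for(1))
})
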