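test_that("constant-stub prediction assembles to that constant exactly", {
  sh <- c(20, 18, 16)
  fx <- toy_volume(sh, seed = 1)
  mv <- toy_volume(sh, seed = 2)
  const_stub <- function(fp, mp) {
    blk <- array(0, c(5, 5, 5, 3))
    blk[, , , 1] <- 0.7; blk[, , , 2] <- -1.2; blk[, , , 3] <- 2.5
    blk
  }
  f <- predict_field(const_stub, fx, mv, window = 16, output = 5,
                     smooth_radius = 0)
  expect_equal(dim(f$vectors), c(sh, 3L))
  # averaging equal contributions reproduces the constant (to fp summation)
  expect_lt(max(abs(f$vectors[, , , 1] - 0.7)), 1e-12)
  expect_lt(max(abs(f$vectors[, , , 2] + 1.2)), 1e-12)
  expect_lt(max(abs(f$vectors[, , , 3] - 2.5)), 1e-12)
  # smoothing a constant field changes nothing
  fs <- predict_field(const_stub, fx, mv, window = 16, output = 5,
                      smooth_radius = 1)
  expect_equal(fs$vectors, f$vectors)
})

test_that("ground-truth-block stub reproduces the field exactly", {
  sh <- c(32, 32, 32)
  fx <- toy_volume(sh, seed = 3)
  mv <- toy_volume(sh, seed = 4)
  gt <- toy_field(sh, max_mag = 2, sigma = 6, seed = 5)
  w <- 16L; o <- 5L
  pad <- as.integer(ceiling((w - o) / 2))
  psh <- sh + 2L * pad
  idx <- lapply(1:3, function(a) pmin(pmax(seq_len(psh[a]) - pad, 1L), sh[a]))
  gt_pad <- gt$vectors[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  centers <- grid_centers(psh, w, o)
  k <- 0L
  gt_stub <- function(fp, mp) {
    k <<- k + 1L
    te <- dhreg:::target_extent(centers[k, ], o)
    gt_pad[te$start[1]:te$end[1], te$start[2]:te$end[2],
           te$start[3]:te$end[3], , drop = FALSE]
  }
  f <- predict_field(gt_stub, fx, mv, window = w, output = o,
                     smooth_radius = 0)
  expect_equal(f$vectors, gt$vectors, tolerance = 1e-12)
  cov <- attr(f, "coverage")
  expect_true(all(cov$W >= 1))
  expect_equal(cov$n_windows, nrow(centers))
})

test_that("overlap averaging implements sum / count exactly", {
  sh <- c(20, 16, 16)
  fx <- toy_volume(sh, seed = 6)
  mv <- toy_volume(sh, seed = 7)
  w <- 16L; o <- 5L
  pad <- as.integer(ceiling((w - o) / 2))
  psh <- sh + 2L * pad
  centers <- grid_centers(psh, w, o)
  # deterministic pseudo-random block per window index
  blocks <- dhreg:::with_seed(99, lapply(seq_len(nrow(centers)), function(i)
    array(rnorm(o^3 * 3), c(o, o, o, 3))))
  k <- 0L
  stub <- function(fp, mp) { k <<- k + 1L; blocks[[k]] }
  f <- predict_field(stub, fx, mv, window = w, output = o, smooth_radius = 0)
  # brute-force accumulation oracle
  phi <- array(0, c(psh, 3)); Wc <- array(0, psh)
  for (i in seq_len(nrow(centers))) {
    te <- dhreg:::target_extent(centers[i, ], o)
    zz <- te$start[1]:te$end[1]; yy <- te$start[2]:te$end[2]
    xx <- te$start[3]:te$end[3]
    phi[zz, yy, xx, ] <- phi[zz, yy, xx, , drop = FALSE] + blocks[[i]]
    Wc[zz, yy, xx] <- Wc[zz, yy, xx] + 1
  }
  crop <- lapply(sh, function(L) pad + seq_len(L))
  expected <- phi[crop[[1]], crop[[2]], crop[[3]], , drop = FALSE] /
    as.numeric(pmax(Wc[crop[[1]], crop[[2]], crop[[3]]], 1))
  expect_equal(f$vectors, expected, tolerance = 1e-12)
  # overlapping voxels exist and carry the two-term average
  Wcrop <- attr(f, "coverage")$W
  expect_gt(max(Wcrop), 1L)
  expect_equal(Wcrop, Wc[crop[[1]], crop[[2]], crop[[3]]])
})

test_that("W depends only on geometry, not the model", {
  sh <- c(20, 20, 20)
  fx <- toy_volume(sh, seed = 8); mv <- toy_volume(sh, seed = 9)
  s1 <- function(fp, mp) array(1, c(5, 5, 5, 3))
  s2 <- function(fp, mp) array(rnorm(375), c(5, 5, 5, 3))
  f1 <- predict_field(s1, fx, mv, window = 16, output = 5, smooth_radius = 0)
  f2 <- predict_field(s2, fx, mv, window = 16, output = 5, smooth_radius = 0)
  expect_identical(attr(f1, "coverage")$W, attr(f2, "coverage")$W)
})

test_that("network prediction is deterministic and respects contracts", {
  sh <- c(20, 20, 20)
  fx <- toy_volume(sh, seed = 10); mv <- toy_volume(sh, seed = 11)
  m <- build_model(network_config(window = 16, output = 5,
                                  base_features = 1, n_encoders = 2,
                                  dropout_rate = 0.5, seed = 13))
  fa <- predict_field(m, fx, mv)
  fb <- predict_field(m, fx, mv)
  expect_identical(fa$vectors, fb$vectors)
  # batched and sequential traversal agree
  fc <- predict_field(m, fx, mv, batch_size = 3L)
  expect_equal(fc$vectors, fa$vectors, tolerance = 1e-12)
  expect_error(predict_field(m, fx, mv, window = 32), "match")
  expect_error(predict_field(function(a, b) NULL, fx, mv), "required")
})

test_that("two-level registration composes stubs correctly", {
  sh <- c(24, 24, 24)
  tr <- toy_triple(sh, max_mag = 1.5, seed = 14)
  zero_stub <- function(fp, mp) array(0, c(5, 5, 5, 3))
  out <- register_volumes(list(level1 = zero_stub, level2 = zero_stub),
                          tr$moving, tr$fixed, window = 16, output = 5)
  expect_equal(out$warped$data, tr$moving$data)
  expect_true(all(out$composed$vectors == 0))

  # level 1 = exact ground truth blocks, level 2 = zero
  w <- 16L; o <- 5L
  pad <- as.integer(ceiling((w - o) / 2))
  psh <- sh + 2L * pad
  idx <- lapply(1:3, function(a) pmin(pmax(seq_len(psh[a]) - pad, 1L), sh[a]))
  gt_pad <- tr$gt_field$vectors[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  centers <- grid_centers(psh, w, o)
  k <- 0L
  gt_stub <- function(fp, mp) {
    k <<- k + 1L
    if (k > nrow(centers)) k <<- 1L
    te <- dhreg:::target_extent(centers[k, ], o)
    gt_pad[te$start[1]:te$end[1], te$start[2]:te$end[2],
           te$start[3]:te$end[3], , drop = FALSE]
  }
  out2 <- register_volumes(list(level1 = gt_stub, level2 = zero_stub),
                           tr$moving, tr$fixed, window = w, output = o,
                           smooth_radius = 0)
  expect_equal(out2$warped$data, warp_volume(tr$moving, tr$gt_field)$data,
               tolerance = 1e-12)
  # similarity to the fixed image improves over the unregistered moving
  ncc <- function(a, b) stats::cor(as.vector(a), as.vector(b))
  expect_gt(ncc(out2$warped$data, tr$fixed$data),
            ncc(tr$moving$data, tr$fixed$data))
})
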