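test_that("grid_centers counts and end-alignment match enumeration", {
  expect_equal(nrow(grid_centers(c(64, 64, 64), 64, 32)), 1L)
  expect_equal(nrow(grid_centers(c(128, 128, 128), 64, 32)), 27L)
  # (100, 64, 64): 100 -> starts 1, 33, end-aligned 37; others exact fit
  g <- grid_centers(c(100, 64, 64), 64, 32)
  expect_equal(nrow(g), 3L)
  expect_equal(sort(unique(g[, "z"])), c(1, 33, 37) + 32)
  expect_error(grid_centers(c(32, 64, 64), 64, 32), "exceeds")
})

test_that("grid windows cover every axis", {
  for (L in c(17, 33, 50, 96)) {
    g <- grid_centers(c(L, 17, 17), 16, 12)
    starts <- sort(unique(g[, "z"])) - 8L
    covered <- sort(unique(unlist(lapply(starts, function(s) s:(s + 15)))))
    expect_equal(covered, 1:L)
  }
})

test_that("extract_patch_pair slices the expected blocks", {
  sh <- c(64, 64, 64)
  tr <- list(fixed = toy_volume(sh, seed = 1), moving = toy_volume(sh, 2))
  gt <- zero_field(sh)
  ctr <- c(33L, 33L, 33L)
  p <- extract_patch_pair(tr$fixed, tr$moving, gt, ctr, w = 64, o = 9)
  expect_equal(p$fixed_patch, tr$fixed$data)    # exact-fit window
  expect_equal(p$moving_patch, tr$moving$data)
  expect_true(all(p$target == 0))
  expect_equal(dim(p$target), c(9L, 9L, 9L, 3L))

  # ramp-valued field: target equals direct slicing
  gt$vectors[, , , 1] <- array(rep(1:64, each = 64 * 64), sh)
  p2 <- extract_patch_pair(tr$fixed, tr$moving, gt, c(20L, 30L, 40L), 16, 5)
  expect_equal(p2$target, gt$vectors[18:22, 28:32, 38:42, , drop = FALSE])

  expect_error(extract_patch_pair(tr$fixed, tr$moving, gt, c(4L, 33L, 33L),
                                  16, 5), "out of bounds")
  expect_error(extract_patch_pair(tr$fixed, tr$moving, gt, ctr, 16, 16),
               "smaller")
})

test_that("distance_histogram rounds half-up and drops zeros", {
  h0 <- distance_histogram(array(0, c(5, 5, 5)))
  expect_length(h0$n_per_bin, 0L)

  d <- array(0, c(2, 2, 1)); d[] <- c(0.4, 1.2, 1.4, 2.6)
  h <- distance_histogram(d)
  expect_equal(unname(h$n_per_bin), c(2L, 0L, 1L))
  expect_equal(names(h$n_per_bin), c("1", "2", "3"))

  h2 <- distance_histogram(array(2, c(10, 10, 10)))
  expect_equal(unname(h2$n_per_bin), c(0L, 1000L))
  # half-up boundary: 1.5 -> 2, 2.5 -> 3
  h3 <- distance_histogram(array(c(1.5, 2.5), c(2, 1, 1)))
  expect_equal(unname(h3$n_per_bin), c(0L, 1L, 1L))
})

test_that("allocate_samples reproduces the closed-form allocation", {
  a <- allocate_samples(c(100L, 100L), alpha = 0.5, A = 10L)
  expect_equal(unname(a$s_per_bin), c(5L, 5L))

  # hand evaluation: weights (0.1, 0.3162...) -> raw (26.43, 83.57)
  b <- allocate_samples(c(100L, 10L), alpha = 0.5, A = 110L)
  expect_equal(unname(b$s_per_bin), c(26L, 84L))

  expect_error(allocate_samples(c(0L, 0L), 0.5, 5L), "empty")
  expect_error(allocate_samples(c(5L, 5L), 0, 5L), "alpha")
})

test_that("allocation sums exactly to A and is monotone in bin counts", {
  set.seed(7)
  for (i in 1:60) {
    nb <- sample(1:8, 1)
    N <- as.integer(rpois(nb, lambda = sample(c(5, 50, 500), 1)))
    if (all(N == 0L)) N[1] <- 1L
    alpha <- sample(c(1, 1/2, 1/4, 1/8, 1/16, 1/32), 1)
    A <- sample(0:500, 1)
    al <- allocate_samples(N, alpha, A)
    expect_identical(sum(al$s_per_bin), as.integer(A))
    expect_true(all(al$s_per_bin[N == 0L] == 0L))
    nz <- which(N > 0L)
    for (i1 in nz) for (i2 in nz)
      if (N[i1] < N[i2]) expect_gte(al$s_per_bin[i1], al$s_per_bin[i2])
  }
})

test_that("smaller alpha flattens the allocation", {
  N <- c(2000L, 200L, 20L, 2L)
  flat <- allocate_samples(N, 1 / 32, 1000L)$s_per_bin
  steep <- allocate_samples(N, 1 / 2, 1000L)$s_per_bin
  expect_lt(stats::var(flat), stats::var(steep))
})

test_that("draw_feedback_centers respects bins, margins and the seed", {
  sh <- c(20, 20, 20)
  d <- array(0, sh)
  d[9:12, 9:12, 9:12] <- 2          # one eligible cluster
  al <- allocate_samples(distance_histogram(d), 0.5, 10L)
  ctr <- draw_feedback_centers(d, al, margin = 8, seed = 3)
  expect_equal(nrow(ctr), 10L)
  expect_true(all(ctr[, "bin"] == 2L))
  for (i in seq_len(nrow(ctr)))
    expect_equal(dhreg:::round_half_up(d[ctr[i, 1], ctr[i, 2], ctr[i, 3]]),
                 2)
  ctr2 <- draw_feedback_centers(d, al, margin = 8, seed = 3)
  expect_identical(ctr, ctr2)
  expect_false(identical(ctr,
                         draw_feedback_centers(d, al, margin = 8, seed = 4)))

  # exactly-exhausted bin: all three voxels drawn
  d2 <- array(0, sh)
  picks <- rbind(c(10, 10, 10), c(11, 10, 10), c(10, 12, 11))
  for (i in 1:3) d2[picks[i, 1], picks[i, 2], picks[i, 3]] <- 3
  al2 <- allocate_samples(distance_histogram(d2), 0.5, 3L)
  ctr3 <- draw_feedback_centers(d2, al2, margin = 8, seed = 1)
  expect_equal(nrow(ctr3), 3L)
  expect_setequal(apply(ctr3[, 1:3], 1, paste, collapse = ","),
                  apply(picks, 1, paste, collapse = ","))

  # short bin falls back to replacement with a warning
  al3 <- allocate_samples(distance_histogram(d2), 0.5, 8L)
  expect_warning(ctr4 <- draw_feedback_centers(d2, al3, margin = 8, seed = 1),
                 "replacement")
  expect_equal(nrow(ctr4), 8L)
})

test_that("build_training_set augments by warp scaling", {
  sh <- c(32, 32, 32)
  tr <- toy_triple(sh, max_mag = 1.5)
  one <- build_training_set(list(tr), w = 32, o = 5, step = 32)
  expect_length(one, 1L)

  three <- build_training_set(list(tr), w = 32, o = 5, step = 32,
                              augment_factors = c(1, -1, 2))
  expect_length(three, 3L)
  expect_equal(vapply(three, function(p) attr(p, "factor"), 1), c(1, -1, 2))
  # factor 1 reproduces the plain extraction
  expect_equal(three[[1]]$moving_patch, one[[1]]$moving_patch)
  # scaled targets are exact multiples
  expect_equal(three[[2]]$target, -one[[1]]$target)
  expect_equal(three[[3]]$target, 2 * one[[1]]$target)

  # zero ground truth: all targets zero, moving untouched by augmentation
  tr0 <- list(fixed = tr$fixed, moving = tr$moving, gt_field = zero_field(sh))
  s0 <- build_training_set(list(tr0), w = 16, o = 5, step = 16,
                           augment_factors = c(1, -1))
  expect_true(all(vapply(s0, function(p) all(p$target == 0), TRUE)))
})
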