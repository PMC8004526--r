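test_that("warping identities hold", {
  v <- toy_volume(c(10, 10, 10))
  expect_equal(warp_volume(v, zero_field(c(10, 10, 10)))$data, v$data)

  const <- volume(array(0.4, c(10, 10, 10)))
  f <- toy_field(c(10, 10, 10), max_mag = 2)
  expect_true(all(abs(warp_volume(const, f)$data - 0.4) < 1e-12))
})

test_that("warp matches direct index arithmetic on translations", {
  v <- ramp_volume(c(8, 8, 8))
  w <- warp_volume(v, shift_field(c(8, 8, 8), dx = 1))
  # interior: out[z,y,x] = v[z,y,x+1]
  expect_equal(w$data[, , 1:7], v$data[, , 2:8])
  # border replication on the last x-slab
  expect_equal(w$data[, , 8], v$data[, , 8])

  # integer translation along all axes at once
  v2 <- toy_volume(c(9, 9, 9), seed = 4)
  w2 <- warp_volume(v2, shift_field(c(9, 9, 9), dx = 2, dy = 1, dz = 3))
  expect_equal(w2$data[1:6, 1:8, 1:7], v2$data[4:9, 2:9, 3:9])
})

test_that("scale_field is exact scalar algebra", {
  f <- toy_field(c(8, 8, 8))
  expect_equal(scale_field(f, 1), f)
  expect_equal(scale_field(scale_field(f, 2), 0.5)$vectors, f$vectors)
  expect_equal(scale_field(f, -1)$vectors, -f$vectors)
})

test_that("compose_fields matches sequential warping", {
  sh <- c(16, 16, 16)
  expect_equal(compose_fields(zero_field(sh), toy_field(sh))$vectors,
               toy_field(sh)$vectors)
  # translation group
  a <- shift_field(sh, dx = 1.5, dz = -0.5)
  b <- shift_field(sh, dy = 2, dz = 1)
  expect_equal(compose_fields(a, b)$vectors, (a$vectors + b$vectors),
               tolerance = 1e-12)
  # smooth fields: sequential warp vs composed warp
  f1 <- toy_field(sh, max_mag = 1.2, sigma = 5, seed = 2)
  f2 <- toy_field(sh, max_mag = 0.8, sigma = 5, seed = 3)
  m <- toy_volume(sh, seed = 6)
  m$data <- dhreg:::gaussian_smooth3d(m$data, 1.5)  # band-limit the texture
  seq_warp <- warp_volume(warp_volume(m, f1), f2)
  one_warp <- warp_volume(m, compose_fields(f1, f2))
  expect_lt(max(abs(seq_warp$data - one_warp$data)), 0.02)
})

test_that("mean_filter_field is an exact box average", {
  f <- toy_field(c(9, 9, 9))
  expect_equal(mean_filter_field(f, 0), f)
  cf <- shift_field(c(9, 9, 9), dx = 3, dy = -1)
  expect_equal(mean_filter_field(cf, 2)$vectors, cf$vectors)
  # unit spike spreads to 27 voxels of 1/27
  sp <- zero_field(c(9, 9, 9))
  sp$vectors[5, 5, 5, 2] <- 1
  sm <- mean_filter_field(sp, 1)
  expect_equal(sm$vectors[5, 5, 5, 2], 1 / 27)
  expect_equal(sum(sm$vectors[, , , 2] > 0), 27L)
  expect_equal(sum(sm$vectors[, , , 2]), 1)
})

test_that("jacobian determinant matches closed forms", {
  sh <- c(8, 8, 8)
  jd <- jacobian_determinant(zero_field(sh))
  expect_true(all(abs(jd[2:7, 2:7, 2:7] - 1) < 1e-12))
  expect_true(all(is.na(jd[1, , ])))

  jd2 <- jacobian_determinant(shift_field(sh, dx = 4, dy = -2, dz = 1))
  expect_true(all(abs(jd2[2:7, 2:7, 2:7] - 1) < 1e-12))

  # affine field u = (a x, b y, c z) -> det = (1+a)(1+b)(1+c)
  af <- zero_field(sh)
  abc <- c(0.1, -0.05, 0.2)
  for (i in 1:8) {
    af$vectors[, , i, 1] <- abc[1] * (i - 1)
    af$vectors[, i, , 2] <- abc[2] * (i - 1)
    af$vectors[i, , , 3] <- abc[3] * (i - 1)
  }
  jd3 <- jacobian_determinant(af)
  expect_equal(max(abs(jd3[2:7, 2:7, 2:7] - prod(1 + abc))), 0,
               tolerance = 1e-6)
  expect_error(jacobian_determinant(zero_field(c(2, 5, 5))), ">= 3")
})

test_that("distance_map is the voxel-wise Euclidean error", {
  sh <- c(5, 5, 5)
  f <- toy_field(sh)
  expect_true(all(distance_map(f, f) == 0))
  G <- zero_field(sh); P <- zero_field(sh)
  P$vectors[3, 3, 3, ] <- c(3, 4, 0)
  expect_equal(distance_map(G, P)[3, 3, 3], 5)
  # element-wise brute force on random fields
  set.seed(42)
  G2 <- displacement_field(array(rnorm(prod(sh) * 3), c(sh, 3)))
  P2 <- displacement_field(array(rnorm(prod(sh) * 3), c(sh, 3)))
  dm <- distance_map(G2, P2)
  brute <- array(0, sh)
  for (z in 1:5) for (y in 1:5) for (x in 1:5)
    brute[z, y, x] <- sqrt(sum((G2$vectors[z, y, x, ] -
                                  P2$vectors[z, y, x, ])^2))
  expect_equal(dm, brute)
  # symmetry and triangle inequality against a third field
  expect_equal(distance_map(G2, P2), distance_map(P2, G2))
  H <- displacement_field(array(rnorm(prod(sh) * 3), c(sh, 3)))
  expect_true(all(distance_map(G2, P2) <=
                    distance_map(G2, H) + distance_map(H, P2) + 1e-12))
  expect_error(distance_map(G2, zero_field(c(4, 5, 5))), "lattice")
})

test_that("invert_field undoes smooth deformations", {
  sh <- c(24, 24, 24)
  f <- toy_field(sh, max_mag = 2, sigma = 6, seed = 9)
  inv <- dhreg:::invert_field(f)
  comp <- compose_fields(inv, f)   # warp by inv then by f ~ identity
  nrm <- sqrt(comp$vectors[, , , 1]^2 + comp$vectors[, , , 2]^2 +
                comp$vectors[, , , 3]^2)
  # interior (border clamping distorts the rim)
  expect_lt(mean(nrm[5:20, 5:20, 5:20]), 0.05)
})
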