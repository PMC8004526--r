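# Shared fixture builders.  Everything is generated in code at test time;
# no binary fixtures ship with the package.

# deterministic textured volume (values in [0, 1])
toy_volume <- function(shape = c(12, 12, 12), seed = 1) {
  with_seed <- dhreg:::with_seed
  arr <- with_seed(seed, array(runif(prod(shape)), shape))
  volume(arr)
}

# smooth small test field via the synthetic generator
toy_field <- function(shape = c(12, 12, 12), max_mag = 1.5, sigma = 4,
                      seed = 1) {
  make_smooth_field(shape, field_spec(max_mag, sigma, seed = seed))
}

# uniform translation field
shift_field <- function(shape, dx = 0, dy = 0, dz = 0) {
  f <- zero_field(shape)
  f$vectors[, , , 1] <- dx
  f$vectors[, , , 2] <- dy
  f$vectors[, , , 3] <- dz
  f
}

# ramp volume increasing along the x (third) axis
ramp_volume <- function(shape = c(8, 8, 8)) {
  arr <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  volume(arr / shape[3])
}

# tiny network configuration for fast unit tests
tiny_net <- function(seed = 1L, window = 8L, output = 3L) {
  network_config(window = window, output = output, base_features = 1L,
                 n_encoders = 1L, dropout_rate = 0, seed = seed)
}

# random patch-pair samples for a given geometry
toy_samples <- function(n, w = 8L, o = 3L, seed = 1) {
  dhreg:::with_seed(seed, lapply(seq_len(n), function(i) {
    structure(list(fixed_patch = array(runif(w^3), c(w, w, w)),
                   moving_patch = array(runif(w^3), c(w, w, w)),
                   target = array(rnorm(o^3 * 3, sd = 0.5), c(o, o, o, 3)),
                   center = c(1L, 1L, 1L)), class = "dh_patch")
  }))
}

# a tiny registration triple on a textured phantom
toy_triple <- function(shape = c(32, 32, 32), max_mag = 2, seed = 5) {
  ph <- make_phantom(phantom_spec(shape, n_regions = 3, texture_scale = 2,
                                  seed = seed))
  gt <- make_smooth_field(shape, field_spec(max_mag, 6, seed = seed + 1))
  mov <- warp_volume(ph$volume, dhreg:::invert_field(gt))
  list(fixed = ph$volume, moving = mov, gt_field = gt,
       labels_fixed = ph$labels)
}
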