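# Internal layer engine for the patch-regression network.
#
# Tensors are plain numeric vectors with explicit integer dims
# (D, H, W, C, B).  Parameters live in a flat named list of arrays;
# gradients mirror the names.  Backprop is hand-written per layer over the
# C++ kernels (im2col convolution, pool, PReLU); the linear head and the
# optimiser run in R.

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# One conv unit's parameters: conv weight/bias + PReLU slope
init_conv_unit <- function(cin, cout, k) {
  list(w = he_init(k^3 * cin, cout, k^3 * cin),
       b = numeric(cout),
       a = rep(0.25, cout))
}

pool_out_dim <- function(n) (n - 1L) %/% 2L + 1L

# Forward through one conv unit (conv + PReLU [+ pool]); returns output,
# dims and the cache needed for backprop.
unit_fw <- function(par, name, x, dims, k, pool = TRUE, pool_type = 0L) {
  w <- par[[paste0(name, ".w")]]
  b <- par[[paste0(name, ".b")]]
  a <- par[[paste0(name, ".a")]]
  y <- cpp_conv3d_fw(x, dims, w, b, k)
  ydims <- c(dims[1:3], ncol(w), dims[5])
  act <- cpp_prelu_fw(y, ydims, a)
  cache <- list(x = x, xdims = dims, pre = y, ydims = ydims, k = k)
  if (pool) {
    p <- cpp_pool3d_fw(act, ydims, pool_type)
    cache$pool_in <- act
    cache$pool_idx <- p$idx
    cache$pool_type <- pool_type
    list(out = p$y, dims = as.integer(p$odim), cache = cache)
  } else {
    list(out = act, dims = ydims, cache = cache)
  }
}

# Backward through one conv unit; returns dx and writes parameter grads.
# `need_dx = FALSE` for the first layer (its input gradient is unused).
unit_bw <- function(par, grads, name, cache, dout, pooled, need_dx = TRUE) {
  w <- par[[paste0(name, ".w")]]
  a <- par[[paste0(name, ".a")]]
  if (pooled)
    dout <- cpp_pool3d_bw(dout, cache$pool_idx, cache$ydims, cache$pool_type)
  pb <- cpp_prelu_bw(cache$pre, cache$ydims, a, dout)
  cb <- cpp_conv3d_bw(cache$x, cache$xdims, w, pb$dx, cache$k, need_dx)
  grads[[paste0(name, ".w")]] <- grads[[paste0(name, ".w")]] + cb$dw
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + cb$db
  grads[[paste0(name, ".a")]] <- grads[[paste0(name, ".a")]] + pb$da
  list(dx = cb$dx, grads = grads)
}

branch_names <- c("fix", "mov")
comp_names <- c("x", "y", "z")

# Flat parameter list for a given configuration, seeded.
init_params <- function(cfg) {
  with_seed(cfg$seed, {
    par <- list()
    f0 <- cfg$base_features
    for (br in branch_names) {
      u <- init_conv_unit(1L, f0, 5L)
      par[[paste0(br, ".ic.w")]] <- u$w
      par[[paste0(br, ".ic.b")]] <- u$b
      par[[paste0(br, ".ic.a")]] <- u$a
      cin <- f0
      for (e in seq_len(cfg$n_encoders)) {
        u <- init_conv_unit(cin, 2L * cin, 3L)
        par[[paste0(br, ".e", e, ".w")]] <- u$w
        par[[paste0(br, ".e", e, ".b")]] <- u$b
        par[[paste0(br, ".e", e, ".a")]] <- u$a
        cin <- 2L * cin
      }
    }
    ccat <- 2L * cfg$base_features * 2L^cfg$n_encoders
    s <- cfg$window
    for (i in seq_len(cfg$n_encoders)) s <- pool_out_dim(s)
    for (cp in comp_names) {
      cin <- ccat
      sd_sp <- s
      for (d in 1:3) {
        u <- init_conv_unit(cin, 2L * cin, 3L)
        par[[paste0(cp, ".d", d, ".w")]] <- u$w
        par[[paste0(cp, ".d", d, ".b")]] <- u$b
        par[[paste0(cp, ".d", d, ".a")]] <- u$a
        cin <- 2L * cin
        sd_sp <- pool_out_dim(sd_sp)
      }
      nin <- cin * sd_sp^3
      # zero-initialised head: the untrained model predicts the identity
      # transform, the natural prior for pre-aligned volumes
      par[[paste0(cp, ".out.w")]] <- matrix(0, cfg$output^3, nin)
      par[[paste0(cp, ".out.b")]] <- numeric(cfg$output^3)
    }
    par
  })
}

branch_fw <- function(par, cfg, br, x, dims, pool_type) {
  caches <- list()
  r <- unit_fw(par, paste0(br, ".ic"), x, dims, 5L, pool = FALSE)
  caches$ic <- r$cache
  for (e in seq_len(cfg$n_encoders)) {
    r <- unit_fw(par, paste0(br, ".e", e), r$out, r$dims, 3L,
                 pool = TRUE, pool_type = pool_type)
    caches[[paste0("e", e)]] <- r$cache
  }
  list(out = r$out, dims = r$dims, caches = caches)
}

branch_bw <- function(par, grads, cfg, br, caches, dout) {
  for (e in rev(seq_len(cfg$n_encoders))) {
    r <- unit_bw(par, grads, paste0(br, ".e", e), caches[[paste0("e", e)]],
                 dout, pooled = TRUE)
    dout <- r$dx; grads <- r$grads
  }
  r <- unit_bw(par, grads, paste0(br, ".ic"), caches$ic, dout,
               pooled = FALSE, need_dx = FALSE)
  list(dx = r$dx, grads = r$grads)
}

# Per-patch standardisation (zero mean, unit variance).  Raw microscopy
# patches are all-positive; without centring, the first-layer features are
# dominated by the DC component and the shift signal never reaches the
# head (training stalls at the unconditional mean).  Standardising also
# absorbs residual per-sample brightness differences after histogram
# matching.  Constant (background) patches map to zero.
standardize_patches <- function(x, n, B) {
  m <- matrix(x, n, B)
  mu <- colMeans(m)
  sd_ <- sqrt(colMeans(m^2) - mu^2)
  as.numeric(sweep(sweep(m, 2, mu), 2, sd_ + 1e-6, "/"))
}

# Full forward pass.  xf, xm: numeric vectors of (w, w, w, B) patches.
# Returns prediction (o, o, o, 3, B) plus caches when `training`.
nn_forward <- function(model, xf, xm, B, training = FALSE,
                       want_cache = training) {
  cfg <- model$cfg
  par <- model$par
  w <- cfg$window
  xf <- standardize_patches(xf, w^3, B)
  xm <- standardize_patches(xm, w^3, B)
  pool_type <- if (identical(cfg$pool, "avg")) 1L else 0L
  dims_in <- c(w, w, w, 1L, B)
  bf <- branch_fw(par, cfg, "fix", xf, dims_in, pool_type)
  bm <- branch_fw(par, cfg, "mov", xm, dims_in, pool_type)
  sp <- prod(bf$dims[1:3]); cb <- bf$dims[4]
  cat_dims <- c(bf$dims[1:3], 2L * cb, B)
  af <- array(bf$out, c(sp, cb, B))
  am <- array(bm$out, c(sp, cb, B))
  xcat <- array(0, c(sp, 2L * cb, B))
  xcat[, seq_len(cb), ] <- af
  xcat[, cb + seq_len(cb), ] <- am
  xcat <- as.numeric(xcat)
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    drop_mask <- (runif(length(xcat)) >= cfg$dropout_rate) /
      (1 - cfg$dropout_rate)
    xcat <- xcat * drop_mask
  }
  o <- cfg$output
  out <- array(0, c(o, o, o, 3L, B))
  comp_caches <- list()
  for (ci in seq_along(comp_names)) {
    cp <- comp_names[ci]
    r <- list(out = xcat, dims = cat_dims)
    caches <- list()
    for (d in 1:3) {
      r <- unit_fw(par, paste0(cp, ".d", d), r$out, r$dims, 3L,
                   pool = TRUE, pool_type = pool_type)
      caches[[paste0("d", d)]] <- r$cache
    }
    flat <- matrix(r$out, ncol = B)            # (nin, B)
    y <- par[[paste0(cp, ".out.w")]] %*% flat + par[[paste0(cp, ".out.b")]]
    caches$flat <- flat
    caches$flat_dims <- r$dims
    out[, , , ci, ] <- array(y, c(o, o, o, B))
    comp_caches[[cp]] <- caches
  }
  res <- list(pred = out)
  if (want_cache)
    res$cache <- list(bf = bf, bm = bm, xcat = xcat, cat_dims = cat_dims,
                      drop_mask = drop_mask, comp = comp_caches, B = B)
  res
}

# Backward pass from dpred (o,o,o,3,B); returns flat gradient list.
nn_backward <- function(model, cache, dpred) {
  cfg <- model$cfg
  par <- model$par
  B <- cache$B
  grads <- lapply(par, function(p) p * 0)
  dxcat <- numeric(length(cache$xcat))
  for (ci in seq_along(comp_names)) {
    cp <- comp_names[ci]
    caches <- cache$comp[[cp]]
    dy <- matrix(dpred[, , , ci, ], ncol = B)  # (o^3, B)
    wout <- par[[paste0(cp, ".out.w")]]
    grads[[paste0(cp, ".out.w")]] <- grads[[paste0(cp, ".out.w")]] +
      dy %*% t(caches$flat)
    grads[[paste0(cp, ".out.b")]] <- grads[[paste0(cp, ".out.b")]] +
      rowSums(dy)
    dout <- as.numeric(t(wout) %*% dy)
    for (d in 3:1) {
      r <- unit_bw(par, grads, paste0(cp, ".d", d),
                   caches[[paste0("d", d)]], dout, pooled = TRUE)
      dout <- r$dx; grads <- r$grads
    }
    dxcat <- dxcat + dout
  }
  if (!is.null(cache$drop_mask)) dxcat <- dxcat * cache$drop_mask
  sp <- prod(cache$cat_dims[1:3]); cb <- cache$cat_dims[4] %/% 2L
  dcat_arr <- array(dxcat, c(sp, 2L * cb, B))
  df <- as.numeric(dcat_arr[, seq_len(cb), , drop = FALSE])
  dm <- as.numeric(dcat_arr[, cb + seq_len(cb), , drop = FALSE])
  r <- branch_bw(par, grads, cfg, "fix", cache$bf$caches, df)
  grads <- r$grads
  r <- branch_bw(par, grads, cfg, "mov", cache$bm$caches, dm)
  r$grads
}

# Adam optimiser state + step
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
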