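#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam, learning rate 1e-4, 200
#' epochs per training stage, batch 64, fixed-grid step 32, and a
#' self-feedback stage that re-samples the training volumes at step 48 and
#' adds roughly 2000 extra patch pairs per volume.  The desk-scale preset
#' (see [preset()]) shrinks all of this to CPU budgets.
#'
#' @param epochs training epochs per stage.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param optimizer only `"adam"` is supported.
#' @param step fixed-grid sampling stride for pretraining patches.
#' @param feedback list with `alpha` (allocation exponent in (0, 1]),
#'   `extra_per_volume` (budget A per training volume),
#'   `feedback_step` (unused grid stride kept for provenance of reports),
#'   `retain_old` (keep pretraining samples when fine-tuning), and
#'   `enabled` (run the feedback pass inside [train_level2()]).
#' @param seed integer seed governing shuffling and dropout.
#' @param val_fraction fraction of samples held out per stage for the
#'   validation loss curve.
#' @param augment_factors warp scalings for level-1 sample building.
#' @param min_patch_sd minimum fixed-patch standard deviation for training
#'   windows (passed to [build_training_set()] by the pipeline drivers);
#'   0 keeps everything.
#' @param augment_factors_l2 warp scalings for level-2 (default adds the
#'   half-shifted deformation).
#' @param smooth_radius mean-filter radius applied to predicted fields.
#' @return A list of class `dh_train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 64L,
                         learning_rate = 1e-4, optimizer = "adam",
                         step = 32L,
                         feedback = list(), seed = 1L, val_fraction = 0.1,
                         augment_factors = 1,
                         augment_factors_l2 = c(1, 0.5),
                         min_patch_sd = 0,
                         smooth_radius = 1L) {
  if (!identical(optimizer, "adam")) stopf("only the adam optimizer is supported")
  fb <- utils::modifyList(
    list(alpha = 1 / 32, extra_per_volume = 2000L, feedback_step = 48L,
         retain_old = TRUE, enabled = TRUE),
    feedback)
  if (!(fb$alpha > 0 && fb$alpha <= 1)) stopf("feedback alpha must be in (0, 1]")
  if (epochs < 1L || batch_size < 1L) stopf("counts must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 step = as.integer(step), feedback = fb,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 augment_factors = augment_factors,
                 augment_factors_l2 = augment_factors_l2,
                 min_patch_sd = min_patch_sd,
                 smooth_radius = as.integer(smooth_radius)),
            class = "dh_train_config")
}

# Stack a list of dh_patch samples into contiguous arrays.
stack_samples <- function(samples, w, o) {
  n <- length(samples)
  xf <- array(0, c(w, w, w, n))
  xm <- array(0, c(w, w, w, n))
  tg <- array(0, c(o, o, o, 3, n))
  for (i in seq_len(n)) {
    xf[, , , i] <- samples[[i]]$fixed_patch
    xm[, , , i] <- samples[[i]]$moving_patch
    tg[, , , , i] <- samples[[i]]$target
  }
  list(xf = xf, xm = xm, tg = tg, n = n)
}

slice_batch <- function(st, idx) {
  list(xf = st$xf[, , , idx, drop = FALSE],
       xm = st$xm[, , , idx, drop = FALSE],
       tg = st$tg[, , , , idx, drop = FALSE],
       n = length(idx))
}

eval_loss <- function(model, st, chunk = 64L) {
  tot <- 0
  for (i0 in seq(1L, st$n, by = chunk)) {
    idx <- i0:min(st$n, i0 + chunk - 1L)
    b <- slice_batch(st, idx)
    r <- nn_forward(model, as.numeric(b$xf), as.numeric(b$xm), b$n,
                    training = FALSE)
    tot <- tot + sum(abs(r$pred - b$tg))
  }
  tot / length(st$tg)
}

# Shared minibatch loop (pretraining, continued training and feedback
# fine-tuning all funnel through here so seeded runs are comparable).
train_loop <- function(model, samples, cfg, epochs = cfg$epochs) {
  w <- model$cfg$window; o <- model$cfg$output
  st <- if (is.list(samples) && !is.null(samples$xf)) samples
        else stack_samples(samples, w, o)
  if (st$n < 1L) stopf("training requires a non-empty sample set")
  with_seed(cfg$seed, {
    n_val <- if (cfg$val_fraction > 0 && st$n >= 5L)
      max(1L, round(cfg$val_fraction * st$n)) else 0L
    val_idx <- if (n_val > 0) sample.int(st$n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(st$n), val_idx)
    val_st <- if (n_val > 0) slice_batch(st, val_idx) else NULL
    state <- adam_init(model$par)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    denom_scale <- 1
    for (ep in seq_len(epochs)) {
      perm <- sample(tr_idx)
      ep_loss <- 0; n_seen <- 0
      for (b0 in seq(1L, length(perm), by = cfg$batch_size)) {
        idx <- perm[b0:min(length(perm), b0 + cfg$batch_size - 1L)]
        b <- slice_batch(st, idx)
        r <- nn_forward(model, as.numeric(b$xf), as.numeric(b$xm), b$n,
                        training = TRUE)
        diff <- r$pred - b$tg
        ep_loss <- ep_loss + sum(abs(diff))
        n_seen <- n_seen + length(diff)
        dpred <- sign(diff) / length(diff)
        grads <- nn_backward(model, r$cache, dpred)
        upd <- adam_step(model$par, grads, state, cfg$learning_rate)
        model$par <- upd$par
        state <- upd$state
      }
      vl <- if (!is.null(val_st)) eval_loss(model, val_st) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / n_seen,
                                     val_loss = vl))
    }
    list(model = model, history = hist, val_idx = val_idx)
  })
}

#' Pretrain a model on fixed-grid samples
#'
#' Trains with L1 loss and Adam for `cfg$epochs` epochs, recording
#' per-epoch training and validation losses.  Reproducible under
#' `cfg$seed`.
#'
#' @param samples list of patch pairs from [build_training_set()].
#' @param cfg a [train_config()].
#' @param net a [network_config()] used to initialise the model, or `NULL`
#'   when `model` is given.
#' @param model optionally, an already-built [build_model()] to continue
#'   from.
#' @return List with `model` (trained `dh_model`) and `history`
#'   (per-epoch data frame of train/validation loss).
#' @export
pretrain <- function(samples, cfg, net = NULL, model = NULL) {
  stopifnot(inherits(cfg, "dh_train_config"))
  if (is.null(model)) {
    if (is.null(net)) stopf("provide either `net` or `model`")
    model <- build_model(net)
  }
  train_loop(model, samples, cfg)
}

#' Continue training an existing model on a fixed sample set
#'
#' Plain continuation with no feedback sampling; the baseline against
#' which self-feedback fine-tuning is compared.
#'
#' @inheritParams pretrain
#' @param model a trained `dh_model`.
#' @param epochs number of additional epochs (default `cfg$epochs`).
#' @return As [pretrain()].
#' @export
continue_training <- function(model, samples, cfg, epochs = cfg$epochs) {
  stopifnot(inherits(model, "dh_model"), inherits(cfg, "dh_train_config"))
  train_loop(model, samples, cfg, epochs = epochs)
}

#' Self-feedback fine-tuning
#'
#' Predicts every training volume with the current model, computes the
#' distance map against the ground truth, histograms the rounded errors,
#' allocates `extra_per_volume` new samples per volume across error bins
#' (inverse-frequency weighting with exponent `alpha`), draws the new
#' patch centers from the corresponding map regions, and fine-tunes on the
#' union of old and new samples (old samples retained when
#' `feedback$retain_old`).
#'
#' @param model a pretrained `dh_model`.
#' @param volumes list of lists with `fixed`, `moving`, `gt_field`.
#' @param old_samples the fixed-grid samples used for pretraining.
#' @param cfg a [train_config()] with `feedback` populated.
#' @param epochs fine-tuning epochs (default `cfg$epochs`).
#' @param predict_fn optional override for the per-volume field predictor
#'   (used for stubbing; defaults to [predict_field()] with the model).
#' @return List with `model`, `history`, and `report` (per-volume bin
#'   histograms/allocations and before/after validation loss).
#' @export
self_feedback_finetune <- function(model, volumes, old_samples, cfg,
                                   epochs = cfg$epochs, predict_fn = NULL) {
  stopifnot(inherits(model, "dh_model"), inherits(cfg, "dh_train_config"))
  fb <- cfg$feedback
  w <- model$cfg$window; o <- model$cfg$output
  seeds <- derive_seeds(cfg$seed + 1L, length(volumes))
  new_samples <- list()
  vol_reports <- list()
  for (vi in seq_along(volumes)) {
    v <- volumes[[vi]]
    P <- if (is.null(predict_fn))
      predict_field(model, v$fixed, v$moving,
                    smooth_radius = cfg$smooth_radius)
    else predict_fn(v$fixed, v$moving)
    dmap <- distance_map(v$gt_field, P)
    hist <- distance_histogram(dmap)
    if (!length(hist$n_per_bin) || fb$extra_per_volume == 0L) {
      vol_reports[[vi]] <- list(n_per_bin = hist$n_per_bin,
                                s_per_bin = integer(0), n_new = 0L)
      next
    }
    alloc <- allocate_samples(hist, fb$alpha, fb$extra_per_volume)
    # bins whose every voxel sits too close to a border cannot host a
    # window; they are logged and skipped
    elig <- eligible_bin_counts(dmap, w)
    empty <- alloc$s_per_bin > 0L &
      (seq_along(alloc$s_per_bin) > length(elig) |
         elig[seq_along(alloc$s_per_bin)] == 0L)
    if (any(empty)) {
      message(sprintf("volume %d: skipping empty feedback bin(s) %s", vi,
                      paste(which(empty), collapse = ", ")))
      alloc$s_per_bin[empty] <- 0L
    }
    centers <- draw_feedback_centers(dmap, alloc, margin = w,
                                     seed = seeds[vi])
    vol_reports[[vi]] <- list(n_per_bin = hist$n_per_bin,
                              s_per_bin = alloc$s_per_bin,
                              n_new = nrow(centers))
    for (ci in seq_len(nrow(centers))) {
      p <- extract_patch_pair(v$fixed, v$moving, v$gt_field,
                              centers[ci, 1:3], w, o)
      attr(p, "volume_id") <- vi
      attr(p, "bin") <- centers[ci, 4]
      new_samples[[length(new_samples) + 1L]] <- p
    }
  }
  merged <- if (isTRUE(fb$retain_old)) c(old_samples, new_samples)
            else if (length(new_samples)) new_samples else old_samples
  res <- continue_training(model, merged, cfg, epochs = epochs)
  res$report <- list(volumes = vol_reports,
                     n_old = length(old_samples),
                     n_new = length(new_samples),
                     retain_old = isTRUE(fb$retain_old))
  res
}

# Residual ground truth for the second level: the field r satisfying
# warp(warp(moving, p1), r) ~ fixed given warp(moving, g) ~ fixed, found
# by fixed-point iteration of r(v) = g(v) - p1(v + r(v)).
residual_field <- function(gt, p1, n_iter = 6L) {
  d <- dim(gt$vectors)[1:3]
  r <- displacement_field(gt$vectors - p1$vectors, gt$spacing)
  for (i in seq_len(n_iter)) {
    nxt <- array(0, dim(gt$vectors))
    for (c in 1:3) {
      samp <- cpp_warp(as.numeric(p1$vectors[, , , c]), d,
                       as.numeric(r$vectors), FALSE)
      nxt[, , , c] <- gt$vectors[, , , c] - array(samp, d)
    }
    r <- displacement_field(nxt, gt$spacing)
  }
  r
}

#' Train the second (fine) level
#'
#' Each training volume is warped by the level-1 model's predicted field;
#' the residual deformation from the warped volume to the fixed volume
#' becomes the level-2 ground truth (computed analytically from the known
#' synthetic field by numeric composition).  Samples are augmented with the
#' half-shifted deformation by default, a fresh model is trained, and — if
#' `cfg$feedback$enabled` — fine-tuned with its own self-feedback pass.
#'
#' @param level1 the trained level-1 `dh_model`.
#' @param volumes2 list of lists with `fixed`, `moving`, `gt_field` (total
#'   ground-truth deformation of the *unwarped* moving volume).
#' @param cfg a [train_config()].
#' @param net optional [network_config()] for the level-2 model (defaults
#'   to the level-1 architecture with a shifted seed).
#' @return List with `model` (level-2 `dh_model`), `history`, `volumes2w`
#'   (the warped pairs + residual fields used for training), and
#'   optionally `feedback_report`.
#' @export
train_level2 <- function(level1, volumes2, cfg, net = NULL) {
  stopifnot(inherits(level1, "dh_model"), inherits(cfg, "dh_train_config"))
  if (is.null(net)) {
    net <- level1$cfg
    net$seed <- net$seed + 1000L
  }
  vol2w <- lapply(volumes2, function(v) {
    p1 <- predict_field(level1, v$fixed, v$moving,
                        smooth_radius = cfg$smooth_radius)
    list(fixed = v$fixed,
         moving = warp_volume(v$moving, p1),
         gt_field = residual_field(v$gt_field, p1),
         level1_field = p1)
  })
  samples <- build_training_set(vol2w, w = net$window, o = net$output,
                                step = cfg$step,
                                augment_factors = cfg$augment_factors_l2,
                                min_sd = cfg$min_patch_sd %||% 0)
  res <- pretrain(samples, cfg, net = net)
  if (isTRUE(cfg$feedback$enabled)) {
    fbres <- self_feedback_finetune(res$model, vol2w, samples, cfg)
    fbres$pretrain_history <- res$history
    fbres$volumes2w <- vol2w
    return(fbres)
  }
  res$volumes2w <- vol2w
  res
}
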