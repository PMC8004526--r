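#' Predict a dense displacement field by sliding-window inference
#'
#' A `w^3` window traverses the (replicate-padded) volumes at stride `o`;
#' each predicted central `o^3` block is added into a running sum and the
#' per-voxel superposition count `W` is incremented there.  The final field
#' is the element-wise quotient of the two accumulators, cropped back to
#' the original lattice and mean-filtered.  Padding by `ceiling((w - o)/2)`
#' guarantees every voxel is covered (`W > 0`).
#'
#' @param model a trained `dh_model`, or a stub `function(fixed_patch,
#'   moving_patch)` returning an `(o, o, o, 3)` block (used in tests and
#'   oracles).
#' @param fixed,moving [volume()]s on the same lattice.
#' @param window,output window and output sizes; default from the model
#'   configuration (required for function stubs).
#' @param smooth_radius mean-filter radius for the assembled field
#'   (default 1; use 0 to inspect the raw assembly).
#' @param batch_size windows per forward pass for `dh_model`s.
#' @return A [displacement_field()] on the fixed lattice; attribute
#'   `coverage` records the superposition counts `W` (cropped) and the
#'   traversal geometry.
#' @export
predict_field <- function(model, fixed, moving, window = NULL,
                          output = NULL, smooth_radius = 1L,
                          batch_size = 64L) {
  check_same_lattice(fixed, moving, "fixed and moving")
  is_net <- inherits(model, "dh_model")
  if (is_net) {
    if (!is.null(window) && window != model$cfg$window)
      stopf("window %d does not match model window %d", window,
            model$cfg$window)
    window <- model$cfg$window
    output <- output %||% model$cfg$output
    if (output != model$cfg$output)
      stopf("output %d does not match model output %d", output,
            model$cfg$output)
  } else if (!is.function(model)) {
    stopf("model must be a dh_model or a stub function")
  } else if (is.null(window) || is.null(output)) {
    stopf("window and output are required for stub models")
  }
  w <- as.integer(window); o <- as.integer(output)
  shape <- vol_shape(fixed)
  pad <- as.integer(ceiling((w - o) / 2))
  pshape <- shape + 2L * pad
  # replicate padding via clamped index maps
  pz <- pmin(pmax(seq_len(pshape[1]) - pad, 1L), shape[1])
  py <- pmin(pmax(seq_len(pshape[2]) - pad, 1L), shape[2])
  px <- pmin(pmax(seq_len(pshape[3]) - pad, 1L), shape[3])
  fp <- fixed$data[pz, py, px]
  mp <- moving$data[pz, py, px]
  centers <- grid_centers(pshape, w, o)
  phi <- array(0, c(pshape, 3L))
  Wc <- array(0L, pshape)
  n_centers <- nrow(centers)
  place_block <- function(center, block) {
    te <- target_extent(center, o)
    tz <- te$start[1]:te$end[1]; ty <- te$start[2]:te$end[2]
    tx <- te$start[3]:te$end[3]
    phi[tz, ty, tx, ] <<- phi[tz, ty, tx, , drop = FALSE] + block
    Wc[tz, ty, tx] <<- Wc[tz, ty, tx] + 1L
  }
  get_patch <- function(center, arr) {
    pe <- patch_extent(center, w)
    arr[pe$start[1]:pe$end[1], pe$start[2]:pe$end[2],
        pe$start[3]:pe$end[3], drop = FALSE]
  }
  if (is_net) {
    for (b0 in seq(1L, n_centers, by = batch_size)) {
      idx <- b0:min(n_centers, b0 + batch_size - 1L)
      B <- length(idx)
      xf <- array(0, c(w, w, w, B))
      xm <- array(0, c(w, w, w, B))
      for (j in seq_len(B)) {
        xf[, , , j] <- get_patch(centers[idx[j], ], fp)
        xm[, , , j] <- get_patch(centers[idx[j], ], mp)
      }
      pred <- nn_forward(model, as.numeric(xf), as.numeric(xm), B,
                         training = FALSE)$pred
      for (j in seq_len(B))
        place_block(centers[idx[j], ], pred[, , , , j])
    }
  } else {
    for (ci in seq_len(n_centers)) {
      blk <- model(get_patch(centers[ci, ], fp), get_patch(centers[ci, ], mp))
      place_block(centers[ci, ], blk)
    }
  }
  cz <- pad + seq_len(shape[1]); cy <- pad + seq_len(shape[2])
  cx <- pad + seq_len(shape[3])
  if (any(Wc[cz, cy, cx] == 0L))
    stopf("internal error: uncovered voxels after padding")
  field <- phi / pmax(as.numeric(Wc), 1L)   # padded rim may be uncovered
  out <- displacement_field(field[cz, cy, cx, , drop = FALSE],
                            spacing = fixed$spacing)
  if (smooth_radius > 0) out <- mean_filter_field(out, smooth_radius)
  attr(out, "coverage") <- list(W = Wc[cz, cy, cx], window = w, output = o,
                                pad = pad, n_windows = n_centers)
  out
}

#' Two-level registration
#'
#' Applies the coarse (level-1) model, then predicts and applies the fine
#' (level-2) model on the level-1-warped volume: the final output is the
#' sequentially warped volume.  The analytic composition of the two fields
#' is also returned for single-resampling use.
#'
#' @param models list with elements `level1` and `level2` (trained
#'   `dh_model`s or stub functions with matching `window`/`output`).
#' @param moving,fixed [volume()]s, linearly pre-aligned.
#' @param smooth_radius mean-filter radius passed to [predict_field()].
#' @param window,output sizes for stub models (defaults from `level1`).
#' @return List with `warped` (final volume), `field1`, `field2`, and
#'   `composed` (field equivalent to the sequential application).
#' @export
register_volumes <- function(models, moving, fixed, smooth_radius = 1L,
                             window = NULL, output = NULL) {
  stopifnot(is.list(models), !is.null(models$level1), !is.null(models$level2))
  f1 <- predict_field(models$level1, fixed, moving, window = window,
                      output = output, smooth_radius = smooth_radius)
  warped1 <- warp_volume(moving, f1)
  f2 <- predict_field(models$level2, fixed, warped1, window = window,
                      output = output, smooth_radius = smooth_radius)
  warped2 <- warp_volume(warped1, f2)
  list(warped = warped2, field1 = f1, field2 = f2,
       composed = compose_fields(f1, f2))
}
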