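#' Network configuration for the dual-branch patch regressor
#'
#' The network takes two co-located `window^3` patches (fixed and moving),
#' passes each through an InputConv unit (5x5x5 conv, stride 1, padding 2,
#' PReLU) and `n_encoders` Encoder units (3x3x3 conv + PReLU + pooling
#' 3x3x3/stride 2/pad 1; feature maps double per unit), concatenates the
#' branch features (dropout applied there during training), and regresses
#' three `output^3` displacement blocks (x, y, z) through per-component
#' chains of three Decoder units and a final learned linear map (OutConn).
#'
#' The full-scale configuration is `window = 64, output = 9,
#' base_features = 4, n_encoders = 3`; smaller variants use windows
#' 16/32 and outputs 3/5/9.
#'
#' @param window input patch size `w` (`w / 2^n_encoders >= 1`).
#' @param output central displacement block size `o` (`o < w`).
#' @param base_features feature maps in the first layer (default 4).
#' @param n_encoders number of encoder units per branch (default 3).
#' @param dropout_rate dropout probability after branch concatenation
#'   (default 0.5; training only).
#' @param pool `"max"` (default) or `"avg"`.
#' @param seed integer seed for parameter initialisation.
#' @return A list of class `dh_net_config`.
#' @export
network_config <- function(window = 64L, output = 9L, base_features = 4L,
                           n_encoders = 3L, dropout_rate = 0.5,
                           pool = c("max", "avg"), seed = 1L) {
  pool <- match.arg(pool)
  window <- as.integer(window); output <- as.integer(output)
  if (window %/% 2L^n_encoders < 1L)
    stopf("window %d underflows after %d encoder poolings", window,
          n_encoders)
  if (output >= window) stopf("output size must be smaller than window")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must be in [0, 1)")
  structure(list(window = window, output = output,
                 base_features = as.integer(base_features),
                 n_encoders = as.integer(n_encoders),
                 dropout_rate = dropout_rate, pool = pool,
                 seed = as.integer(seed)),
            class = "dh_net_config")
}

#' Build (initialise) a patch-regression model
#'
#' Parameter initialisation is deterministic in `cfg$seed`: rebuilding with
#' the same configuration yields bit-identical parameters.
#'
#' @param cfg a [network_config()].
#' @return An object of class `dh_model` with fields `cfg` and `par`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "dh_net_config"))
  structure(list(cfg = cfg, par = init_params(cfg)), class = "dh_model")
}

#' @export
print.dh_model <- function(x, ...) {
  n_par <- sum(vapply(x$par, length, 1L))
  cat(sprintf(
    "<dh_model window %d, output %d, base %d, %d encoders, %d parameters>\n",
    x$cfg$window, x$cfg$output, x$cfg$base_features, x$cfg$n_encoders,
    n_par))
  invisible(x)
}

#' Predict displacement blocks for patch pairs
#'
#' Inference-mode forward pass (dropout disabled; deterministic).  Accepts
#' a single `(w, w, w)` patch pair or a batch `(w, w, w, B)`.
#'
#' @param model a [build_model()] result.
#' @param fixed_patch,moving_patch numeric arrays `(w, w, w)` or
#'   `(w, w, w, B)`.
#' @return Displacement block array `(o, o, o, 3)` (components ordered
#'   x, y, z) or `(o, o, o, 3, B)` for batched input.
#' @export
model_forward <- function(model, fixed_patch, moving_patch) {
  stopifnot(inherits(model, "dh_model"))
  w <- model$cfg$window
  df <- dim(fixed_patch)
  batched <- length(df) == 4L
  if (!identical(dim(fixed_patch), dim(moving_patch)))
    stopf("fixed and moving patches must have identical shape")
  if (!all(df[1:3] == w))
    stopf("patch shape %s does not match model window %d",
          paste(df, collapse = "x"), w)
  B <- if (batched) df[4] else 1L
  r <- nn_forward(model, as.numeric(fixed_patch), as.numeric(moving_patch),
                  B, training = FALSE)
  if (batched) r$pred else array(r$pred, dim(r$pred)[1:4])
}

#' Mean absolute error (L1) between displacement blocks
#'
#' The mean of absolute differences over all `3 * o^3` entries (and the
#' batch, if present), i.e. the per-component pixel error used as the
#' training loss and reported on loss curves.
#'
#' @param pred,target arrays of identical shape.
#' @return Scalar loss.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stopf("pred and target shapes differ")
  mean(abs(pred - target))
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full configuration alongside the parameters.
#'
#' @param model a `dh_model`.
#' @param path file path (`.rds`).
#' @return `save_model`: the path, invisibly.  `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dh_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dh_model")) stopf("not a dh_model checkpoint: %s", path)
  m
}
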