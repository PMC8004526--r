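#' Phantom specification
#'
#' Describes the brain-like test object: a nested-ellipsoid "brain" with
#' `n_regions` labelled substructures and band-limited intensity texture
#' (so that patches carry matchable detail, as the cytoarchitecture
#' counterstain does in real data).
#'
#' @param shape lattice dimensions `(Z, Y, X)`, each `>= 48` for the
#'   default window variants.
#' @param n_regions number of labelled substructures (`>= 2`).
#' @param texture_scale correlation length of the intensity texture in
#'   voxels.
#' @param seed integer seed.
#' @return List of class `dh_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), n_regions = 5L,
                         texture_scale = 3, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stopf("invalid phantom shape")
  if (n_regions < 2L) stopf("n_regions must be >= 2")
  structure(list(shape = shape, n_regions = as.integer(n_regions),
                 texture_scale = texture_scale, seed = as.integer(seed)),
            class = "dh_phantom_spec")
}

#' Displacement-field specification
#'
#' Smooth random fields: white noise per component, Gaussian-smoothed with
#' kernel width `smoothness`, rescaled so the maximum vector norm equals
#' `max_magnitude`.  Large-magnitude fields stand in for the coarse
#' (level-1) deformations, small ones for the residual (level-2)
#' deformations.  Generated fields must be fold-free; generation fails if
#' the magnitude/smoothness combination produces non-positive Jacobians.
#'
#' @param max_magnitude maximum displacement norm in voxels (`>= 0`).
#' @param smoothness Gaussian kernel sigma in voxels.
#' @param seed integer seed.
#' @return List of class `dh_field_spec`.
#' @export
field_spec <- function(max_magnitude = 6, smoothness = 12, seed = 1L) {
  if (max_magnitude < 0) stopf("max_magnitude must be >= 0")
  if (smoothness <= 0) stopf("smoothness must be > 0")
  structure(list(max_magnitude = max_magnitude, smoothness = smoothness,
                 seed = as.integer(seed)),
            class = "dh_field_spec")
}

#' Generate a textured brain-like phantom with region labels
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (intensities in `[0, 1]`) and `labels`
#'   (region ids `0..n_regions`; all present).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "dh_phantom_spec"))
  shape <- spec$shape
  with_seed(spec$seed, {
    ctr <- (shape + 1) / 2
    ax <- shape * 0.42
    zi <- seq_len(shape[1]); yi <- seq_len(shape[2]); xi <- seq_len(shape[3])
    zz <- array(rep(zi, times = shape[2] * shape[3]), shape)
    yy <- array(rep(rep(yi, each = shape[1]), times = shape[3]), shape)
    xx <- array(rep(xi, each = shape[1] * shape[2]), shape)
    brain <- ((zz - ctr[1]) / ax[1])^2 + ((yy - ctr[2]) / ax[2])^2 +
             ((xx - ctr[3]) / ax[3])^2 <= 1
    labels <- array(0L, shape)
    vol <- array(0, shape)
    vol[brain] <- 0.35
    # substructure centres on a jittered ring so every region survives
    angles <- seq(0, 2 * pi, length.out = spec$n_regions + 1L)[-1] +
      runif(spec$n_regions, -0.2, 0.2)
    base_int <- seq(0.2, 0.9, length.out = spec$n_regions)
    for (r in seq_len(spec$n_regions)) {
      rc <- ctr + c(0.5 * ax[1] * sin(angles[r]),
                    0.5 * ax[2] * cos(angles[r]),
                    runif(1, -0.3, 0.3) * ax[3])
      ra <- ax * runif(3, 0.12, 0.22)
      inside <- ((zz - rc[1]) / ra[1])^2 + ((yy - rc[2]) / ra[2])^2 +
                ((xx - rc[3]) / ra[3])^2 <= 1
      inside <- inside & brain
      labels[inside] <- r
      vol[inside] <- base_int[r]
    }
    texture <- gaussian_smooth3d(array(rnorm(prod(shape)), shape),
                                 spec$texture_scale)
    texture <- texture / max(abs(texture)) * 0.35
    vol[brain] <- vol[brain] + texture[brain]
    vol <- pmin(pmax(vol, 0), 1)
    list(volume = volume(array(vol, shape)),
         labels = label_volume(labels))
  })
}

#' Generate a smooth, fold-free random displacement field
#'
#' @param shape lattice dimensions `(Z, Y, X)`.
#' @param spec a [field_spec()].
#' @return A [displacement_field()] whose maximum vector norm equals
#'   `spec$max_magnitude` (to rescaling precision) and whose Jacobian
#'   determinant is positive at every interior voxel.
#' @export
make_smooth_field <- function(shape, spec) {
  stopifnot(inherits(spec, "dh_field_spec"))
  shape <- as.integer(shape)
  if (spec$max_magnitude == 0) return(zero_field(shape))
  u <- with_seed(spec$seed, {
    arr <- array(0, c(shape, 3))
    for (c in 1:3)
      arr[, , , c] <- gaussian_smooth3d(array(rnorm(prod(shape)), shape),
                                        spec$smoothness)
    arr
  })
  nrm <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u <- u * (spec$max_magnitude / max(nrm))
  f <- displacement_field(u)
  if (all(dim(f$vectors)[1:3] >= 3L)) {
    jr <- jacobian_report(f)
    if (jr$n_nonpositive > 0)
      stopf(paste("field spec (max_magnitude %.3g, smoothness %.3g)",
                  "violates the fold-free bound: %d voxel(s) with",
                  "non-positive Jacobian"),
            spec$max_magnitude, spec$smoothness, jr$n_nonpositive)
  }
  f
}

# moving = fixed sampled through the inverse deformation, so that
# warp(moving, gt) reproduces fixed up to interpolation error
synth_moving <- function(fixed, gt, gamma = 1, noise_sd = 0,
                         noise_seed = 1L) {
  inv <- invert_field(gt)
  mov <- warp_volume(fixed, inv)
  arr <- mov$data
  if (gamma != 1) arr <- pmin(pmax(arr, 0), 1)^gamma
  if (noise_sd > 0)
    arr <- arr + with_seed(noise_seed,
                           array(rnorm(length(arr), sd = noise_sd), dim(arr)))
  volume(pmin(pmax(arr, 0), 1), fixed$spacing)
}

#' Generate a synthetic registration corpus
#'
#' Emulates the data layout of the full-scale setup: one fixed reference,
#' `n_train1` coarse-deformation training pairs (large fields),
#' `n_train2` fine-level training pairs whose total deformation composes a
#' large and a small field (so the level-1 residual is small), and `n_val`
#' validation pairs mirroring the fine-level statistics.  Each moving
#' volume gets a mild intensity perturbation (gamma jitter + noise),
#' standing in for cross-sample appearance differences that histogram
#' matching normalises in real data.
#'
#' @param n_train1,n_train2,n_val sample counts per group.
#' @param phantom a [phantom_spec()].
#' @param large,small [field_spec()]s for the coarse and residual
#'   deformations (`large$max_magnitude > small$max_magnitude`).
#' @param out_dir output directory for the on-disk corpus (NIfTI volumes,
#'   labels, fields + `manifest.json`), or `NULL` for in-memory only.
#' @param seed top-level seed; all per-sample seeds derive from it.
#' @return Invisibly, a list with `fixed`, `fixed_labels`, and the three
#'   sample groups (`train1`, `train2`, `val`), each sample holding
#'   `fixed`, `moving`, `gt_field`, `labels_fixed`, `labels_moving`.
#' @export
make_dataset <- function(n_train1, n_train2, n_val,
                         phantom = phantom_spec(),
                         large = field_spec(max_magnitude = 6,
                                            smoothness = 12, seed = 1L),
                         small = field_spec(max_magnitude = 2,
                                            smoothness = 12, seed = 2L),
                         out_dir = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "dh_phantom_spec"))
  if (large$max_magnitude <= small$max_magnitude)
    stopf("large fields must exceed small fields in magnitude")
  n_tot <- n_train1 + n_train2 + n_val
  seeds <- derive_seeds(seed, 2L * n_tot + 1L)
  ph <- make_phantom(phantom_spec(phantom$shape, phantom$n_regions,
                                  phantom$texture_scale, seeds[1]))
  shape <- phantom$shape
  make_sample <- function(i, group) {
    fs_large <- field_spec(large$max_magnitude, large$smoothness,
                           seed = seeds[1 + i])
    gt <- if (group == "train1") {
      make_smooth_field(shape, fs_large)
    } else {
      fs_small <- field_spec(small$max_magnitude, small$smoothness,
                             seed = seeds[1 + n_tot + i])
      compose_fields(make_smooth_field(shape, fs_large),
                     make_smooth_field(shape, fs_small))
    }
    pert <- with_seed(seeds[1 + n_tot + i] + 7L,
                      c(gamma = runif(1, 0.9, 1.1)))
    mov <- synth_moving(ph$volume, gt, gamma = pert[["gamma"]],
                        noise_sd = 0.01, noise_seed = seeds[1 + i] + 13L)
    labels_moving <- warp_volume(ph$labels, invert_field(gt))
    list(fixed = ph$volume, moving = mov, gt_field = gt,
         labels_fixed = ph$labels, labels_moving = labels_moving,
         group = group, id = sprintf("%s_%02d", group, i))
  }
  idx <- 0L
  groups <- list(train1 = n_train1, train2 = n_train2, val = n_val)
  corpus <- list(fixed = ph$volume, fixed_labels = ph$labels)
  manifest <- list(seed = seed, shape = shape,
                   large = unclass(large)[1:2], small = unclass(small)[1:2],
                   samples = list())
  for (g in names(groups)) {
    corpus[[g]] <- vector("list", groups[[g]])
    for (i in seq_len(groups[[g]])) {
      idx <- idx + 1L
      s <- make_sample(idx, g)
      corpus[[g]][[i]] <- s
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, s$id)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_volume(s$fixed, file.path(d, "fixed.nii.gz"))
        write_volume(s$moving, file.path(d, "moving.nii.gz"))
        write_field(s$gt_field, file.path(d, "gt_field.nii.gz"))
        write_labels(s$labels_fixed, file.path(d, "labels_fixed.nii.gz"))
        write_labels(s$labels_moving, file.path(d, "labels_moving.nii.gz"))
      }
      manifest$samples[[length(manifest$samples) + 1L]] <-
        list(id = s$id, group = g)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(corpus)
}

#' Load an on-disk corpus written by [make_dataset()]
#' @param dir corpus directory containing `manifest.json`.
#' @return A corpus list as returned by [make_dataset()].
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json in %s", dir)
  mf <- jsonlite::read_json(mf_path)
  corpus <- list(train1 = list(), train2 = list(), val = list())
  for (s in mf$samples) {
    d <- file.path(dir, s$id)
    smp <- list(fixed = read_volume(file.path(d, "fixed.nii.gz")),
                moving = read_volume(file.path(d, "moving.nii.gz")),
                gt_field = read_field(file.path(d, "gt_field.nii.gz")),
                labels_fixed = read_labels(file.path(d, "labels_fixed.nii.gz")),
                labels_moving = read_labels(file.path(d, "labels_moving.nii.gz")),
                group = s$group, id = s$id)
    corpus[[s$group]][[length(corpus[[s$group]]) + 1L]] <- smp
  }
  corpus$fixed <- corpus$train1[[1]]$fixed %||% corpus$val[[1]]$fixed
  corpus
}
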