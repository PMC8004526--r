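#' Window centers for fixed-step patch traversal
#'
#' Window start positions run at multiples of `step` per axis, plus one
#' end-aligned window per axis when `(L - window)` is not a multiple of
#' `step`, so the union of windows covers the whole axis.  Centers are
#' reported as `start + window %/% 2` (1-based voxel coordinates).
#'
#' @param shape integer length-3 lattice dimensions `(Z, Y, X)`.
#' @param window cubic window size `w` (must fit in every dimension).
#' @param step stride `>= 1`.
#' @return Integer matrix with one row per center and columns `(z, y, x)`.
#' @export
grid_centers <- function(shape, window, step) {
  shape <- as.integer(shape); window <- as.integer(window)
  step <- as.integer(step)
  if (any(window > shape))
    stopf("window %d exceeds volume shape %s", window,
          paste(shape, collapse = "x"))
  if (step < 1L) stopf("step must be >= 1")
  axis_starts <- lapply(shape, function(L) {
    s <- seq.int(1L, L - window + 1L, by = step)
    if (s[length(s)] != L - window + 1L) s <- c(s, L - window + 1L)
    s
  })
  g <- as.matrix(expand.grid(z = axis_starts[[1]], y = axis_starts[[2]],
                             x = axis_starts[[3]], KEEP.OUT.ATTRS = FALSE))
  g <- g + window %/% 2L
  storage.mode(g) <- "integer"
  g
}

# counts of rounded distance-map values over the window-eligible interior
eligible_bin_counts <- function(dmap, w) {
  shape <- dim(dmap)
  lo <- rep(1L + w %/% 2L, 3L)
  hi <- shape - w + 1L + w %/% 2L
  if (any(hi < lo)) return(integer(0))
  r <- round_half_up(dmap[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  if (!any(r > 0)) return(integer(0))
  tabulate(r[r >= 1], nbins = max(r))
}

# window/target extents for a center coordinate (shared by extraction and
# dense assembly so the two always agree)
patch_extent <- function(center, w) {
  start <- center - w %/% 2L
  list(start = start, end = start + w - 1L)
}

target_extent <- function(center, o) {
  start <- center - o %/% 2L
  list(start = start, end = start + o - 1L)
}

#' Extract one training patch pair
#'
#' Co-located `w^3` windows from the fixed and moving volumes plus the
#' central `o^3` block of the ground-truth field (channel order x, y, z).
#'
#' @param fixed,moving [volume()]s of identical shape.
#' @param gt_field ground-truth [displacement_field()] on the same lattice.
#' @param center integer `(z, y, x)` center coordinate (1-based).
#' @param w window size; `o` target block size (`o < w`).
#' @param o target block size.
#' @return A list of class `dh_patch` with `fixed_patch`, `moving_patch`,
#'   `target` (array `(o, o, o, 3)`), and `center`.
#' @export
extract_patch_pair <- function(fixed, moving, gt_field, center, w, o) {
  check_same_lattice(fixed, moving, "fixed and moving")
  check_same_lattice(fixed, gt_field, "volumes and field")
  shape <- vol_shape(fixed)
  center <- as.integer(center); w <- as.integer(w); o <- as.integer(o)
  if (o >= w) stopf("output size o must be smaller than window size w")
  pe <- patch_extent(center, w)
  te <- target_extent(center, o)
  if (any(pe$start < 1L) || any(pe$end > shape))
    stopf("patch window [%s..%s] out of bounds for shape %s",
          paste(pe$start, collapse = ","), paste(pe$end, collapse = ","),
          paste(shape, collapse = "x"))
  zi <- pe$start[1]:pe$end[1]; yi <- pe$start[2]:pe$end[2]
  xi <- pe$start[3]:pe$end[3]
  tz <- te$start[1]:te$end[1]; ty <- te$start[2]:te$end[2]
  tx <- te$start[3]:te$end[3]
  structure(list(
    fixed_patch = fixed$data[zi, yi, xi, drop = FALSE],
    moving_patch = moving$data[zi, yi, xi, drop = FALSE],
    target = gt_field$vectors[tz, ty, tx, , drop = FALSE],
    center = center), class = "dh_patch")
}

#' Histogram of rounded distance-map errors
#'
#' Each voxel's endpoint error is rounded half-up to the nearest integer;
#' bins run `1..n` where `n` is the largest rounded error.  Voxels rounding
#' to 0 (already well-predicted) are excluded.
#'
#' @param dmap 3D array of non-negative distances (from [distance_map()]).
#' @return An object of class `dh_allocation` with `n_per_bin` (named
#'   integer vector, names `1..n`); `s_per_bin` is filled in by
#'   [allocate_samples()].
#' @export
distance_histogram <- function(dmap) {
  if (!length(dmap)) stopf("distance map is empty")
  r <- round_half_up(as.numeric(dmap))
  n <- if (any(r > 0)) max(r) else 0
  counts <- if (n >= 1) tabulate(r[r >= 1], nbins = n) else integer(0)
  structure(list(n_per_bin = stats::setNames(as.integer(counts),
                                             seq_len(n)),
                 s_per_bin = NULL, alpha = NULL, total_extra = NULL),
            class = "dh_allocation")
}

#' Allocate extra feedback samples across error bins
#'
#' Distributes a budget of `A` additional training samples over the error
#' bins in inverse proportion to their frequency raised to `alpha`:
#' rare (hard, high-error) bins receive more samples.  Fractional
#' allocations are integerised by largest-remainder rounding so the bin
#' totals sum to `A` exactly.  Smaller `alpha` flattens the allocation
#' toward equal counts per bin.
#'
#' @param n_per_bin integer bin counts (a `dh_allocation` or named vector).
#' @param alpha exponent in `(0, 1]` (typical values 1/2 .. 1/32).
#' @param A total number of extra samples (`>= 0`).
#' @return A `dh_allocation` with `s_per_bin` summing exactly to `A`.
#' @export
allocate_samples <- function(n_per_bin, alpha, A) {
  if (inherits(n_per_bin, "dh_allocation")) n_per_bin <- n_per_bin$n_per_bin
  n_per_bin <- as.integer(n_per_bin)
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must be in (0, 1]")
  if (A < 0) stopf("A must be >= 0")
  nz <- which(n_per_bin > 0L)
  if (!length(nz)) stopf("all bins are empty; nothing to allocate")
  w <- numeric(length(n_per_bin))
  w[nz] <- (1 / n_per_bin[nz])^alpha
  raw <- A * w / sum(w)
  s <- floor(raw)
  rem <- A - sum(s)
  if (rem > 0) {
    # largest remainder; ties broken by lower bin index
    ord <- order(raw - s, decreasing = TRUE)
    s[ord[seq_len(rem)]] <- s[ord[seq_len(rem)]] + 1
  }
  structure(list(n_per_bin = stats::setNames(n_per_bin,
                                             seq_along(n_per_bin)),
                 s_per_bin = stats::setNames(as.integer(s),
                                             seq_along(n_per_bin)),
                 alpha = alpha, total_extra = as.integer(A)),
            class = "dh_allocation")
}

#' Draw feedback sample centers from the distance map
#'
#' For each error bin `i`, draws `S(i)` voxel coordinates uniformly without
#' replacement from the voxels whose rounded error equals `i` and whose
#' `margin`-sized window fits inside the volume.  If a bin holds fewer
#' eligible voxels than requested, sampling falls back to with-replacement
#' (with a warning).  Deterministic for a given seed.
#'
#' @param dmap 3D distance array.
#' @param alloc a `dh_allocation` with `s_per_bin` populated.
#' @param margin window size `w` whose extent must fit around each center.
#' @param seed integer RNG seed.
#' @return Integer matrix of `(z, y, x)` centers with a `bin` column.
#' @export
draw_feedback_centers <- function(dmap, alloc, margin, seed) {
  stopifnot(inherits(alloc, "dh_allocation"), !is.null(alloc$s_per_bin))
  shape <- dim(dmap)
  w <- as.integer(margin)
  r <- array(round_half_up(as.numeric(dmap)), shape)
  lo <- rep(1L + w %/% 2L, 3L)
  hi <- shape - w + 1L + w %/% 2L
  if (any(hi < lo)) stopf("margin %d does not fit in shape %s", w,
                          paste(shape, collapse = "x"))
  req <- alloc$s_per_bin[alloc$s_per_bin > 0L]
  if (!length(req))
    return(matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("z", "y", "x", "bin"))))
  idx_grid <- arrayInd(seq_along(r), shape)
  eligible <- idx_grid[, 1] >= lo[1] & idx_grid[, 1] <= hi[1] &
              idx_grid[, 2] >= lo[2] & idx_grid[, 2] <= hi[2] &
              idx_grid[, 3] >= lo[3] & idx_grid[, 3] <= hi[3]
  out <- with_seed(seed, {
    rows <- list()
    for (bname in names(req)) {
      bin <- as.integer(bname)
      want <- req[[bname]]
      pool <- which(eligible & as.vector(r) == bin)
      if (!length(pool))
        stopf("no eligible voxels for error bin %d", bin)
      take <- if (length(pool) >= want) sample(pool, want)
              else {
                warning(sprintf(
                  "bin %d has %d eligible voxels < %d requested; %s",
                  bin, length(pool), want, "sampling with replacement"))
                sample(pool, want, replace = TRUE)
              }
      rows[[bname]] <- cbind(idx_grid[take, , drop = FALSE], bin)
    }
    do.call(rbind, rows)
  })
  colnames(out) <- c("z", "y", "x", "bin")
  storage.mode(out) <- "integer"
  out
}

#' Build a fixed-step training set with warp-scaling augmentation
#'
#' For every `(fixed, moving, gt_field)` triple and every augmentation
#' factor `k`, the ground truth becomes `k * gt` and the moving image is
#' re-warped by `(1 - k) * gt` so that the pair remains consistent with the
#' scaled field (`k = 1` reproduces the original pair exactly).  Patch
#' pairs are extracted at [grid_centers()].
#'
#' @param volumes list of lists with elements `fixed`, `moving`, `gt_field`.
#' @param w,o window and output-block sizes.
#' @param step traversal stride.
#' @param augment_factors numeric vector of warp scalings (default `1`,
#'   i.e. no augmentation; the coarse level conventionally adds `-1` and
#'   `2`, the fine level `1/2`).
#' @param min_sd optional minimum standard deviation of the fixed patch:
#'   windows with less intensity structure (e.g. empty background in
#'   phantom data, where no correspondence evidence exists) are skipped.
#'   Default 0 keeps every window.
#' @return List of `dh_patch` objects; each carries attributes `volume_id`
#'   and `factor`.
#' @export
build_training_set <- function(volumes, w, o, step, augment_factors = 1,
                               min_sd = 0) {
  out <- list()
  for (vi in seq_along(volumes)) {
    v <- volumes[[vi]]
    centers <- grid_centers(vol_shape(v$fixed), w, step)
    for (k in augment_factors) {
      gt_k <- scale_field(v$gt_field, k)
      mov_k <- if (k == 1) v$moving
               else warp_volume(v$moving, scale_field(v$gt_field, 1 - k))
      for (ci in seq_len(nrow(centers))) {
        p <- extract_patch_pair(v$fixed, mov_k, gt_k, centers[ci, ], w, o)
        if (min_sd > 0 && stats::sd(p$fixed_patch) < min_sd) next
        attr(p, "volume_id") <- vi
        attr(p, "factor") <- k
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out
}
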