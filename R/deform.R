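#' Warp a volume by a displacement field
#'
#' Pull-convention warping: output voxel `v` takes the trilinear sample of
#' `moving` at `v + u(v)`.  Sample coordinates outside the lattice are
#' clamped to the border (border replication).
#'
#' @param moving a [volume()] or [label_volume()].
#' @param field a [displacement_field()] on the same lattice.
#' @param interp `"linear"` (default) or `"nearest"` (use for labels).
#' @return Warped object of the same class as `moving`.
#' @export
warp_volume <- function(moving, field, interp = c("linear", "nearest")) {
  stopifnot(inherits(field, "dh_field"))
  is_lab <- inherits(moving, "dh_labels")
  interp <- if (missing(interp) && is_lab) "nearest" else match.arg(interp)
  arr <- if (is_lab) moving$labels else moving$data
  check_same_lattice(moving, field, "moving volume and field")
  out <- cpp_warp(as.numeric(arr), dim(arr), as.numeric(field$vectors),
                  interp == "nearest")
  out <- array(out, dim(arr))
  if (is_lab) label_volume(out, moving$spacing)
  else volume(out, moving$spacing)
}

#' Scale a displacement field by a scalar
#'
#' Used for warp-based augmentation: factor `-1` reverses the deformation
#' ("-Warp"), `2` doubles it ("2*Warp"), `1/2` halves it ("1/2*Warp").
#'
#' @param field a [displacement_field()].
#' @param k finite scalar.
#' @return The scaled field.
#' @export
scale_field <- function(field, k) {
  stopifnot(inherits(field, "dh_field"), is.finite(k))
  displacement_field(field$vectors * k, field$spacing)
}

#' Compose two displacement fields
#'
#' Returns the field equivalent to warping with `first` and then warping
#' the result with `second`.  Under the pull convention this is
#' `result(v) = second(v) + first(v + second(v))` with trilinear sampling
#' of `first`, so that `warp(warp(M, first), second)` agrees with
#' `warp(M, compose_fields(first, second))` up to interpolation error.
#'
#' @param first,second [displacement_field()]s on the same lattice.
#' @return The composed field.
#' @export
compose_fields <- function(first, second) {
  stopifnot(inherits(first, "dh_field"), inherits(second, "dh_field"))
  check_same_lattice(first, second, "fields")
  d <- dim(first$vectors)[1:3]
  out <- array(0, dim(first$vectors))
  for (c in 1:3) {
    samp <- cpp_warp(as.numeric(first$vectors[, , , c]), d,
                     as.numeric(second$vectors), FALSE)
    out[, , , c] <- second$vectors[, , , c] + array(samp, d)
  }
  displacement_field(out, first$spacing)
}

#' Mean-filter (box smooth) a displacement field
#'
#' Each component is averaged over a `(2*radius+1)^3` box with border
#' replication — the post-processing smoothing applied to assembled fields
#' to suppress patch-seam artefacts.
#'
#' @param field a [displacement_field()].
#' @param radius non-negative integer box radius (default 1, a 3^3 box).
#' @return The smoothed field.
#' @export
mean_filter_field <- function(field, radius = 1L) {
  stopifnot(inherits(field, "dh_field"), radius >= 0)
  if (radius == 0) return(field)
  d <- dim(field$vectors)[1:3]
  out <- array(0, dim(field$vectors))
  for (c in 1:3)
    out[, , , c] <- array(cpp_boxfilter3d(as.numeric(field$vectors[, , , c]),
                                          d, as.integer(radius)), d)
  displacement_field(out, field$spacing)
}

#' Jacobian determinant of the deformation
#'
#' For the mapping `v -> v + u(v)`, computes `det(I + grad u)` per voxel
#' using central differences.  Only interior voxels (where the central
#' difference exists) carry a value; the one-voxel boundary rim is `NA`.
#' A determinant everywhere positive indicates a locally invertible,
#' orientation-preserving (fold-free, diffeomorphic) deformation.
#'
#' @param field a [displacement_field()] with all dimensions >= 3.
#' @return A 3D array of determinants (`NA` on the boundary rim).
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "dh_field"))
  d <- dim(field$vectors)[1:3]
  if (any(d < 3L)) stopf("jacobian requires all dimensions >= 3")
  u <- field$vectors
  # central difference of component c along axis ax, on the interior
  grad <- function(c, ax) {
    z <- 2:(d[1] - 1); y <- 2:(d[2] - 1); x <- 2:(d[3] - 1)
    switch(ax,
      z = (u[z + 1, y, x, c] - u[z - 1, y, x, c]) / 2,
      y = (u[z, y + 1, x, c] - u[z, y - 1, x, c]) / 2,
      x = (u[z, y, x + 1, c] - u[z, y, x - 1, c]) / 2)
  }
  # rows of (I + grad u): component order (x, y, z) against axes (x, y, z)
  uxx <- 1 + grad(1, "x"); uxy <- grad(1, "y"); uxz <- grad(1, "z")
  uyx <- grad(2, "x"); uyy <- 1 + grad(2, "y"); uyz <- grad(2, "z")
  uzx <- grad(3, "x"); uzy <- grad(3, "y"); uzz <- 1 + grad(3, "z")
  det_int <- uxx * (uyy * uzz - uyz * uzy) -
             uxy * (uyx * uzz - uyz * uzx) +
             uxz * (uyx * uzy - uyy * uzx)
  out <- array(NA_real_, d)
  out[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- det_int
  out
}

#' Per-voxel endpoint error between two displacement fields
#'
#' The Euclidean norm of the component-wise difference between a true and a
#' predicted field, i.e. the distance map that drives self-feedback
#' sampling.
#'
#' @param G,P [displacement_field()]s on the same lattice.
#' @return A 3D array of non-negative distances (voxel units).
#' @export
distance_map <- function(G, P) {
  stopifnot(inherits(G, "dh_field"), inherits(P, "dh_field"))
  check_same_lattice(G, P, "fields")
  diff <- G$vectors - P$vectors
  sqrt(diff[, , , 1]^2 + diff[, , , 2]^2 + diff[, , , 3]^2)
}

# Numeric inversion of a displacement field by fixed-point iteration:
# find h with h(v) = -u(v + h(v)).  Converges for the smooth, fold-free
# fields this package generates and predicts.
invert_field <- function(field, n_iter = 10L) {
  d <- dim(field$vectors)[1:3]
  h <- displacement_field(-field$vectors, field$spacing)
  for (i in seq_len(n_iter)) {
    nxt <- array(0, dim(field$vectors))
    for (c in 1:3)
      nxt[, , , c] <- -array(cpp_warp(as.numeric(field$vectors[, , , c]), d,
                                      as.numeric(h$vectors), FALSE), d)
    h <- displacement_field(nxt, field$spacing)
  }
  h
}
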