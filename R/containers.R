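#' Intensity volume
#'
#' A 3D scalar grid together with its voxel spacing.  Arrays are indexed
#' `[z, y, x]` with 1-based integer voxel coordinates; this convention is
#' used throughout the package.
#'
#' @param data 3D numeric array, indexed `[z, y, x]`.
#' @param spacing numeric length-3 voxel size in micrometres, per axis
#'   `(z, y, x)`.  Defaults to the 25 um working resolution.
#' @return An object of class `dh_volume` with fields `data` and `spacing`.
#' @export
volume <- function(data, spacing = c(25, 25, 25)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stopf("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers")
  structure(list(data = data, spacing = spacing), class = "dh_volume")
}

#' Region-label volume
#'
#' @param labels 3D array of non-negative integer region IDs (0 = background).
#' @param spacing voxel size in micrometres, as for [volume()].
#' @return An object of class `dh_labels`.
#' @export
label_volume <- function(labels, spacing = c(25, 25, 25)) {
  if (length(dim(labels)) != 3L) stopf("label data must be a 3D array")
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stopf("labels must be finite non-negative integers")
  v <- volume(labels, spacing)
  structure(list(labels = v$data, spacing = v$spacing), class = "dh_labels")
}

#' Dense displacement field
#'
#' Per-voxel displacement vectors, in voxel units, over the fixed-image
#' lattice.  The field maps fixed-lattice voxel `v` to sampling location
#' `v + u(v)` in the moving image ("pull" convention).
#'
#' @param vectors 4D numeric array of shape `(Z, Y, X, 3)`.  Component 1 is
#'   the x-displacement (third array index), component 2 the y-displacement,
#'   component 3 the z-displacement.
#' @param spacing voxel size in micrometres, as for [volume()].
#' @return An object of class `dh_field` with fields `vectors` and `spacing`.
#' @export
displacement_field <- function(vectors, spacing = c(25, 25, 25)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stopf("field must be a 4D array with last dimension 3")
  if (any(!is.finite(vectors))) stopf("field components must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  structure(list(vectors = vectors, spacing = spacing), class = "dh_field")
}

#' Zero displacement field on a given lattice
#' @param shape integer length-3 lattice dimensions `(Z, Y, X)`.
#' @param spacing voxel size in micrometres.
#' @return A `dh_field` with all components zero.
#' @export
zero_field <- function(shape, spacing = c(25, 25, 25)) {
  displacement_field(array(0, c(shape, 3)), spacing)
}

vol_shape <- function(x) {
  if (inherits(x, "dh_volume")) dim(x$data)
  else if (inherits(x, "dh_labels")) dim(x$labels)
  else if (inherits(x, "dh_field")) dim(x$vectors)[1:3]
  else dim(x)
}

check_same_lattice <- function(a, b, what = "objects") {
  if (!identical(as.integer(vol_shape(a)), as.integer(vol_shape(b))))
    stopf("%s must share the same lattice shape (%s vs %s)", what,
          paste(vol_shape(a), collapse = "x"),
          paste(vol_shape(b), collapse = "x"))
  invisible(TRUE)
}

#' @export
print.dh_volume <- function(x, ...) {
  cat(sprintf("<dh_volume %s, spacing %s um, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "/"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.dh_field <- function(x, ...) {
  n <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<dh_field %s, spacing %s um, max |u| = %.4g vox>\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              paste(x$spacing, collapse = "/"), max(n)))
  invisible(x)
}

#' @export
print.dh_labels <- function(x, ...) {
  cat(sprintf("<dh_labels %s, %d region(s)>\n",
              paste(dim(x$labels), collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0))))
  invisible(x)
}
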