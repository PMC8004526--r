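#' Read a 3D intensity volume
#'
#' Reads a NIfTI-1 file (`.nii`/`.nii.gz`) or an uncompressed multi-page
#' grayscale TIFF stack.  Volumes lacking usable spacing metadata default
#' to 25 um isotropic (the package's working resolution).
#'
#' @param path file path.
#' @param format `"nifti"`, `"tiff_stack"`, or `"auto"` (by extension).
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff_stack")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tif{1,2}$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  if (format == "tiff_stack") {
    arr <- read_tiff_stack_raw(path)
    return(volume(arr))
  }
  nii <- read_nifti_raw(path)
  if (length(dim(nii$data)) != 3L)
    stopf("expected a 3D volume, got a %dD payload in %s",
          length(dim(nii$data)), path)
  # disk order (x, y, z) -> in-memory (z, y, x); spacing likewise reversed
  volume(aperm(nii$data, c(3, 2, 1)), spacing = rev(nii$spacing_xyz))
}

#' Write a 3D intensity volume as NIfTI
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "dh_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  write_nifti_raw(aperm(vol$data, c(3, 2, 1)), path,
                  spacing_xyz = rev(vol$spacing), datatype = 64L)
  invisible(path)
}

#' Read a region-label volume (int NIfTI)
#' @param path file path.
#' @return A [label_volume()].
#' @export
read_labels <- function(path) {
  nii <- read_nifti_raw(path)
  if (length(dim(nii$data)) != 3L) stopf("expected a 3D label volume")
  label_volume(aperm(nii$data, c(3, 2, 1)), spacing = rev(nii$spacing_xyz))
}

#' Write a region-label volume as NIfTI (int32)
#' @param lab a [label_volume()].
#' @param path output path.
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "dh_labels"))
  write_nifti_raw(aperm(lab$labels, c(3, 2, 1)), path,
                  spacing_xyz = rev(lab$spacing), datatype = 8L)
  invisible(path)
}

#' Read a displacement field (4D NIfTI)
#'
#' Field files are 4D with the vector dimension last and components ordered
#' `(x, y, z)` in voxel units.
#' @param path file path.
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  nii <- read_nifti_raw(path)
  d <- dim(nii$data)
  if (length(d) != 4L || d[4] != 3L)
    stopf("expected a 4D field with 3 components, got shape %s",
          paste(d, collapse = "x"))
  displacement_field(aperm(nii$data, c(3, 2, 1, 4)),
                     spacing = rev(nii$spacing_xyz))
}

#' Write a displacement field (4D NIfTI, float64)
#' @param field a [displacement_field()].
#' @param path output path.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "dh_field"))
  write_nifti_raw(aperm(field$vectors, c(3, 2, 1, 4)), path,
                  spacing_xyz = rev(field$spacing), datatype = 64L)
  invisible(path)
}

#' Histogram-match a moving volume to a fixed volume
#'
#' Monotone intensity remap via an `n_bins`-bin empirical CDF lookup so the
#' moving volume's intensity distribution matches the fixed volume's,
#' followed by a linear rescale of the output to `[0, 1]`.  This is the
#' standard appearance normalisation applied to every dataset against the
#' one reference (fixed) image before training or prediction.
#'
#' @param moving,fixed [volume()] objects; both must be non-constant.
#' @param n_bins number of histogram bins (default 256).
#' @return The remapped moving volume, intensities in `[0, 1]`.
#' @export
histogram_match <- function(moving, fixed, n_bins = 256L) {
  stopifnot(inherits(moving, "dh_volume"), inherits(fixed, "dh_volume"))
  mv <- as.numeric(moving$data); fv <- as.numeric(fixed$data)
  if (diff(range(mv)) == 0 || diff(range(fv)) == 0)
    stopf("histogram matching requires non-constant volumes")
  edges_m <- seq(min(mv), max(mv), length.out = n_bins + 1L)
  edges_f <- seq(min(fv), max(fv), length.out = n_bins + 1L)
  cdf_m <- cumsum(tabulate(findInterval(mv, edges_m, all.inside = TRUE),
                           n_bins)) / length(mv)
  cdf_f <- cumsum(tabulate(findInterval(fv, edges_f, all.inside = TRUE),
                           n_bins)) / length(fv)
  # map each moving bin to the first fixed bin whose CDF reaches it
  target_bin <- findInterval(cdf_m, cdf_f, left.open = TRUE) + 1L
  target_bin <- pmin(target_bin, n_bins)
  centers_f <- (edges_f[-1] + edges_f[-(n_bins + 1L)]) / 2
  mapped <- centers_f[target_bin][findInterval(mv, edges_m, all.inside = TRUE)]
  rng <- range(mapped)
  out <- if (diff(rng) > 0) (mapped - rng[1]) / diff(rng)
         else rep(0, length(mapped))
  volume(array(out, dim(moving$data)), spacing = moving$spacing)
}

#' Isotropically downsample a volume
#'
#' Trilinear resampling onto an isotropic lattice at `target_spacing`; the
#' output shape is `round(shape * spacing / target_spacing)` per axis.
#' Upsampling is refused.
#'
#' @param vol a [volume()].
#' @param target_spacing target voxel size in micrometres (scalar,
#'   `>= max(vol$spacing)`).
#' @return The resampled [volume()] with isotropic spacing.
#' @export
downsample_isotropic <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "dh_volume"))
  if (target_spacing < max(vol$spacing))
    stopf("target_spacing %.3g um would upsample (current %s um)",
          target_spacing, paste(vol$spacing, collapse = "/"))
  shape <- dim(vol$data)
  out_shape <- pmax(1L, as.integer(round(shape * vol$spacing / target_spacing)))
  if (all(out_shape == shape) && all(vol$spacing == target_spacing))
    return(vol)
  scale <- target_spacing / vol$spacing
  # pixel-center alignment: out voxel centre i maps to (i + 0.5)*s - 0.5
  offset <- 0.5 * scale - 0.5
  arr <- cpp_resample(as.numeric(vol$data), shape, out_shape, scale, offset)
  volume(array(arr, out_shape), spacing = rep(target_spacing, 3))
}
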