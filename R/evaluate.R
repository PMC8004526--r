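#' Dice overlap per region
#'
#' For each region id `r`, `2 |A_r intersect B_r| / (|A_r| + |B_r|)`.
#' Regions absent from both volumes are reported as `NA` and excluded from
#' the summary.
#'
#' @param a,b [label_volume()]s of identical shape.
#' @param region_ids integer region ids to score; default: all non-zero
#'   labels present in either volume.
#' @return List of class `dh_dice` with `per_region` (named numeric),
#'   `mean`, and `sd`.
#' @export
dice_score <- function(a, b, region_ids = NULL) {
  stopifnot(inherits(a, "dh_labels"), inherits(b, "dh_labels"))
  check_same_lattice(a, b, "label volumes")
  la <- as.vector(a$labels); lb <- as.vector(b$labels)
  if (is.null(region_ids))
    region_ids <- sort(setdiff(unique(c(la, lb)), 0))
  scores <- vapply(region_ids, function(r) {
    na <- sum(la == r); nb <- sum(lb == r)
    if (na + nb == 0L) return(NA_real_)
    2 * sum(la == r & lb == r) / (na + nb)
  }, numeric(1))
  names(scores) <- region_ids
  ok <- !is.na(scores)
  structure(list(per_region = scores,
                 mean = if (any(ok)) mean(scores[ok]) else NA_real_,
                 sd = if (sum(ok) > 1) sd(scores[ok]) else NA_real_),
            class = "dh_dice")
}

#' @export
print.dh_dice <- function(x, ...) {
  cat(sprintf("<dh_dice %d region(s), mean %.3f +/- %.3f>\n",
              length(x$per_region), x$mean, x$sd %||% NA))
  invisible(x)
}

#' Endpoint-error summary between two fields
#'
#' Mean/median/max of the per-voxel Euclidean distance between the true
#' and predicted displacement vectors, optionally restricted to a mask.
#'
#' @param G,P [displacement_field()]s on the same lattice.
#' @param mask optional logical/0-1 array selecting voxels.
#' @return List with `mean`, `median`, `max`, `n`.
#' @export
endpoint_error_stats <- function(G, P, mask = NULL) {
  d <- distance_map(G, P)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(d))) stopf("mask shape mismatch")
    d <- d[as.logical(mask)]
    if (!length(d)) stopf("mask selects no voxels")
  }
  list(mean = mean(d), median = median(d), max = max(d), n = length(d))
}

#' Sample (true, predicted) displacement pairs for correlation plots
#'
#' Draws a seeded uniform sample of (voxel, component) entries without
#' replacement and returns the paired true/predicted scalar displacements
#' — the raw material of the correlation dot plots (the full-scale
#' evaluation samples 150 points from each of five datasets, 750 total).
#'
#' @param G,P [displacement_field()]s on the same lattice.
#' @param n_points number of pairs (at most `3 * n_voxels`).
#' @param seed integer RNG seed.
#' @return Data frame with columns `true` and `predicted`.
#' @export
correlation_points <- function(G, P, n_points, seed = 1L) {
  stopifnot(inherits(G, "dh_field"), inherits(P, "dh_field"))
  check_same_lattice(G, P, "fields")
  n_entries <- length(G$vectors)
  if (n_points > n_entries)
    stopf("cannot sample %d points from %d entries without replacement",
          n_points, n_entries)
  idx <- with_seed(seed, sample.int(n_entries, n_points))
  data.frame(true = as.numeric(G$vectors[idx]),
             predicted = as.numeric(P$vectors[idx]))
}

#' Jacobian-determinant folding report
#'
#' Counts interior voxels with non-positive Jacobian determinant (folding;
#' anatomically impossible) and summarises the determinant distribution.
#' A diffeomorphic field reports zero non-positive voxels.
#'
#' @param field a [displacement_field()] with all dimensions >= 3.
#' @return List with `n_interior`, `n_nonpositive`, `fraction_nonpositive`,
#'   `min_det`, `mean_det`.
#' @export
jacobian_report <- function(field) {
  det <- jacobian_determinant(field)
  v <- det[!is.na(det)]
  list(n_interior = length(v),
       n_nonpositive = sum(v <= 0),
       fraction_nonpositive = mean(v <= 0),
       min_det = min(v),
       mean_det = mean(v))
}
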