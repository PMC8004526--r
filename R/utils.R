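#' @useDynLib dhreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd median
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Gaussian smoothing of a 3D array by circular (FFT) convolution.
# Periodic boundaries keep the smoothed-noise variance stationary across
# the lattice (replicate-padded convolution inflates border variance,
# which would let border voxels dominate max-based rescaling).
gaussian_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  axis_k <- lapply(d, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    fft(k / sum(k))
  })
  K <- outer(outer(axis_k[[1]], axis_k[[2]]), axis_k[[3]])
  Re(fft(fft(arr) * array(K, d), inverse = TRUE)) / prod(d)
}
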