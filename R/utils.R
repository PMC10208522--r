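#' Gaussian smoothing of a regularly sampled series
#'
#' Convolves a numeric series with a normalized Gaussian kernel truncated at
#' `truncate` standard deviations, using reflective boundary handling so that
#' no mass is lost at the edges (the sum of a non-negative series is conserved
#' up to floating point).
#'
#' @param x Numeric vector, sampled on a regular grid.
#' @param sd Kernel standard deviation, in grid steps. `sd = 0` returns `x`
#'   unchanged.
#' @param truncate Kernel half-width in standard deviations (default 4).
#' @return Numeric vector of the same length as `x`.
#' @export
gaussian_smooth <- function(x, sd, truncate = 4) {
  n <- length(x)
  if (sd <= 0) return(x)
  radius <- max(1L, as.integer(ceiling(truncate * sd)))
  kern <- stats::dnorm(seq(-radius, radius), sd = sd)
  kern <- kern / sum(kern)
  if (n < 2L) stop("series too short to smooth (need at least 2 points)")
  # reflective padding; reflection index pattern repeats if radius > n - 1
  pad_idx <- function(i) {
    # map arbitrary integer index onto 1..n by reflection about the ends
    m <- 2L * (n - 1L)
    j <- ((i - 1L) %% m + m) %% m
    ifelse(j < n, j + 1L, m - j + 1L)
  }
  xp <- x[pad_idx(seq.int(1L - radius, n + radius))]
  # FFT-based 'open' convolution (length np + nk - 1); fast for the wide
  # kernels used on millisecond-resolution series
  full <- stats::convolve(xp, rev(kern), type = "open")
  full[(2L * radius + 1L):(2L * radius + n)]
}

#' Affine rescaling of a series to a fixed range
#'
#' Maps a series linearly so that its minimum and maximum become `lo` and
#' `hi`; the pre-scaling midpoint (max+min)/2 maps to the range center.
#' A zero-variance series maps to the constant center value.
#'
#' @param x Numeric vector.
#' @param lo,hi Target minimum and maximum.
#' @return Rescaled numeric vector.
#' @export
rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[1]))) {
    return(rep((lo + hi) / 2, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

# Deterministic derivation of sub-seeds from a master seed. Plain
# multiplicative mixing over the Mersenne-31 modulus; all arithmetic stays
# exact in doubles (< 2^53).
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- (as.double(master) %% m)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) * 2654435 + 11) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# weighted total-least-squares (orthogonal distance) line fit; returns
# slope/intercept of the principal axis plus the summed squared orthogonal
# residuals. Used by the phase-precession fitter and exported via odr_slope().
tls_line <- function(x, y, w = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  dx <- x - mx
  dy <- y - my
  sxx <- sum(w * dx * dx)
  syy <- sum(w * dy * dy)
  sxy <- sum(w * dx * dy)
  # principal eigenvector of the 2x2 weighted scatter matrix
  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  disc <- sqrt(max(0, tr * tr / 4 - det))
  lam1 <- tr / 2 + disc # largest eigenvalue
  lam2 <- tr / 2 - disc # orthogonal SSE along the fitted line
  if (abs(sxy) > .Machine$double.eps * max(1, tr)) {
    v <- c(lam1 - syy, sxy)
  } else if (sxx >= syy) {
    v <- c(1, 0)
  } else {
    v <- c(0, 1)
  }
  slope <- if (abs(v[1]) < 1e-300) Inf else v[2] / v[1]
  list(slope = slope,
       intercept = if (is.finite(slope)) my - slope * mx else NA_real_,
       center = c(mx, my),
       ossr = lam2)
}

#' Orthogonal distance regression line fit
#'
#' Fits a straight line to a 2-D point cloud by minimizing the (optionally
#' weighted) sum of squared perpendicular distances from the points to the
#' line — total least squares, i.e. the principal axis of the weighted
#' scatter. Unlike ordinary least squares it recovers near-vertical clouds
#' with a finite, steep slope instead of flattening them, which is what makes
#' it suitable for steep phase-precession clouds.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param weights Optional non-negative weights, one per point.
#' @return A list with elements `slope`, `intercept` (NA for a vertical fit),
#'   and `ossr`, the weighted sum of squared orthogonal residuals.
#' @export
odr_slope <- function(x, y, weights = NULL) {
  if (length(x) < 2) stop("need at least 2 points")
  tls_line(x, y, weights)[c("slope", "intercept", "ossr")]
}
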