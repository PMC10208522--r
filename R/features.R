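#' Generate the frozen weakly-spatially-tuned input features
#'
#' Builds `n_features` fixed spatial signals over the 1 cm bins of the track:
#' independent standard Gaussian noise per bin, smoothed with a Gaussian
#' kernel whose standard deviation is drawn uniformly from `std_range` (cm)
#' for each feature, then affinely mapped so each feature ranges between -1
#' and 1 with the range midpoint at 0. The features are frozen: the same
#' seed yields bit-identical banks, and they never change during a run. They
#' stand in for a mixture of weakly spatially modulated entorhinal inputs
#' (border, grid and object cells).
#'
#' @param track A [track_spec()].
#' @param n_features Number of features (128 by default).
#' @param std_range Range (cm) the per-feature smoothing standard deviation
#'   is drawn from, uniformly.
#' @param seed Integer seed.
#' @return An object of class `feature_bank`: a list with `values`
#'   (`n_features` x `n_bins` matrix in \[-1, 1\]), `smoothing_stds`,
#'   `bin_size`, `track_length` and `seed`.
#' @export
generate_features <- function(track, n_features = 128, std_range = c(2, 20),
                              seed = 1) {
  if (n_features < 1) stop("n_features must be at least 1")
  stopifnot(std_range[1] > 0, std_range[2] < track$length,
            std_range[1] <= std_range[2])
  n_bins <- as.integer(round(track$length / track$bin_size_features))
  set.seed(seed)
  stds <- stats::runif(n_features, std_range[1], std_range[2])
  values <- matrix(0, n_features, n_bins)
  for (i in seq_len(n_features)) {
    raw <- stats::rnorm(n_bins)
    sm <- gaussian_smooth(raw, stds[i] / track$bin_size_features)
    values[i, ] <- rescale_range(sm, -1, 1)
  }
  structure(list(values = values, smoothing_stds = stds,
                 bin_size = track$bin_size_features,
                 track_length = track$length, seed = seed),
            class = "feature_bank")
}

#' Look up the feature vector at a position
#'
#' Nearest-bin lookup (no interpolation) with half-open bins
#' `[k*bin, (k+1)*bin)`.
#'
#' @param bank A [generate_features()] bank.
#' @param x Position in cm, in `[0, track_length)`.
#' @return Numeric vector of length `n_features`.
#' @export
features_at <- function(bank, x) {
  if (x < 0 || x >= bank$track_length) stop("position outside the track")
  col <- floor(x / bank$bin_size) + 1L
  bank$values[, col]
}

#' Export a feature bank as CSV (features x bins)
#'
#' @param bank A [generate_features()] bank.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features <- function(bank, path) {
  df <- as.data.frame(bank$values)
  names(df) <- sprintf("bin_%d", seq_len(ncol(df)) - 1L)
  utils::write.csv(cbind(feature = seq_len(nrow(df)) - 1L,
                         smoothing_std = bank$smoothing_stds, df),
                   path, row.names = FALSE)
  invisible(path)
}
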