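#' Time-delay embedding
#'
#' Maps a scalar series to m-dimensional state vectors with delay tau:
#' row i is `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`. With `m = 1` the states
#' are the samples themselves and a 1000-point series yields a
#' 1000-by-1000 recurrence matrix downstream.
#'
#' @param series numeric vector of length N.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return matrix with `N - (m - 1) * tau` rows and `m` columns.
#' @export
embed_series <- function(series, m = 1, tau = 1) {
  series <- as.numeric(series)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1 || tau < 1) stop("m and tau must be >= 1")
  n_states <- length(series) - (m - 1L) * tau
  if (n_states < 1)
    stop("series too short: need at least (m-1)*tau + 1 = ",
         (m - 1L) * tau + 1L, " samples, got ", length(series))
  idx <- outer(seq_len(n_states), (seq_len(m) - 1L) * tau, `+`)
  matrix(series[idx], n_states, m)
}

#' Pairwise state-distance matrix
#'
#' @param states state matrix from [embed_series()], one state per row.
#' @param norm `"euclidean"` (default), `"manhattan"` or `"chebyshev"`.
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
distance_matrix <- function(states, norm = c("euclidean", "manhattan", "chebyshev")) {
  norm <- match.arg(norm)
  states <- as.matrix(states)
  method <- c(euclidean = "euclidean", manhattan = "manhattan",
              chebyshev = "maximum")[[norm]]
  as.matrix(stats::dist(states, method = method))
}

#' Thresholded recurrence plot
#'
#' Heaviside-thresholded distances: `R_ij = 1` when `epsilon - r_ij >= 0`,
#' else 0. With a negative epsilon even the diagonal is 0.
#'
#' @param r distance matrix.
#' @param epsilon recurrence threshold (finite).
#' @return binary matrix of the same dimension.
#' @export
recurrence_plot <- function(r, epsilon) {
  if (!is.finite(epsilon)) stop("epsilon must be finite")
  (epsilon - r >= 0) * 1
}

#' Unthresholded recurrence plot
#'
#' Retains the continuous value `ER_ij = |epsilon - r_ij|` instead of
#' thresholding, so no dynamical structure is discarded. With the default
#' `epsilon = 0` this is exactly the distance matrix.
#'
#' @param r distance matrix.
#' @param epsilon offset; either an absolute value (default 0) or set via
#'   `quantile_of_r` as a quantile of the off-diagonal distances.
#' @param quantile_of_r optional quantile in \[0, 1\] overriding `epsilon`.
#' @return non-negative matrix of the same dimension.
#' @export
no_threshold_rp <- function(r, epsilon = 0, quantile_of_r = NULL) {
  if (!is.null(quantile_of_r)) {
    epsilon <- stats::quantile(r[row(r) != col(r)], quantile_of_r, names = FALSE)
  }
  if (!is.finite(epsilon)) stop("epsilon must be finite")
  abs(epsilon - r)
}

#' Downsample and scale a recurrence matrix to an image
#'
#' Block-mean downsampling to `side_out` x `side_out` (bins of near-equal
#' size when the input side is not a multiple), then scaling to \[0, 1\]:
#' `minmax` rescales each image by its own range (a constant matrix maps to
#' all zeros); `global` divides by `global_max` and clips, preserving
#' absolute amplitude across images.
#'
#' @param er recurrence or distance matrix.
#' @param side_out output side (>= 8, and at most the input side).
#' @param scaling `"minmax"` (default) or `"global"`.
#' @param global_max divisor for `scaling = "global"`.
#' @return `side_out` x `side_out` matrix with values in \[0, 1\].
#' @export
rp_to_image <- function(er, side_out = 64, scaling = c("minmax", "global"),
                        global_max = NULL) {
  scaling <- match.arg(scaling)
  er <- as.matrix(er)
  side_in <- nrow(er)
  if (side_out < 8) stop("side_out must be >= 8")
  if (side_out > side_in)
    stop("side_out = ", side_out, " exceeds the input side ", side_in,
         "; upsampling is not supported")
  if (side_in > side_out) {
    bins <- floor(seq.int(0L, side_in, length.out = side_out + 1L))
    g <- rep(seq_len(side_out), times = diff(bins))
    # row-bin then column-bin means
    er <- rowsum(er, g) / as.vector(table(g))
    er <- t(rowsum(t(er), g) / as.vector(table(g)))
  }
  if (scaling == "minmax") {
    rng <- range(er)
    if (diff(rng) < .Machine$double.eps) return(er * 0)
    (er - rng[1]) / diff(rng)
  } else {
    if (is.null(global_max) || global_max <= 0)
      stop("scaling = 'global' requires a positive global_max")
    pmax(pmin(er / global_max, 1), 0)
  }
}

#' One-call recurrence image from a recording channel
#'
#' Embeds one channel, computes distances, applies the unthresholded
#' transform and renders the image. Defaults are the paper-faithful
#' settings: `m = 1`, `tau = 1`, `epsilon = 0`, so a 1000-sample channel
#' passes through a 1000 x 1000 distance matrix.
#'
#' @param recording an [eeg_recording()].
#' @param channel label or index.
#' @param m,tau embedding parameters.
#' @param epsilon offset of the unthresholded transform.
#' @param side_out image side.
#' @param norm distance norm.
#' @param scaling,global_max see [rp_to_image()].
#' @return image matrix in \[0, 1\].
#' @export
recurrence_image <- function(recording, channel = 1, m = 1, tau = 1,
                             epsilon = 0, side_out = 64,
                             norm = "euclidean", scaling = "minmax",
                             global_max = NULL) {
  x <- recording$data[channel_index(recording, channel), ]
  er <- no_threshold_rp(distance_matrix(embed_series(x, m, tau), norm), epsilon)
  rp_to_image(er, side_out, scaling, global_max)
}
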