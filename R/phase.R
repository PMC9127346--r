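#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the pass band is isolated without phase
#' distortion.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band `(low, high)` in Hz, inside (0, fs/2).
#' @param order filter order (default 4).
#' @return filtered vector, same length as `x`.
#' @export
bandpass_filtfilt <- function(x, fs, band, order = 4) {
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band (", band[1], ", ", band[2], ") Hz must lie inside (0, fs/2) = (0, ",
         fs / 2, ") Hz")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Analytic signal by the FFT construction: zero the negative frequencies,
# double the positive ones, keep DC and (for even n) Nyquist unscaled.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of one EEG channel
#'
#' Band-pass filters the channel (zero-phase Butterworth) and takes the
#' angle of the analytic signal, wrapped to (-pi, pi]. This is the standard
#' construction feeding the phase-locking value.
#'
#' @param recording an [eeg_recording()].
#' @param channel channel label or index.
#' @param band `(low, high)` Hz; default 8-30.
#' @param trim_edges if `TRUE`, drop the first and last 5\% of samples to
#'   limit filter transients (default `FALSE`).
#' @return a `phase_series` object: list with `phase` (radians), `fs`,
#'   `source_channel`.
#' @export
instantaneous_phase <- function(recording, channel, band = c(8, 30),
                                trim_edges = FALSE) {
  idx <- channel_index(recording, channel)
  x <- recording$data[idx, ]
  if (length(x) < 8 * 4)
    stop("series too short for stable filtering (need >= 32 samples)")
  if (all(abs(x) < .Machine$double.eps))
    stop("channel '", recording$channel_labels[idx],
         "' is identically zero: phase undefined")
  xf <- bandpass_filtfilt(x, recording$fs, band)
  ph <- Arg(analytic_signal(xf))
  # Arg() returns (-pi, pi]; map -pi (possible from rounding) to pi
  ph[ph <= -pi] <- pi
  if (trim_edges) {
    n <- length(ph)
    keep <- seq.int(floor(0.05 * n) + 1L, n - floor(0.05 * n))
    ph <- ph[keep]
  }
  structure(list(phase = ph, fs = recording$fs,
                 source_channel = recording$channel_labels[idx]),
            class = "phase_series")
}

# Accept a phase_series or bare numeric vector of radians.
phase_values <- function(p) {
  if (inherits(p, "phase_series")) p$phase else as.numeric(p)
}

#' Phase-locking value between two phase series
#'
#' The modulus of the time-averaged unit phasor of the phase difference:
#' `PLV = | mean_j exp(i * (phi_x[j] - phi_y[j])) |`, computed over all N
#' samples. 1 means perfect phase locking; independent phases give values
#' near `sqrt(pi) / (2 sqrt(N))`.
#'
#' @param phase_x,phase_y phase series (from [instantaneous_phase()]) or
#'   numeric vectors of radians; equal length (and equal fs if both are
#'   phase series).
#' @return scalar in \[0, 1\].
#' @export
plv_pair <- function(phase_x, phase_y) {
  if (inherits(phase_x, "phase_series") && inherits(phase_y, "phase_series") &&
      phase_x$fs != phase_y$fs)
    stop("phase series have different sampling rates")
  px <- phase_values(phase_x); py <- phase_values(phase_y)
  if (length(px) != length(py))
    stop("phase series lengths differ (", length(px), " vs ", length(py), ")")
  min(1, Mod(mean(exp(1i * (px - py)))))
}

#' Pairwise phase-locking matrix of a recording
#'
#' @param recording an [eeg_recording()] with at least 2 channels.
#' @param band `(low, high)` Hz.
#' @param trim_edges see [instantaneous_phase()].
#' @return a `plv_matrix` object: symmetric matrix in \[0, 1\] with unit
#'   diagonal, plus `channel_labels` and `n_samples_used`.
#' @export
plv_matrix <- function(recording, band = c(8, 30), trim_edges = FALSE) {
  k <- nrow(recording$data)
  if (k < 2) stop("need at least 2 channels for a PLV matrix")
  phases <- lapply(seq_len(k), function(i) {
    tryCatch(instantaneous_phase(recording, i, band, trim_edges),
             error = function(e) stop("channel '", recording$channel_labels[i],
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  m <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- plv_pair(phases[[i]], phases[[j]])
  }
  dimnames(m) <- list(recording$channel_labels, recording$channel_labels)
  structure(list(values = m, channel_labels = recording$channel_labels,
                 n_samples_used = length(phases[[1]]$phase)),
            class = "plv_matrix")
}

validate_plv <- function(plv) {
  v <- plv$values
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  if (max(abs(v - t(v))) > 1e-9) stop("PLV matrix must be symmetric")
  if (any(v < 0 | v > 1 + 1e-12)) stop("PLV entries must lie in [0, 1]")
  if (max(abs(diag(v) - 1)) > 1e-12) stop("PLV diagonal must be 1")
  invisible(plv)
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %d channels, N = %d samples\n",
              nrow(x$values), x$n_samples_used))
  print(round(x$values, 3))
  invisible(x)
}

#' Sliding-window PLV matrices
#'
#' Exploratory variant of [plv_matrix()]: phases are extracted once over the
#' whole recording, then the phase-locking value is computed in windows of
#' `window` samples advanced by `step`, giving a coarse view of how
#' synchrony evolves. The full-window PLV remains the primary quantity.
#'
#' @param recording an [eeg_recording()].
#' @param band `(low, high)` Hz.
#' @param window window length in samples.
#' @param step advance between windows in samples (default `window`,
#'   non-overlapping).
#' @return list of `plv_matrix` objects, one per window, each carrying a
#'   `window_start` attribute (1-based sample index).
#' @export
plv_sliding <- function(recording, band = c(8, 30), window = 256,
                        step = window) {
  k <- nrow(recording$data)
  if (k < 2) stop("need at least 2 channels")
  n <- ncol(recording$data)
  if (window < 8 || window > n) stop("window must lie in [8, n_samples]")
  phases <- vapply(seq_len(k), function(i)
    instantaneous_phase(recording, i, band)$phase, numeric(n))
  starts <- seq.int(1L, n - window + 1L, by = step)
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    m <- diag(1, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- plv_pair(phases[idx, i], phases[idx, j])
    }
    dimnames(m) <- list(recording$channel_labels, recording$channel_labels)
    structure(list(values = m, channel_labels = recording$channel_labels,
                   n_samples_used = window),
              window_start = s, class = "plv_matrix")
  })
}

#' Write / read a PLV matrix as labeled TSV
#' @param plv a `plv_matrix`.
#' @param path file path.
#' @export
write_plv <- function(plv, path) {
  utils::write.table(format(plv$values, digits = 17), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_plv
#' @export
read_plv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  m <- (m + t(m)) / 2   # symmetrize text-precision round-off
  structure(list(values = m, channel_labels = rownames(m),
                 n_samples_used = NA_integer_),
            class = "plv_matrix")
}
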