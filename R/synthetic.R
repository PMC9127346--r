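#' @useDynLib adeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default per-state amplitude profiles
#'
#' Gain multiplies the oscillation envelope; volatility sets the depth of the
#' slow (~0.5 s) envelope bursts. Gains increase calm < transitional <
#' morbidity so pooled sample variance orders the states, and volatility
#' increases in step so the *texture* of the recurrence image changes even
#' after per-image rescaling: calm traces are steady, morbidity traces come
#' in large irregular bursts. `spatial` is a per-channel relative gain
#' pattern (recycled over channels) emulating the spatial redistribution of
#' power as disease progresses; it gives the states distinct spatial
#' covariance shapes, which is what spatial filters can exploit.
#'
#' @return named list of `list(gain, volatility, spatial)` per state.
#' @export
default_amplitude_profile <- function() {
  list(calm         = list(gain = 1, volatility = 0.10,
                           spatial = c(1, 1, 1, 1)),
       transitional = list(gain = 2, volatility = 0.45,
                           spatial = c(1, 1.4, 0.75, 1)),
       morbidity    = list(gain = 4, volatility = 0.80,
                           spatial = c(0.7, 1, 1.4, 1.4)))
}

#' Pairwise phase-coupling specification
#'
#' @param kappa symmetric matrix of coupling strengths in \[0, 1\] with unit
#'   diagonal; entry (i, j) near 1 means channels i and j share a common
#'   phase process, 0 means independent phases.
#' @param band frequency band `(low, high)` in Hz; default 8-30 Hz.
#' @param amplitude_profile named list of per-state `list(gain, volatility)`;
#'   see [default_amplitude_profile()].
#' @return a `coupling_spec` object.
#' @export
coupling_spec <- function(kappa, band = c(8, 30),
                          amplitude_profile = default_amplitude_profile()) {
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != ncol(kappa)) stop("kappa must be square")
  if (max(abs(kappa - t(kappa))) > 1e-12) stop("kappa must be symmetric")
  if (any(kappa < 0 | kappa > 1)) stop("kappa entries must lie in [0, 1]")
  if (max(abs(diag(kappa) - 1)) > 1e-12) stop("kappa diagonal must be 1")
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be (low, high) with 0 < low < high")
  structure(list(kappa = kappa, band = as.numeric(band),
                 amplitude_profile = amplitude_profile),
            class = "coupling_spec")
}

# Smooth positive-mean burst envelope, unit-sd fluctuation around 1.
burst_envelope <- function(n, fs, gain, volatility) {
  w <- max(3L, as.integer(fs / 2))
  raw <- stats::rnorm(n + 2L * w)
  sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
  sm <- sm[(w + 1L):(w + n)]
  sm <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
  gain * pmax(0.15, 1 + volatility * sm)
}

#' Generate one phase-coupled multichannel EEG recording
#'
#' Each channel is an amplitude-modulated oscillation in `spec$band` plus
#' white noise, band-pass filtered to the band. A channel's phase is a convex
#' mix of its own random phase walk (with a channel-specific carrier
#' frequency) and a single shared phase walk; the mixing weight is derived
#' from the channel's strongest coupling in `spec$kappa`, so pairs with kappa
#' near 1 phase-lock while pairs with kappa 0 drift apart.
#'
#' @param spec a [coupling_spec()].
#' @param n_samples samples per channel (>= 64).
#' @param fs sampling rate in Hz; must exceed twice the band's upper edge.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @param state optional state label; selects the amplitude profile.
#' @param channel_labels labels; default `ch1..chK`.
#' @param subject_id optional subject identifier.
#' @return an [eeg_recording()].
#' @export
generate_coupled_recording <- function(spec, n_samples = 1000, fs = 128,
                                       seed = NULL, state = NA_character_,
                                       channel_labels = NULL,
                                       subject_id = NA_character_) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_samples < 64) stop("n_samples must be at least 64")
  if (fs <= 2 * spec$band[2])
    stop("configuration error: fs = ", fs, " Hz must exceed twice the band ",
         "upper edge (", spec$band[2], " Hz) to satisfy Nyquist")
  prof <- if (!is.na(state) && state %in% names(spec$amplitude_profile)) {
    spec$amplitude_profile[[state]]
  } else {
    list(gain = 1, volatility = 0.10)
  }
  if (is.null(prof$spatial)) prof$spatial <- 1
  with_seed(seed, {
    k <- nrow(spec$kappa)
    n <- as.integer(n_samples)
    f_lo <- spec$band[1]; f_hi <- spec$band[2]
    f_c <- (f_lo + f_hi) / 2
    delta <- min(3, (f_hi - f_lo) / 2 - 1)
    # coupling weight of each channel to the shared driver; the quarter
    # power steepens the map so PLV separates visibly across kappa values
    off <- spec$kappa; diag(off) <- 0
    a <- apply(off, 1, max)^0.25
    f_i <- f_c + stats::runif(k, -delta, delta)
    sigma <- 0.15                       # phase-walk step (rad/sample)
    shared <- cumsum(stats::rnorm(n, 0, sigma))
    t_idx <- seq_len(n) - 1L
    data <- matrix(0, k, n)
    spatial <- rep_len(prof$spatial, k)
    for (i in seq_len(k)) {
      own <- cumsum(stats::rnorm(n, 0, sigma))
      phase <- 2 * pi * ((1 - a[i]) * f_i[i] + a[i] * f_c) * t_idx / fs +
        (1 - a[i]) * own + a[i] * shared
      g <- prof$gain * spatial[i]
      env <- burst_envelope(n, fs, g, prof$volatility)
      x <- env * cos(phase) + stats::rnorm(n, 0, 0.25 * g)
      data[i, ] <- bandpass_filtfilt(x, fs, spec$band)
    }
    eeg_recording(data, fs = fs, channel_labels = channel_labels,
                  state = state, subject_id = subject_id)
  })
}

default_state_kappa <- function(n_channels) {
  kappa <- diag(n_channels)
  if (n_channels >= 4) {
    # Fp2/F3/F4-style coupled clique; Fp1 weakly connected
    for (i in 2:min(4L, n_channels)) for (j in 2:min(4L, n_channels)) {
      if (i != j) kappa[i, j] <- 0.6
    }
    kappa[1, 2] <- kappa[2, 1] <- 0.1
  } else if (n_channels >= 2) {
    kappa[1, 2] <- kappa[2, 1] <- 0.6
  }
  kappa
}

#' Generate a labeled three-state synthetic EEG dataset
#'
#' Produces `n_per_state` subjects, each contributing one recording per state
#' (calm, transitional, morbidity) under [default_amplitude_profile()], so
#' pooled sample variance strictly increases across the three states.
#'
#' @param n_per_state recordings per state (>= 1).
#' @param n_channels number of channels; the default 4 is labeled
#'   Fp1/Fp2/F3/F4.
#' @param n_samples samples per recording.
#' @param fs sampling rate (Hz).
#' @param seed integer seed; the full dataset is reproducible given the seed.
#' @param kappa optional coupling matrix; default couples Fp2/F3/F4 at 0.6
#'   with Fp1 weakly attached.
#' @return list of [eeg_recording()] objects, length `3 * n_per_state`.
#' @export
generate_state_dataset <- function(n_per_state = 50, n_channels = 4,
                                   n_samples = 1000, fs = 128, seed = 1,
                                   kappa = NULL) {
  if (n_per_state < 1) stop("n_per_state must be >= 1")
  if (is.null(kappa)) kappa <- default_state_kappa(n_channels)
  labels <- if (n_channels == 4) c("Fp1", "Fp2", "F3", "F4")
            else paste0("ch", seq_len(n_channels))
  spec <- coupling_spec(kappa)
  with_seed(seed, {
    recs <- vector("list", 3L * n_per_state)
    idx <- 1L
    for (i in seq_len(n_per_state)) {
      sid <- sprintf("S%03d", i)
      for (st in eeg_states) {
        recs[[idx]] <- generate_coupled_recording(
          spec, n_samples = n_samples, fs = fs, seed = NULL, state = st,
          channel_labels = labels, subject_id = sid)
        idx <- idx + 1L
      }
    }
    recs
  })
}

clinical_feature_names <- c("age", "sex", "hypertension", "hyperlipidemia",
                            "diabetes", "eye_movement")

#' Default injected clinical effects
#'
#' Effect sizes are per adjacent disease state: Cohen's d for continuous
#' features (age rises, eye-movement score falls with disease stage) and a
#' risk difference for binary features. The defaults make age, diabetes and
#' eye_movement carry real class effects while sex, hypertension and
#' hyperlipidemia stay label-independent.
#'
#' @return named list of per-step effect sizes.
#' @export
default_clinical_effects <- function() {
  list(age = 1.0, diabetes = 0.3, eye_movement = 1.0)
}

#' Generate a synthetic clinical covariate table
#'
#' @param n_patients number of patients (>= 10), split as evenly as possible
#'   across the three states.
#' @param effects named list of per-step effect sizes (see
#'   [default_clinical_effects()]); names must be clinical feature names.
#' @param seed integer seed.
#' @return a [clinical_table()] data.frame with one row per patient.
#' @export
generate_clinical_table <- function(n_patients = 100,
                                    effects = default_clinical_effects(),
                                    seed = 1) {
  if (n_patients < 10) stop("n_patients must be >= 10")
  unknown <- setdiff(names(effects), clinical_feature_names)
  if (length(unknown))
    stop("unknown clinical feature(s) in effects: ",
         paste(unknown, collapse = ", "))
  eff <- function(f) if (is.null(effects[[f]])) 0 else effects[[f]]
  with_seed(seed, {
    lab <- rep_len(eeg_states, n_patients)
    step <- match(lab, eeg_states) - 1L        # 0, 1, 2
    rbinom_p <- function(p) stats::rbinom(n_patients, 1, pmin(0.98, pmax(0.02, p)))
    age <- pmin(100, pmax(40, stats::rnorm(n_patients, 62 + step * eff("age") * 8, 8)))
    eye <- stats::rnorm(n_patients, 55 - step * eff("eye_movement") * 10, 10)
    df <- data.frame(
      age = age,
      sex = c("F", "M")[1L + rbinom_p(0.5 + step * eff("sex"))],
      hypertension = rbinom_p(0.30 + step * eff("hypertension")),
      hyperlipidemia = rbinom_p(0.30 + step * eff("hyperlipidemia")),
      diabetes = rbinom_p(0.15 + step * eff("diabetes")),
      eye_movement = eye,
      label = lab,
      stringsAsFactors = FALSE)
    clinical_table(df)
  })
}
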