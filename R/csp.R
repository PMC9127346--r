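rec_matrix <- function(x) {
  if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
}

#' Trace-normalized covariance of a trial
#'
#' `R = X X^T / trace(X X^T)`: symmetric, positive semi-definite, unit
#' trace, so trials of different power contribute comparably to the class
#' averages.
#'
#' @param X channels-by-samples matrix (or an [eeg_recording()]).
#' @return M-by-M covariance matrix with trace 1.
#' @export
normalized_covariance <- function(X) {
  X <- rec_matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  S <- tcrossprod(X)
  tr <- sum(diag(S))
  if (tr <= 0) stop("zero-power trial: trace of X X^T is 0")
  S / tr
}

#' Fit two-class common spatial patterns
#'
#' Learns spatial filters that maximise the variance of one class while
#' minimising the other. The class-average normalized covariances are
#' summed, the composite is whitened (`P = Lambda_c^{-1/2} U_c^T`, so
#' `P Rc P^T = I`), and the whitened class-1 covariance is diagonalized by
#' an orthogonal `B`; because the whitened class covariances sum to the
#' identity, `B` diagonalizes both with eigenvalue matrices satisfying
#' `Lambda1 + Lambda2 = I`. The projection is `W = (B^T P)^T`, columns
#' ordered by decreasing class-1 eigenvalue: the first columns respond to
#' class 1, the last to class 2.
#'
#' @param class1,class2 lists of channels-by-samples matrices or
#'   [eeg_recording()]s, equal channel counts.
#' @param m filters kept per side; `2m` must not exceed the channel count.
#' @param regularize add a ridge `lambda I` with
#'   `lambda = 1e-6 trace(Rc) / M` to the composite covariance before the
#'   eigendecomposition (default `TRUE`).
#' @return a `csp_model`: `R1_bar`, `R2_bar`, `Rc`, `P`, `B`, `Lambda1`,
#'   `Lambda2`, `W` (M-by-M, columns = filters), `m`.
#' @export
fit_csp <- function(class1, class2, m = 1, regularize = TRUE) {
  if (!length(class1) || !length(class2)) stop("both classes must be non-empty")
  avg_cov <- function(recs) {
    covs <- lapply(recs, normalized_covariance)
    M <- nrow(covs[[1]])
    if (!all(vapply(covs, nrow, 0L) == M))
      stop("inconsistent channel counts within a class")
    Reduce(`+`, covs) / length(covs)
  }
  R1 <- avg_cov(class1)
  R2 <- avg_cov(class2)
  if (nrow(R1) != nrow(R2)) stop("classes have different channel counts")
  M <- nrow(R1)
  if (2 * m > M) stop("2m = ", 2 * m, " filters exceed the ", M, " channels")
  Rc <- R1 + R2
  if (regularize) Rc <- Rc + diag(1e-6 * sum(diag(Rc)) / M, M)
  ec <- eigen(Rc, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values))
    stop("composite covariance is rank deficient; enable regularize = TRUE ",
         "or supply more/longer trials")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S1 <- P %*% R1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)        # eigenvalues descending
  B <- e1$vectors
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(M)) {
    k <- which.max(abs(B[, j]))
    if (B[k, j] < 0) B[, j] <- -B[, j]
  }
  l1 <- e1$values
  W <- t(P) %*% B
  rownames(W) <- rownames(R1)
  structure(list(R1_bar = R1, R2_bar = R2, Rc = Rc, P = P, B = B,
                 Lambda1 = diag(l1, M), Lambda2 = diag(1 - l1, M),
                 W = W, m = as.integer(m)),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, m = %d; class-1 eigenvalues: %s\n",
              nrow(x$W), x$m,
              paste(round(diag(x$Lambda1), 3), collapse = ", ")))
  invisible(x)
}

#' Extract CSP features from a trial
#'
#' Projects the trial through the filter bank (`Z = W^T X`) and summarises
#' the first m and last m filter outputs. `log_variance` (default, the
#' standard CSP feature) returns the log of each selected output's variance
#' normalized by the total over selected outputs, so it is invariant to
#' amplitude rescaling; `paper_max` returns each selected output's maximum
#' absolute value.
#'
#' @param model a `csp_model`.
#' @param X channels-by-samples matrix or [eeg_recording()].
#' @param selector `"log_variance"` or `"paper_max"`.
#' @return numeric feature vector of length `2m`.
#' @export
csp_features <- function(model, X, selector = c("log_variance", "paper_max")) {
  selector <- match.arg(selector)
  X <- rec_matrix(X)
  M <- nrow(model$W)
  if (nrow(X) != M)
    stop("trial has ", nrow(X), " channels but the model expects ", M)
  m <- model$m
  sel <- c(seq_len(m), seq.int(M - m + 1L, M))
  Z <- t(model$W[, sel, drop = FALSE]) %*% X
  if (selector == "paper_max") {
    f <- apply(abs(Z), 1, max)
  } else {
    v <- apply(Z, 1, stats::var)
    f <- log(v / sum(v))
  }
  stats::setNames(as.numeric(f), paste0("csp", sel))
}

#' One-vs-rest CSP filter banks for the three disease states
#'
#' Two-class CSP applied once per state against the union of the other two,
#' giving three filter banks; per-trial features are the concatenation of
#' the three banks' features (length `3 * 2m`).
#'
#' @param recordings list of [eeg_recording()]s with state labels.
#' @param m filters per side for each bank.
#' @param selector passed to [csp_features()].
#' @return a `csp_ovr` object (list of three `csp_model`s).
#' @export
fit_csp_ovr <- function(recordings, m = 1,
                        selector = c("log_variance", "paper_max")) {
  selector <- match.arg(selector)
  states <- vapply(recordings, function(r) r$state, "")
  if (length(unique(states[states %in% eeg_states])) < 2)
    stop("need recordings from at least 2 states")
  models <- lapply(eeg_states, function(st) {
    fit_csp(recordings[states == st], recordings[states != st], m = m)
  })
  structure(list(models = stats::setNames(models, eeg_states),
                 selector = selector),
            class = "csp_ovr")
}

#' @rdname fit_csp_ovr
#' @param model a `csp_ovr` object.
#' @param X a trial.
#' @export
csp_features_ovr <- function(model, X) {
  f <- lapply(eeg_states, function(st) {
    v <- csp_features(model$models[[st]], X, model$selector)
    stats::setNames(v, paste0(st, "_", names(v)))
  })
  do.call(c, f)
}
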