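clinical_feature_kind <- c(age = "continuous", sex = "binary",
                           hypertension = "binary", hyperlipidemia = "binary",
                           diabetes = "binary", eye_movement = "continuous")

#' Screen clinical covariates for class association
#'
#' Tests each covariate against the three-state label: continuous features
#' by the Kruskal-Wallis rank test, binary features by the chi-squared
#' independence test (Fisher's exact test when any expected cell count falls
#' below 5). Features with p below `alpha` are selected. No multiple-testing
#' correction is applied by default; set `correction` to any
#' [stats::p.adjust()] method to change that.
#'
#' @param table a [clinical_table()].
#' @param alpha significance level in (0, 1).
#' @param correction p-adjustment method (default `"none"`).
#' @return a `screening_result`: data.frame of feature/test/statistic/p plus
#'   the selected feature names and `alpha`.
#' @export
screen_clinical <- function(table, alpha = 0.05, correction = "none") {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  lab <- factor(table$label, levels = eeg_states)
  if (nlevels(droplevels(lab)) < 2)
    stop("need at least 2 states represented for screening")
  rows <- lapply(names(clinical_feature_kind), function(f) {
    x <- table[[f]]
    if (f == "sex") x <- as.integer(x == "M")
    if (length(unique(x)) < 2L) {
      warning("feature '", f, "' is constant; p set to 1")
      return(data.frame(feature = f, test = "none", statistic = NA_real_,
                        p = 1))
    }
    if (clinical_feature_kind[[f]] == "continuous") {
      ht <- stats::kruskal.test(x, lab)
      data.frame(feature = f, test = "kruskal-wallis",
                 statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      tab <- table(x, lab)
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ht <- stats::fisher.test(tab)
        data.frame(feature = f, test = "fisher-exact", statistic = NA_real_,
                   p = ht$p.value)
      } else {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(feature = f, test = "chi-squared",
                   statistic = unname(ht$statistic), p = ht$p.value)
      }
    }
  })
  df <- do.call(rbind, rows)
  df$p_adj <- stats::p.adjust(df$p, method = correction)
  structure(list(tests = df, selected = df$feature[df$p_adj < alpha],
                 alpha = alpha),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> alpha =", x$alpha, "\n")
  print(transform(x$tests, p = signif(p, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

simplex_check <- function(p, tol = 1e-6) {
  p <- as.matrix(p)
  stopifnot(all(p >= -tol), all(abs(rowSums(p) - 1) <= tol))
  invisible(p)
}

# Seeded, L2-regularized multinomial logistic fit on standardized features.
fit_multinom <- function(X, labels, seed = 1, decay = 1e-2) {
  X <- as.matrix(X)
  y <- factor(as.character(labels), levels = eeg_states)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, ctr, scl)
  df <- data.frame(Xs)
  names(df) <- paste0("f", seq_len(ncol(Xs)))
  df$.y <- y
  fit <- with_seed(seed, nnet::multinom(.y ~ ., df, decay = decay,
                                        trace = FALSE, maxit = 300))
  structure(list(fit = fit, center = ctr, scale = scl, p = ncol(X)),
            class = "adeeg_multinom")
}

predict_multinom <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("feature dimension ", ncol(X), " does not match the fitted model (",
         model$p, ")")
  df <- data.frame(scale(X, model$center, model$scale))
  names(df) <- paste0("f", seq_len(ncol(X)))
  pr <- stats::predict(model$fit, df, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(X), byrow = FALSE,
                                     dimnames = list(NULL, names(pr)))
  out <- matrix(0, nrow(X), 3, dimnames = list(NULL, eeg_states))
  out[, colnames(pr)] <- pr
  simplex_check(out)
}

#' Combined CSP + network features for the PE branch
#'
#' Per recording: the one-vs-rest CSP features concatenated with the PLV
#' brain-network metric vector.
#'
#' @param recordings list of [eeg_recording()]s.
#' @param csp a fitted [fit_csp_ovr()] bank.
#' @param band PLV band in Hz.
#' @return numeric feature matrix, one row per recording.
#' @export
pe_features <- function(recordings, csp, band = c(8, 30)) {
  rows <- lapply(recordings, function(rec) {
    c(csp_features_ovr(csp, rec),
      network_feature_vector(from_plv(plv_matrix(rec, band))))
  })
  do.call(rbind, rows)
}

#' Fit / apply the PE classifier
#'
#' Multinomial logistic regression over the combined CSP and network
#' features, seeded and L2-regularized.
#'
#' @param features feature matrix (rows = recordings), e.g. from
#'   [pe_features()].
#' @param labels state labels for the training rows.
#' @param seed integer seed.
#' @return `fit_pe`: a `pe_model`; `classify_pe`: n-by-3 simplex matrix.
#' @export
fit_pe <- function(features, labels, seed = 1) {
  m <- fit_multinom(features, labels, seed)
  class(m) <- c("pe_model", class(m))
  m
}

#' @rdname fit_pe
#' @param model a `pe_model`.
#' @export
classify_pe <- function(model, features) predict_multinom(model, features)

#' Fit / apply the clinical probability model
#'
#' Multinomial logistic regression over the screened covariates only. With
#' an empty screened set the model is uninformative and predicts the uniform
#' vector (1/3, 1/3, 1/3) with a warning.
#'
#' @param table training [clinical_table()].
#' @param screening a `screening_result` from [screen_clinical()].
#' @param seed integer seed.
#' @return a `clinical_model`.
#' @export
fit_clinical <- function(table, screening, seed = 1) {
  feats <- screening$selected
  if (!length(feats)) {
    warning("no screened features; clinical model is uninformative")
    return(structure(list(features = character(0)), class = "clinical_model"))
  }
  X <- clinical_design(table, feats)
  m <- fit_multinom(X, table$label, seed)
  structure(list(features = feats, model = m), class = "clinical_model")
}

clinical_design <- function(table, feats) {
  X <- sapply(feats, function(f) {
    x <- table[[f]]
    if (f == "sex") {
      bad <- !x %in% c("F", "M")
      if (any(bad)) {
        warning("unseen sex level mapped to reference 'F'")
        x[bad] <- "F"
      }
      as.numeric(x == "M")
    } else as.numeric(x)
  })
  matrix(X, nrow = nrow(table), dimnames = list(NULL, feats))
}

#' @rdname fit_clinical
#' @param model a `clinical_model`.
#' @export
clinical_probability <- function(model, table) {
  if (!length(model$features)) {
    return(simplex_check(matrix(1 / 3, nrow(table), 3,
                                dimnames = list(NULL, eeg_states))))
  }
  predict_multinom(model$model, clinical_design(table, model$features))
}

#' Fit a stacked fusion meta-classifier
#'
#' Multinomial logistic regression over the concatenated source
#' probabilities; fit it on a fold held out from the base-model training
#' data so the meta-model sees honest probabilities.
#'
#' @param sources named list of n-by-3 probability matrices (e.g. `pe`,
#'   `re`, `clinical`) on the meta fold.
#' @param labels state labels on the meta fold.
#' @param seed integer seed.
#' @return a `fusion_meta` model.
#' @export
fit_stacked_fusion <- function(sources, labels, seed = 1) {
  X <- do.call(cbind, lapply(sources, simplex_check))
  m <- fit_multinom(X, labels, seed)
  structure(list(model = m, n_sources = length(sources)),
            class = "fusion_meta")
}

#' Decision-level fusion of source probabilities
#'
#' Combines per-source class probabilities into one decision vector:
#' `mean` averages the available sources and renormalizes; `weighted` takes
#' a convex combination (weights renormalized with a warning if they do not
#' sum to 1); `stacked` applies a fitted [fit_stacked_fusion()]
#' meta-classifier.
#'
#' @param sources named list of n-by-3 probability matrices (or 3-vectors);
#'   at least one.
#' @param method `"mean"`, `"weighted"` or `"stacked"`.
#' @param weights numeric weights, one per source (weighted only).
#' @param meta a `fusion_meta` (stacked only).
#' @return n-by-3 fused probability matrix on the simplex.
#' @export
fuse <- function(sources, method = c("mean", "weighted", "stacked"),
                 weights = NULL, meta = NULL) {
  method <- match.arg(method)
  if (!length(sources)) stop("at least one probability source required")
  mats <- lapply(sources, function(s) {
    if (is.null(dim(s))) s <- matrix(s, 1)
    colnames(s) <- eeg_states
    simplex_check(s)
  })
  n <- unique(vapply(mats, nrow, 0L))
  if (length(n) != 1) stop("sources have different numbers of rows")
  fused <- switch(method,
    mean = Reduce(`+`, mats) / length(mats),
    weighted = {
      if (is.null(weights) || length(weights) != length(mats))
        stop("weighted fusion needs one weight per source")
      if (any(weights < 0)) stop("weights must be non-negative")
      if (abs(sum(weights) - 1) > 1e-8) {
        warning("weights do not sum to 1; renormalizing")
        weights <- weights / sum(weights)
      } else weights <- weights / sum(weights)
      Reduce(`+`, Map(`*`, mats, as.list(weights)))
    },
    stacked = {
      if (is.null(meta) || !inherits(meta, "fusion_meta"))
        stop("stacked fusion needs a fitted fusion_meta model")
      predict_multinom(meta$model, do.call(cbind, mats))
    })
  fused <- fused / rowSums(fused)
  colnames(fused) <- eeg_states
  simplex_check(fused)
}

#' One-vs-rest confusion counts
#'
#' @param predicted,truth state labels (or factors), equal length.
#' @param positive_class the state treated as positive.
#' @return named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, truth, positive_class) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  pp <- predicted == positive_class
  tp <- truth == positive_class
  c(TP = sum(pp & tp), FP = sum(pp & !tp),
    TN = sum(!pp & !tp), FN = sum(!pp & tp))
}

#' Classification accuracy from confusion counts
#'
#' `A = (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return scalar in \[0, 1\].
#' @export
accuracy <- function(counts) {
  counts <- unlist(counts)[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative TP/FP/TN/FN")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  unname((counts["TP"] + counts["TN"]) / total)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the scores of the positive class,
#' one-vs-rest; ties share a threshold. The AUC equals the rank
#' (concordance) statistic.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels state labels (or any labels), same length.
#' @param positive_class label treated as positive.
#' @return list with non-decreasing `fpr`, `tpr`, the `thresholds`, and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels, positive_class) {
  pos <- as.character(labels) == as.character(positive_class)
  if (!any(pos) || all(pos))
    stop("ROC needs both positive and negative samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[keep]; fp <- cumsum(!p)[keep]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[keep]), auc = auc)
}
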