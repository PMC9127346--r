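#' Pipeline configuration
#'
#' Desk-scale defaults: 50 subjects per state (150 recordings), 4 channels,
#' 1000 samples at 128 Hz, recurrence images at side 64, 30 training epochs.
#'
#' @param n_per_state subjects per state.
#' @param n_channels EEG channels.
#' @param n_samples samples per recording.
#' @param fs sampling rate (Hz).
#' @param band PLV band (Hz).
#' @param side recurrence-image side.
#' @param epochs,batch,lr CNN training hyperparameters.
#' @param m_csp CSP filters per side.
#' @param rp_channel channel feeding the recurrence branch (label or index).
#' @param fusion `"stacked"`, `"mean"` or `"weighted"`.
#' @param weights fusion weights (weighted only).
#' @param test_fraction fraction of subjects held out for evaluation.
#' @param meta_fraction fraction of remaining subjects used to fit the
#'   stacked meta-classifier.
#' @param seed master seed.
#' @return a config list.
#' @export
pipeline_config <- function(n_per_state = 50, n_channels = 4,
                            n_samples = 1000, fs = 128, band = c(8, 30),
                            side = 64, epochs = 30, batch = 16, lr = 1e-3,
                            m_csp = 1, rp_channel = 1,
                            fusion = "stacked", weights = NULL,
                            test_fraction = 0.25, meta_fraction = 0.25,
                            seed = 1) {
  as.list(environment())
}

#' Run the full synthetic evaluation pipeline
#'
#' Generates the labeled synthetic dataset and aligned clinical table, then
#' runs the three decision branches and their fusion:
#' PLV network + CSP features -> multinomial classifier (PE);
#' unthresholded recurrence images -> residual CNN (RE);
#' screened clinical covariates -> multinomial model (clinical);
#' decision-level fusion of the three probability sets. Subjects are split
#' into train / meta / test groups so all reported accuracies are held-out,
#' and every stage is seeded from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a report list: per-source and fused test accuracies, Eq.-style
#'   one-vs-rest accuracies, 3x3 confusion matrices, per-state ROC/AUC of
#'   the fused decision, screening results, stage timings and seeds.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  t0 <- proc.time()[["elapsed"]]
  recs <- generate_state_dataset(cf$n_per_state, cf$n_channels, cf$n_samples,
                                 cf$fs, seed = cf$seed)
  clin <- generate_clinical_table(3 * cf$n_per_state, seed = cf$seed + 1)
  labels <- vapply(recs, function(r) r$state, "")
  stopifnot(identical(labels, clin$label))   # rows aligned to recordings
  subjects <- vapply(recs, function(r) r$subject_id, "")
  tick("simulate", t0)

  # subject-level split: all three states of a subject stay together
  uniq <- unique(subjects)
  split <- with_seed(cf$seed + 2, {
    test_s <- sample(uniq, max(1L, round(cf$test_fraction * length(uniq))))
    rest <- setdiff(uniq, test_s)
    meta_s <- if (cf$fusion == "stacked") {
      sample(rest, max(1L, round(cf$meta_fraction * length(rest))))
    } else character(0)
    list(test = test_s, meta = meta_s, train = setdiff(rest, meta_s))
  })
  idx_train <- which(subjects %in% split$train)
  idx_meta <- which(subjects %in% split$meta)
  idx_test <- which(subjects %in% split$test)

  # PE branch: CSP one-vs-rest + PLV network metrics -> multinomial
  t0 <- proc.time()[["elapsed"]]
  csp <- fit_csp_ovr(recs[idx_train], m = cf$m_csp)
  feat <- pe_features(recs, csp, cf$band)
  pe_model <- fit_pe(feat[idx_train, , drop = FALSE], labels[idx_train],
                     seed = cf$seed + 3)
  pe_prob <- classify_pe(pe_model, feat)
  tick("pe_branch", t0)

  # RE branch: unthresholded recurrence images -> residual CNN
  t0 <- proc.time()[["elapsed"]]
  images <- lapply(recs, recurrence_image, channel = cf$rp_channel,
                   side_out = cf$side)
  tick("recurrence_images", t0)
  t0 <- proc.time()[["elapsed"]]
  net <- build_rpnet(rpnet_config(side = cf$side, seed = cf$seed + 4))
  net <- train_rpnet(net, images[idx_train], labels[idx_train],
                     epochs = cf$epochs, batch = cf$batch, lr = cf$lr,
                     seed = cf$seed + 4, val_fraction = 0)
  re_prob <- predict_re(net, images)
  tick("rpnet_training", t0)

  # clinical branch: screen then model
  t0 <- proc.time()[["elapsed"]]
  screening <- screen_clinical(clin[idx_train, ])
  clin_model <- fit_clinical(clin[idx_train, ], screening,
                             seed = cf$seed + 5)
  clin_prob <- clinical_probability(clin_model, clin)
  tick("clinical", t0)

  # fusion
  t0 <- proc.time()[["elapsed"]]
  sub <- function(p, idx) p[idx, , drop = FALSE]
  sources_of <- function(idx) list(pe = sub(pe_prob, idx),
                                   re = sub(re_prob, idx),
                                   clinical = sub(clin_prob, idx))
  meta <- NULL
  if (cf$fusion == "stacked") {
    meta <- fit_stacked_fusion(sources_of(idx_meta), labels[idx_meta],
                               seed = cf$seed + 6)
  }
  fused_prob <- fuse(sources_of(idx_test), method = cf$fusion,
                     weights = cf$weights, meta = meta)
  tick("fusion", t0)

  truth <- labels[idx_test]
  pred_of <- function(p) eeg_states[max.col(p, ties.method = "first")]
  eval_source <- function(p) {
    pred <- pred_of(p)
    per_class <- vapply(eeg_states, function(st)
      accuracy(confusion_counts(pred, truth, st)), 0)
    list(accuracy = mean(pred == truth),
         per_class_accuracy = per_class,
         macro_accuracy = mean(per_class),
         confusion = table(truth = factor(truth, eeg_states),
                           predicted = factor(pred, eeg_states)))
  }
  sources_test <- sources_of(idx_test)
  evaluation <- lapply(c(sources_test, list(fused = fused_prob)), eval_source)
  roc <- lapply(stats::setNames(eeg_states, eeg_states), function(st)
    roc_curve(fused_prob[, st], truth, st))

  list(config = cf,
       split = split,
       screening = screening,
       train_report = net$report,
       accuracies = vapply(evaluation, function(e) e$accuracy, 0),
       evaluation = evaluation,
       roc_auc = vapply(roc, function(r) r$auc, 0),
       roc = roc,
       n_test = length(idx_test),
       timings = c(timings, total = round(proc.time()[["elapsed"]] - t_all, 2)),
       seed = cf$seed)
}
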