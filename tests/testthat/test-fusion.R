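test_that("screening selects everything at alpha = 1 and warns on constants", {
  tab <- generate_clinical_table(60, seed = 5)
  sc <- screen_clinical(tab, alpha = 1)
  expect_setequal(sc$selected, c("age", "sex", "hypertension",
                                 "hyperlipidemia", "diabetes", "eye_movement"))
  tab$hypertension <- 0
  expect_warning(sc2 <- screen_clinical(tab), "constant")
  expect_false("hypertension" %in% sc2$selected)
  expect_equal(sc2$tests$p[sc2$tests$feature == "hypertension"], 1)
  expect_error(screen_clinical(tab, alpha = 0), "alpha")
})

test_that("screening recovers injected effects on one table", {
  sc <- screen_clinical(generate_clinical_table(100, seed = 2))
  expect_true(all(c("age", "eye_movement") %in% sc$selected))
  expect_true(all(sc$tests$p >= 0 & sc$tests$p <= 1))
})

test_that("accuracy implements (TP + TN) / total", {
  expect_equal(accuracy(c(TP = 10, FP = 0, TN = 10, FN = 0)), 1)
  expect_equal(accuracy(c(TP = 3, FP = 1, TN = 4, FN = 2)), 0.7)
  expect_equal(accuracy(c(TP = 0, FP = 5, TN = 0, FN = 5)), 0)
  expect_error(accuracy(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("confusion-count accuracy equals the direct decision rate", {
  set.seed(6)
  states <- c("calm", "transitional", "morbidity")
  for (rep in 1:20) {
    truth <- sample(states, 40, TRUE)
    pred <- sample(states, 40, TRUE)
    for (st in states) {
      counts <- confusion_counts(pred, truth, st)
      expect_equal(sum(counts), 40)
      direct <- mean((pred == st) == (truth == st))
      expect_equal(accuracy(counts), direct, tolerance = 1e-12)
    }
  }
})

test_that("roc_curve sweeps thresholds and equals the concordance statistic", {
  # perfect separation
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("a", "a", "b", "b"), "a")
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_error(roc_curve(runif(5), rep("a", 5), "a"), "both positive")

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)   # force ties
    lab <- sample(c("pos", "neg"), n, TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    r <- roc_curve(sc, lab, "pos")
    pos <- sc[lab == "pos"]; neg <- sc[lab == "neg"]
    conc <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, conc, tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("neg", "pos"),
                                                  direction = "<", quiet = TRUE))),
                   tolerance = 1e-12)
    }
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(8)
  sc <- runif(1000)
  lab <- sample(c("pos", "neg"), 1000, TRUE)
  expect_lt(abs(roc_curve(sc, lab, "pos")$auc - 0.5), 0.05)
})

test_that("fusion rules honour fixed points, weights and the simplex", {
  p <- matrix(c(0.2, 0.5, 0.3), 4, 3, byrow = TRUE)
  colnames(p) <- c("calm", "transitional", "morbidity")
  same <- list(pe = p, re = p, clinical = p)
  expect_equal(fuse(same, "mean"), p, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fuse(same, "weighted", weights = c(0.2, 0.3, 0.5)), p,
               tolerance = 1e-12, ignore_attr = TRUE)

  q <- matrix(c(0.7, 0.2, 0.1), 4, 3, byrow = TRUE)
  expect_equal(fuse(list(pe = p, re = q), "weighted", weights = c(1, 0)), p,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(f <- fuse(list(pe = p, re = q), "weighted",
                           weights = c(2, 2)), "renormalizing")
  expect_equal(unname(rowSums(f)), rep(1, 4), tolerance = 1e-9)
  expect_error(fuse(list(), "mean"), "at least one")
  expect_error(fuse(list(pe = p), "stacked"), "fusion_meta")
})

test_that("stacked fusion learns to follow the informative source", {
  set.seed(9)
  n <- 120
  truth <- sample(c("calm", "transitional", "morbidity"), n, TRUE)
  onehot <- t(vapply(truth, function(s)
    0.1 + 0.7 * (c("calm", "transitional", "morbidity") == s), numeric(3)))
  noise <- matrix(runif(n * 3), n); noise <- noise / rowSums(noise)
  meta <- fit_stacked_fusion(list(pe = onehot, re = noise), truth, seed = 1)
  fused <- fuse(list(pe = onehot, re = noise), "stacked", meta = meta)
  pred <- c("calm", "transitional", "morbidity")[max.col(fused)]
  expect_gt(mean(pred == truth), 0.9)
})

test_that("pe and clinical classifiers emit simplex rows deterministically", {
  recs <- tiny_dataset()
  states <- vapply(recs, function(r) r$state, "")
  ovr <- fit_csp_ovr(recs, m = 1)
  feat <- pe_features(recs, ovr)
  pe <- fit_pe(feat, states, seed = 3)
  pr <- classify_pe(pe, feat)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(feat)), tolerance = 1e-6)
  expect_gt(mean(c("calm", "transitional", "morbidity")[max.col(pr)] == states),
            1 / 3 + 0.2)
  # duplicated rows give identical probabilities
  pr2 <- classify_pe(pe, feat[c(1, 1), ])
  expect_identical(pr2[1, ], pr2[2, ])
  expect_error(classify_pe(pe, feat[, -1]), "dimension")

  tab <- generate_clinical_table(90, seed = 11)
  sc <- screen_clinical(tab)
  cm <- fit_clinical(tab[1:60, ], sc, seed = 4)
  cp <- clinical_probability(cm, tab[61:90, ])
  expect_equal(unname(rowSums(cp)), rep(1, 30), tolerance = 1e-6)
  expect_gt(mean(c("calm", "transitional", "morbidity")[max.col(cp)] ==
                   tab$label[61:90]), 1 / 3)
})

test_that("an empty screened set falls back to the uniform distribution", {
  tab <- generate_clinical_table(30, effects = list(), seed = 12)
  sc <- screen_clinical(tab, alpha = 1e-9)
  expect_length(sc$selected, 0)
  expect_warning(cm <- fit_clinical(tab, sc), "uninformative")
  expect_equal(unname(clinical_probability(cm, tab[1:5, ])),
               matrix(1 / 3, 5, 3))
})
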