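test_that("generator is deterministic and respects the shape contract", {
  kap <- diag(4); kap[2:4, 2:4] <- 0.6; diag(kap) <- 1
  spec <- coupling_spec(kap)
  r1 <- generate_coupled_recording(spec, n_samples = 256, seed = 5)
  r2 <- generate_coupled_recording(spec, n_samples = 256, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_identical(dim(r1$data), c(4L, 256L))
  expect_true(all(is.finite(r1$data)))

  d1 <- generate_state_dataset(2, n_samples = 256, seed = 9)
  d2 <- generate_state_dataset(2, n_samples = 256, seed = 9)
  expect_identical(lapply(d1, `[[`, "data"), lapply(d2, `[[`, "data"))

  t1 <- generate_clinical_table(30, seed = 4)
  t2 <- generate_clinical_table(30, seed = 4)
  expect_identical(t1, t2)
})

test_that("coupling spec and generator validate their inputs", {
  expect_error(coupling_spec(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  k <- diag(2); k[1, 2] <- k[2, 1] <- 0.5
  expect_error(coupling_spec(k, band = c(30, 8)), "band")
  spec <- coupling_spec(k)
  expect_error(generate_coupled_recording(spec, n_samples = 32), "64")
  expect_error(generate_coupled_recording(spec, fs = 50), "Nyquist")
})

test_that("state dataset is balanced with strictly increasing variance", {
  recs <- generate_state_dataset(12, n_samples = 1000, seed = 21)
  states <- vapply(recs, function(r) r$state, "")
  expect_length(recs, 36)
  expect_true(all(table(states) == 12))
  expect_true(all(vapply(recs, function(r) ncol(r$data) == 1000, TRUE)))

  v <- vapply(c("calm", "transitional", "morbidity"), function(s)
    mean(vapply(recs[states == s], function(r) stats::var(as.vector(r$data)), 0)), 0)
  expect_lt(v[["calm"]], v[["transitional"]])
  expect_lt(v[["transitional"]], v[["morbidity"]])
})

test_that("a variance threshold separates the three states", {
  recs <- generate_state_dataset(25, n_samples = 1000, seed = 31)
  states <- factor(vapply(recs, function(r) r$state, ""),
                   levels = c("calm", "transitional", "morbidity"))
  lv <- log(vapply(recs, function(r) stats::var(as.vector(r$data)), 0))
  centers <- tapply(lv, states, mean)
  cut1 <- mean(centers[1:2]); cut2 <- mean(centers[2:3])
  pred <- cut(lv, c(-Inf, cut1, cut2, Inf),
              labels = c("calm", "transitional", "morbidity"))
  expect_gte(mean(pred == states), 0.90)
})

test_that("clinical generator injects the stated effects and rejects unknowns", {
  tab <- generate_clinical_table(120, seed = 2)
  expect_equal(nrow(tab), 120)
  expect_true(all(tab$age >= 40 & tab$age <= 100))
  expect_true(all(tab$diabetes %in% 0:1))
  expect_error(generate_clinical_table(50, effects = list(bmi = 1)),
               "unknown clinical feature")

  # injected features shift across states, null features do not
  calm <- tab[tab$label == "calm", ]; morb <- tab[tab$label == "morbidity", ]
  expect_gt(mean(morb$age) - mean(calm$age), 5)
  expect_gt(mean(morb$diabetes) - mean(calm$diabetes), 0.2)
  expect_lt(mean(calm$eye_movement) - mean(morb$eye_movement), 40)
})

test_that("null clinical effects give screening rates near alpha", {
  feats <- c("age", "sex", "hypertension", "hyperlipidemia", "diabetes",
             "eye_movement")
  hits <- integer(6)
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    tab <- generate_clinical_table(100, effects = list(), seed = 7000 + s)
    sel <- screen_clinical(tab)$selected
    hits <- hits + (feats %in% sel)
  }
  rates <- hits / n_rep
  # binomial noise at 60 reps: each rate should stay well below 3 * alpha
  expect_true(all(rates < 0.15))
  expect_lt(mean(rates), 0.10)
})
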