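toy_images <- function(n, side = 32, seed = 1, sd = 0.1) {
  with_seed2(seed, {
    states <- rep(c("calm", "transitional", "morbidity"), length.out = n)
    base <- c(calm = 0.2, transitional = 0.5, morbidity = 0.8)
    imgs <- lapply(seq_len(n), function(i)
      matrix(pmin(1, pmax(0, base[[states[i]]] + rnorm(side^2, 0, sd))),
             side, side))
    list(images = imgs, states = states)
  })
}

test_that("builds are deterministic and reject incompatible input sides", {
  m1 <- build_rpnet(rpnet_config(side = 32, seed = 5))
  m2 <- build_rpnet(rpnet_config(side = 32, seed = 5))
  expect_identical(n_parameters(m1), n_parameters(m2))
  img <- matrix(runif(32 * 32), 32)
  expect_identical(predict_re(m1, img), predict_re(m2, img))
  # different seed changes weights but not the parameter count
  m3 <- build_rpnet(rpnet_config(side = 32, seed = 6))
  expect_identical(n_parameters(m1), n_parameters(m3))
  expect_false(identical(predict_re(m1, img), predict_re(m3, img)))

  expect_error(build_rpnet(rpnet_config(side = 31)), "stride")
  expect_error(build_rpnet(rpnet_config(side = 24)), "must be")
})

test_that("predictions lie on the simplex and are inference-deterministic", {
  m <- build_rpnet(rpnet_config(side = 32, seed = 2))
  arr <- array(runif(32 * 32 * 3), c(32, 32, 3))
  arr[, , 3] <- arr[, , 1]   # duplicated image
  p <- predict_re(m, arr)
  expect_identical(dim(p), c(3L, 3L))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-6)
  expect_identical(p[1, ], p[3, ])
  expect_identical(predict_re(m, arr), p)
  expect_error(predict_re(m, matrix(0, 16, 16)), "expects")
})

test_that("with residual branches silenced, output ignores branch weights", {
  m <- build_rpnet(rpnet_config(side = 32, seed = 3))
  scale_residual_branches(m, 0)
  img <- matrix(runif(32 * 32), 32)
  p0 <- predict_re(m, img)
  # perturb every weight, then zero the residual-branch outputs again;
  # restore conv1/BN1/head so only branch internals differ
  st <- rpnet_state(m)
  keep <- st
  st$weights <- lapply(st$weights, function(w) w + 0.3)
  nw <- length(st$weights)
  st$weights[[1]] <- keep$weights[[1]]            # conv1
  st$weights[[2]] <- keep$weights[[2]]            # bn1 gamma
  st$weights[[3]] <- keep$weights[[3]]            # bn1 beta
  st$weights[[nw - 1]] <- keep$weights[[nw - 1]]  # dense W
  st$weights[[nw]] <- keep$weights[[nw]]          # dense b
  # projection shortcuts must also stay fixed: blocks 3, 5, 7, 8 have them
  # weight layout per block: c1, bn1g, bn1b, c2, bn2g, bn2b [, proj, bnpg, bnpb]
  pos <- 4
  for (blk in 1:8) {
    has_proj <- blk %in% c(3, 5, 7, 8)
    if (has_proj) {
      for (off in 6:8) st$weights[[pos + off]] <- keep$weights[[pos + off]]
      pos <- pos + 9
    } else {
      pos <- pos + 6
    }
  }
  rpnet_restore(m, st)
  scale_residual_branches(m, 0)
  expect_equal(predict_re(m, img), p0, tolerance = 1e-6)
})

test_that("training reduces loss, is seed-reproducible and validates input", {
  toy <- toy_images(24, seed = 11)
  m <- build_rpnet(rpnet_config(side = 32, seed = 11))
  m <- train_rpnet(m, toy$images, toy$states, epochs = 3, batch = 8,
                   seed = 11, val_fraction = 0.25)
  rep1 <- m$report
  expect_length(rep1$train_loss, 3)
  expect_true(all(is.finite(rep1$train_loss)))
  expect_lt(rep1$train_loss[3], rep1$train_loss[1])

  m2 <- build_rpnet(rpnet_config(side = 32, seed = 11))
  m2 <- train_rpnet(m2, toy$images, toy$states, epochs = 3, batch = 8,
                    seed = 11, val_fraction = 0.25)
  expect_equal(rep1$train_loss, m2$report$train_loss, tolerance = 1e-4)

  expect_error(train_rpnet(m, toy$images, rep("calm", 24)), "2 classes")
  expect_error(train_rpnet(m, toy$images, toy$states[-1]), "one label")
  expect_error(train_rpnet(m, toy$images, toy$states, epochs = 0), "epochs")
})

test_that("the network can memorize a small labeled set", {
  toy <- toy_images(30, seed = 12, sd = 0.25)
  m <- build_rpnet(rpnet_config(side = 32, seed = 12))
  m <- train_rpnet(m, toy$images, toy$states, epochs = 25, batch = 10,
                   lr = 1e-3, seed = 12, val_fraction = 0)
  expect_lt(min(m$report$train_loss), 0.1)
})

test_that("checkpoints round-trip through save and load", {
  toy <- toy_images(12, seed = 13)
  m <- build_rpnet(rpnet_config(side = 32, seed = 13))
  m <- train_rpnet(m, toy$images, toy$states, epochs = 2, batch = 6,
                   seed = 13, val_fraction = 0)
  path <- withr::local_tempfile(fileext = ".rds")
  save_rpnet(m, path)
  m2 <- load_rpnet(path)
  arr <- array(runif(32 * 32 * 2), c(32, 32, 2))
  expect_equal(predict_re(m2, arr), predict_re(m, arr), tolerance = 1e-7)
  expect_equal(m2$report$train_loss, m$report$train_loss)
})
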