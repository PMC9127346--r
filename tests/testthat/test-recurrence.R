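test_that("time-delay embedding unrolls the definition", {
  expect_equal(embed_series(c(1, 2, 3, 4), m = 2, tau = 1),
               rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(embed_series(rnorm(1000), m = 1, tau = 1)), 1000)
  # boundary: exactly one state
  expect_equal(nrow(embed_series(1:7, m = 4, tau = 2)), 1)
  expect_error(embed_series(1:6, m = 4, tau = 2), "at least")
})

test_that("distance matrix matches a pairwise loop oracle", {
  expect_equal(distance_matrix(matrix(c(0, 3), 2, 1))[1, 2], 3)
  expect_true(all(distance_matrix(matrix(1, 5, 2)) == 0))

  set.seed(4)
  st <- matrix(rnorm(30), 10, 3)
  for (nm in c("euclidean", "manhattan", "chebyshev")) {
    r <- distance_matrix(st, nm)
    oracle <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      d <- st[i, ] - st[j, ]
      oracle[i, j] <- switch(nm, euclidean = sqrt(sum(d^2)),
                             manhattan = sum(abs(d)), chebyshev = max(abs(d)))
    }
    expect_equal(unname(r), oracle, tolerance = 1e-12)
  }
})

test_that("thresholded plot is the elementwise Heaviside of eps - r", {
  set.seed(5)
  r <- distance_matrix(matrix(rnorm(8), 8, 1))
  eps <- stats::median(r)
  expect_identical(unname(recurrence_plot(r, eps)),
                   (eps - unname(r) >= 0) * 1)
  expect_true(all(recurrence_plot(r, max(r)) == 1))
  expect_true(all(recurrence_plot(r, -0.1) == 0))   # diagonal included
  expect_true(all(diag(recurrence_plot(r, 0)) == 1))
})

test_that("unthresholded plot is |eps - r| and reduces to r at eps = 0", {
  set.seed(6)
  r <- distance_matrix(matrix(rnorm(8), 8, 1))
  expect_equal(no_threshold_rp(r, 0), r, tolerance = 1e-15)
  er <- no_threshold_rp(r, 1.3)
  expect_equal(unname(er), abs(1.3 - unname(r)), tolerance = 1e-12)
  expect_equal(unname(diag(er)), rep(1.3, 8))
  # constant series: every entry |eps|
  rc <- distance_matrix(matrix(2, 6, 1))
  expect_true(all(no_threshold_rp(rc, 0.7) == 0.7))
  # quantile form of epsilon
  expect_equal(no_threshold_rp(r, quantile_of_r = 0),
               abs(min(r[row(r) != col(r)]) - r), tolerance = 1e-12)
})

test_that("thresholding the unthresholded plot recovers the binary plot", {
  set.seed(7)
  for (rep in 1:5) {
    r <- distance_matrix(matrix(rnorm(12), 12, 1))
    eps <- stats::quantile(r, runif(1))
    R <- recurrence_plot(r, eps)
    # sign restoration: eps - r >= 0 iff r <= eps
    expect_identical(unname(R), unname((r <= eps) * 1))
  }
})

test_that("time reversal flips the m = 1 recurrence structure", {
  set.seed(8)
  x <- rnorm(32)
  r <- distance_matrix(embed_series(x, 1, 1))
  rr <- distance_matrix(embed_series(rev(x), 1, 1))
  n <- length(x)
  expect_equal(unname(rr), unname(r[n:1, n:1]), tolerance = 1e-12)
})

test_that("scaling the series scales distances linearly", {
  set.seed(9)
  x <- rnorm(50)
  r1 <- distance_matrix(embed_series(x, 3, 4))
  r3 <- distance_matrix(embed_series(3 * x, 3, 4))
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("rp_to_image downsamples by block means and scales to [0, 1]", {
  # 16x16 checkerboard -> 8x8 of 2x2 block means, all exactly 0.5
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  down <- rp_to_image(cb, 8, scaling = "global", global_max = 1)
  expect_equal(unname(down), matrix(0.5, 8, 8), tolerance = 1e-12)

  # constant matrix maps to all zeros under degenerate minmax
  expect_true(all(rp_to_image(matrix(2.5, 16, 16), 8) == 0))

  set.seed(10)
  big <- distance_matrix(embed_series(rnorm(200), 1, 1))
  img <- rp_to_image(big, 64)
  expect_identical(dim(img), c(64L, 64L))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(range(img), c(0, 1), tolerance = 1e-12)

  expect_error(rp_to_image(big, 4), ">= 8")
  expect_error(rp_to_image(matrix(0, 16, 16), 32), "upsampling")
  expect_error(rp_to_image(big, 64, scaling = "global"), "global_max")
})

test_that("recurrence_image composes the chain on a recording channel", {
  rec <- eeg_recording(rbind(sin(1:300 / 5), cos(1:300 / 7)), fs = 128,
                       channel_labels = c("F3", "F4"))
  img <- recurrence_image(rec, "F4", side_out = 32)
  expect_identical(dim(img), c(32L, 32L))
  expect_true(all(img >= 0 & img <= 1))
})
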