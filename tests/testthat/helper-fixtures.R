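# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# tiny labeled dataset reused across CSP / fusion / pipeline tests
tiny_dataset <- function() {
  if (is.null(fixture_env$tiny)) {
    fixture_env$tiny <- generate_state_dataset(n_per_state = 6,
                                               n_samples = 512, seed = 404)
  }
  fixture_env$tiny
}

# two-class trials with known diagonal covariances diag(5,1) vs diag(1,5)
csp_toy_trials <- function(n_per_class = 100, n_samples = 200, seed = 7) {
  with_seed2(seed, {
    mk <- function(d) lapply(seq_len(n_per_class), function(i)
      diag(sqrt(d)) %*% matrix(stats::rnorm(2 * n_samples), 2))
    list(c1 = mk(c(5, 1)), c2 = mk(c(1, 5)))
  })
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
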