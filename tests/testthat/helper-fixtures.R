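# Shared builders for fast, fully in-code fixtures.

# Small deterministic replicate set from a smooth noiseless response:
# ns = f(bap, iba), other hormones 0. Used for convergence and recovery
# tests where the true function is known.
noiseless_records <- function(n = 150, f = function(b, i) 0.5 * b,
                              seed = 42, noise_sd = 0) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      experiment_id = 1, media_id = seq_len(n), replicate = 1,
      bap = stats::runif(n, 0, 2), kin = stats::runif(n, 0, 2), tdz = 0,
      iba = stats::runif(n, 0, 0.15), naa = 0
    )
    d$ns <- pmax(0, f(d$bap, d$iba) + stats::rnorm(n, 0, noise_sd))
    d$ls <- d$ns + 1
    d$cw <- 0.1 * d$bap
    d$qi <- pmin(5, pmax(0, 5 - d$bap))
    d
  })
}

# Quick training settings for unit tests (full defaults are exercised in
# the acceptance suite).
quick_control <- function(max_epochs = 200, ...) {
  hormonet::ann_control(max_epochs = max_epochs, ...)
}

quick_ga <- function(population_size = 30, generations = 80, ...) {
  hormonet::ga_control(population_size = population_size,
                       generations = generations, ...)
}

expect_monotone_nonincreasing <- function(x) {
  expect_true(all(diff(x) <= 1e-12))
}
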