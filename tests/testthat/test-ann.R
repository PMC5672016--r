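test_that("normalizer maps endpoints to ±1, midpoint to 0, and round-trips", {
  d <- tibble::tibble(a = c(0, 1, 2), b = c(5, 5, 5))
  spec <- fit_normalizer(d)
  expect_equal(normalize_values(c(0, 1, 2), spec, "a"), c(-1, 0, 1))
  # degenerate constant column maps to 0 and is flagged
  expect_true(spec$degenerate[spec$variable == "b"])
  expect_equal(normalize_values(c(5, 7), spec, "b"), c(0, 0))
  withr::with_seed(3, {
    x <- runif(50, -10, 10)
    spec2 <- fit_normalizer(tibble::tibble(x = x))
    expect_equal(denormalize_values(normalize_values(x, spec2, "x"), spec2, "x"),
                 x, tolerance = 1e-14)
  })
})

test_that("forward pass equals an independently coded per-neuron loop", {
  withr::with_seed(21, {
    H <- 3; p <- 2
    m <- structure(list(
      trait = "ns", inputs = c("bap", "iba"), n_hidden = H,
      W1 = matrix(rnorm(H * p), H, p), b1 = rnorm(H), w2 = rnorm(H),
      b2 = rnorm(1)
    ), class = "ann_surrogate")
    loop_oracle <- function(x) {
      out <- m$b2
      for (j in 1:H) {
        a <- m$b1[j]
        for (i in 1:p) a <- a + m$W1[j, i] * x[i]
        out <- out + m$w2[j] * tanh(a)
      }
      out
    }
    for (k in 1:10) {
      x <- rnorm(p)
      expect_equal(forward(m, x), loop_oracle(x), tolerance = 1e-14)
    }
  })
})

test_that("forward edge cases: zero weights and dimension mismatch", {
  z <- structure(list(trait = "ns", inputs = c("bap", "iba"), n_hidden = 2,
                      W1 = matrix(0, 2, 2), b1 = c(0, 0), w2 = c(0, 0),
                      b2 = 0.7), class = "ann_surrogate")
  expect_equal(forward(z, c(3, -1)), 0.7) # zero net outputs its bias
  z$b2 <- 0
  expect_equal(forward(z, c(1, 1)), 0)
  expect_error(forward(z, c(1, 2, 3)), "expected 2 inputs")
})

test_that("LM reaches the MSE goal on a realizable (linear) target", {
  ds <- noiseless_records(n = 100) # ns = 0.5 * bap, noiseless
  m <- train_surrogate(ds, "ns", inputs = c("bap", "kin"), n_hidden = 5,
                       control = ann_control(max_epochs = 800), seed = 1)
  expect_true(m$converged)
  expect_lt(m$n_epochs, 800)
  expect_lte(m$final_mse, 0.01)
})

test_that("accepted-step training MSE history is monotone non-increasing", {
  ds <- noiseless_records(n = 80, noise_sd = 0.1, seed = 9)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "iba"), n_hidden = 4,
                       control = quick_control(), seed = 3)
  expect_gt(nrow(m$history), 1)
  expect_monotone_nonincreasing(m$history$mse)
})

test_that("training is bitwise deterministic in the seed", {
  ds <- noiseless_records(n = 60, noise_sd = 0.05, seed = 2)
  args <- list(ds, "ns", inputs = c("bap", "iba"), n_hidden = 3,
               control = quick_control(max_epochs = 40))
  a <- do.call(train_surrogate, c(args, seed = 5))
  b <- do.call(train_surrogate, c(args, seed = 5))
  expect_identical(a$W1, b$W1)
  expect_identical(a$history, b$history)
  c <- do.call(train_surrogate, c(args, seed = 6))
  expect_false(identical(a$W1, c$W1))
})

test_that("training never touches rows outside the train split", {
  ds <- noiseless_records(n = 90, noise_sd = 0.05, seed = 4) |>
    split_dataset(train_fraction = 0.7, seed = 1)
  poisoned <- ds
  poisoned$ns[poisoned$.split == "test"] <- 999
  args <- list(trait = "ns", inputs = c("bap", "iba"), n_hidden = 3,
               control = quick_control(max_epochs = 30), seed = 8)
  a <- do.call(train_surrogate, c(list(ds), args))
  b <- do.call(train_surrogate, c(list(poisoned), args))
  expect_identical(a$W1, b$W1)
  expect_identical(a$b2, b$b2)
})

test_that("predict equals the manual normalize-forward-denormalize chain", {
  ds <- noiseless_records(n = 70, noise_sd = 0.1, seed = 6)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "iba"), n_hidden = 3,
                       control = quick_control(max_epochs = 30), seed = 2)
  new <- tibble::tibble(bap = c(0.3, 1.7), iba = c(0.02, 0.13))
  manual <- denormalize_values(
    forward(m, cbind(normalize_values(new$bap, m$normalization, "bap"),
                     normalize_values(new$iba, m$normalization, "iba"))),
    m$normalization, "ns")
  expect_equal(predict(m, new), manual, tolerance = 1e-14)
})

test_that("meeting the normalized goal bounds the raw training RMSE", {
  ds <- noiseless_records(n = 100)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "kin"), n_hidden = 5,
                       control = ann_control(max_epochs = 800), seed = 1)
  expect_true(m$converged)
  spec <- m$normalization
  half_range <- (spec$max[spec$variable == "ns"] -
                 spec$min[spec$variable == "ns"]) / 2
  # goal met on the fit rows; check the bound there (val rows excluded)
  ev <- evaluate_surrogate(m, ds)
  expect_lte(ev$rmse[1], half_range * sqrt(m$control$mse_goal) * 1.05)
})

test_that("a smooth 2-input surface is recovered from noisy replicates", {
  ds <- noiseless_records(
    n = 250, seed = 13, noise_sd = 0.05,
    f = function(b, i) 2 + sin(b * 2) + 8 * i
  ) |> split_dataset(train_fraction = 0.7, seed = 2)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "iba"), n_hidden = 6,
                       control = ann_control(), seed = 1)
  ev <- evaluate_surrogate(m, ds)
  expect_gt(ev$r_squared[ev$split == "test"], 0.95)
})

test_that("constant-trait training data is rejected", {
  ds <- noiseless_records(n = 30, f = function(b, i) 1)
  expect_error(train_surrogate(ds, "ns", inputs = c("bap", "iba"), seed = 1),
               "constant")
})

test_that("four trait models share the input normalization on one split", {
  ds <- expand_replicates(media_tables(experiment = 1), seed = 5) |>
    split_dataset(seed = 5)
  ms <- lapply(c("ns", "ls"), function(tr) {
    train_surrogate(ds, tr, n_hidden = 3,
                    control = quick_control(max_epochs = 15), seed = 1)
  })
  in_spec <- function(m) {
    s <- m$normalization
    as.data.frame(s[s$variable %in% hormone_cols(), ])
  }
  expect_equal(in_spec(ms[[1]]), in_spec(ms[[2]]))
})

test_that("JSON serialization round-trips predictions exactly", {
  ds <- noiseless_records(n = 60, noise_sd = 0.1, seed = 3)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "iba"), n_hidden = 3,
                       control = quick_control(max_epochs = 25), seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  new <- tibble::tibble(bap = seq(0, 2, length.out = 9),
                        iba = seq(0, 0.15, length.out = 9))
  expect_equal(predict(m2, new), predict(m, new), tolerance = 1e-12)
  expect_equal(m2$trait, "ns")
})

test_that("tidy and glance expose coefficients and fit metadata", {
  ds <- noiseless_records(n = 50, noise_sd = 0.1, seed = 8)
  m <- train_surrogate(ds, "ns", inputs = c("bap", "iba"), n_hidden = 3,
                       control = quick_control(max_epochs = 10), seed = 1)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 3 * 2 + 3 + 3 + 1)
  expect_true(all(is.finite(td$estimate)))
  gl <- generics::glance(m)
  expect_equal(gl$n_hidden, 3)
  expect_equal(gl$trait, "ns")
})
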