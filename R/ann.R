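#' Training control for the Levenberg-Marquardt fitter
#'
#' Defaults mirror the published training protocol: stop when the
#' mean-squared error on the normalized output scale reaches 0.01, or after
#' 800 epochs. The damping schedule is the conventional one: start at
#' `lambda0`, divide by `lambda_dec` after an accepted step, multiply by
#' `lambda_inc` after a rejected one, abort if `lambda_max` is exceeded
#' before any step is accepted.
#'
#' In addition, a validation fraction of the training rows is held out for
#' early stopping, the standard guard against the wild between-point
#' oscillations a fully converged unregularized network develops on small
#' noisy data: training stops once the validation MSE has failed to improve
#' for `max_fail` consecutive epochs and the weights from the
#' best-validation epoch are restored. The default patience of 50 is long
#' relative to the usual 6 because accepted Levenberg-Marquardt steps are
#' large and the validation curve is coarse; stopping is then governed by
#' the validation minimum rather than transient plateaus. Set
#' `val_fraction = 0` to disable and train to full convergence on all
#' rows.
#'
#' @param max_epochs Maximum number of accepted LM iterations.
#' @param mse_goal Stopping MSE on the normalized (\[-1, 1\]) output scale.
#' @param lambda0,lambda_inc,lambda_dec,lambda_max Damping schedule.
#' @param val_fraction Fraction of training rows held out for early
#'   stopping (default 0.15; 0 disables early stopping).
#' @param max_fail Consecutive epochs without validation improvement
#'   tolerated before stopping.
#' @return A list of class `ann_control`.
#' @export
ann_control <- function(max_epochs = 800, mse_goal = 0.01, lambda0 = 1e-3,
                        lambda_inc = 10, lambda_dec = 10, lambda_max = 1e10,
                        val_fraction = 0.15, max_fail = 50) {
  stopifnot(max_epochs >= 1, mse_goal > 0, lambda0 > 0,
            lambda_inc > 1, lambda_dec > 1, lambda_max > lambda0,
            val_fraction >= 0, val_fraction < 1, max_fail >= 1)
  structure(list(max_epochs = max_epochs, mse_goal = mse_goal,
                 lambda0 = lambda0, lambda_inc = lambda_inc,
                 lambda_dec = lambda_dec, lambda_max = lambda_max,
                 val_fraction = val_fraction, max_fail = max_fail),
            class = "ann_control")
}

# ---- parameter packing -----------------------------------------------------

n_params <- function(n_inputs, n_hidden) n_hidden * n_inputs + 2 * n_hidden + 1

pack_params <- function(W1, b1, w2, b2) c(as.vector(W1), b1, w2, b2)

unpack_params <- function(theta, n_inputs, n_hidden) {
  i <- n_hidden * n_inputs
  list(
    W1 = matrix(theta[seq_len(i)], nrow = n_hidden, ncol = n_inputs),
    b1 = theta[i + seq_len(n_hidden)],
    w2 = theta[i + n_hidden + seq_len(n_hidden)],
    b2 = theta[i + 2 * n_hidden + 1]
  )
}

# ---- forward pass ----------------------------------------------------------

# X: n x p matrix on the normalized scale. Returns length-n vector.
forward_matrix <- function(W1, b1, w2, b2, X) {
  A <- X %*% t(W1)
  A <- sweep(A, 2, b1, "+")
  H <- tanh(A)
  drop(H %*% w2) + b2
}

#' Forward pass of a trained surrogate on the normalized scale
#'
#' Computes `b2 + sum_j w2_j * tanh(b1_j + sum_i W1_ji * x_i)`: a tanh
#' hidden layer followed by a linear output unit. Operates on normalized
#' inputs and returns normalized outputs; [predict.ann_surrogate()] wraps
#' it between the normalization maps.
#'
#' @param model An `ann_surrogate`.
#' @param x Numeric vector of length `n_inputs`, or a matrix with
#'   `n_inputs` columns.
#' @return Numeric vector of normalized network outputs.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "ann_surrogate"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(model$inputs)) {
    abort(sprintf("expected %d inputs, got %d", length(model$inputs), ncol(X)))
  }
  forward_matrix(model$W1, model$b1, model$w2, model$b2, X)
}

# Jacobian of predictions wrt packed parameters; n x P matrix.
forward_jacobian <- function(W1, b1, w2, b2, X) {
  n <- nrow(X); p <- ncol(X); H <- length(b1)
  A <- sweep(X %*% t(W1), 2, b1, "+")
  Th <- tanh(A)                       # n x H
  D <- (1 - Th^2) * matrix(w2, n, H, byrow = TRUE)  # n x H: df/da_j
  # d f / d W1[j, i] = D[, j] * X[, i]; column order matches pack_params
  JW <- matrix(0, n, H * p)
  for (i in seq_len(p)) JW[, (i - 1) * H + seq_len(H)] <- D * X[, i]
  cbind(JW, D, Th, rep(1, n))
}

# ---- training --------------------------------------------------------------

#' Train a single-hidden-layer surrogate by Levenberg-Marquardt
#'
#' Fits a feed-forward network (tanh hidden layer, linear output) mapping
#' hormone concentrations to one growth trait. Inputs and the output are
#' min-max normalized to \[-1, 1\] using the training rows only; weights are
#' initialized from a seeded uniform draw on \[-0.5, 0.5\]; damped
#' Gauss-Newton (Levenberg-Marquardt) steps are accepted only if they
#' reduce the training MSE, so the recorded per-epoch MSE history is
#' non-increasing. Training stops at the MSE goal, the epoch cap, or when
#' the damping parameter exceeds its maximum without an acceptable step.
#'
#' @param data Replicate tibble; if it has a `.split` column only the
#'   `"train"` rows are fitted (the rest are kept aside for evaluation).
#' @param trait Output trait, one of [trait_names()].
#' @param inputs Input columns; defaults to the five hormones. Sensitivity
#'   refits pass a subset.
#' @param n_hidden Hidden-layer size (default 10).
#' @param control An [ann_control()] list.
#' @param seed Integer seed for weight initialization.
#' @return An `ann_surrogate` object: weights, normalization spec, training
#'   history and metadata.
#' @export
#' @examples
#' ds <- media_tables(1) |> expand_replicates(seed = 1) |> split_dataset(seed = 1)
#' m <- train_surrogate(ds, "ns", n_hidden = 4,
#'                      control = ann_control(max_epochs = 50), seed = 1)
#' glance(m)
train_surrogate <- function(data, trait, inputs = hormone_cols(),
                            n_hidden = 10, control = ann_control(),
                            seed = 1) {
  trait <- match_trait(trait)
  stopifnot(n_hidden >= 1, inherits(control, "ann_control"))
  train <- if (".split" %in% names(data)) {
    filter(data, .data$.split == "train")
  } else data
  if (nrow(train) == 0) abort("training split is empty")
  missing <- setdiff(c(inputs, trait), names(train))
  if (length(missing) > 0) {
    abort(sprintf("data lacks column(s): %s", paste(missing, collapse = ", ")))
  }

  norm <- fit_normalizer(train, cols = c(inputs, trait))
  Xall <- normalize_matrix(train, norm, inputs)
  yall <- normalize_values(train[[trait]], norm, trait)
  if (norm$degenerate[norm$variable == trait]) {
    abort(sprintf("trait '%s' is constant on the training split", trait))
  }

  P <- n_params(length(inputs), n_hidden)
  n_val <- round(control$val_fraction * nrow(Xall))
  use_val <- n_val >= 1 && n_val < nrow(Xall)
  init <- withr::with_seed(seed, {
    list(theta = runif(P, -0.5, 0.5),
         val_idx = if (use_val) sample.int(nrow(Xall), n_val) else integer(0))
  })
  theta <- init$theta
  if (use_val) {
    Xv <- Xall[init$val_idx, , drop = FALSE]
    yv <- yall[init$val_idx]
    X <- Xall[-init$val_idx, , drop = FALSE]
    y <- yall[-init$val_idx]
  } else {
    X <- Xall
    y <- yall
  }

  mse_on <- function(theta, Xm, ym) {
    w <- unpack_params(theta, length(inputs), n_hidden)
    mean((ym - forward_matrix(w$W1, w$b1, w$w2, w$b2, Xm))^2)
  }
  mse_of <- function(theta) mse_on(theta, X, y)

  lambda <- control$lambda0
  mse <- mse_of(theta)
  val_mse <- if (use_val) mse_on(theta, Xv, yv) else NA_real_
  best_val <- val_mse
  best_theta <- theta
  n_fail <- 0L
  history <- vector("list", control$max_epochs)
  aborted <- FALSE
  epoch <- 0L
  while (epoch < control$max_epochs && mse > control$mse_goal) {
    w <- unpack_params(theta, length(inputs), n_hidden)
    r <- y - forward_matrix(w$W1, w$b1, w$w2, w$b2, X)
    J <- forward_jacobian(w$W1, w$b1, w$w2, w$b2, X)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    while (!accepted && lambda <= control$lambda_max) {
      step <- tryCatch(
        solve(JtJ + diag(lambda, P), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- theta + drop(step)
        cand_mse <- mse_of(cand)
        if (is.finite(cand_mse) && cand_mse < mse) {
          theta <- cand
          mse <- cand_mse
          lambda <- lambda / control$lambda_dec
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * control$lambda_inc
    }
    if (!accepted) {
      aborted <- TRUE
      break
    }
    epoch <- epoch + 1L
    if (use_val) {
      val_mse <- mse_on(theta, Xv, yv)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_theta <- theta
        n_fail <- 0L
      } else {
        n_fail <- n_fail + 1L
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, mse = mse, val_mse = val_mse,
                               lambda = lambda)
    if (use_val && n_fail >= control$max_fail) break
  }
  history <- bind_rows(history[seq_len(epoch)])
  if (use_val) {
    theta <- best_theta
    mse <- mse_of(theta)
  }

  w <- unpack_params(theta, length(inputs), n_hidden)
  structure(list(
    trait = trait, inputs = inputs, n_hidden = n_hidden,
    W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
    normalization = norm, control = control, seed = seed,
    history = history, n_epochs = epoch, final_mse = mse,
    converged = mse <= control$mse_goal, aborted = aborted,
    n_train = nrow(train)
  ), class = "ann_surrogate")
}

#' Predict a trait from hormone concentrations
#'
#' Normalize-forward-denormalize composition: deterministic, defined on any
#' finite point (extrapolation beyond the training box is allowed and
#' follows the same linear normalization).
#'
#' @param object An `ann_surrogate`.
#' @param newdata Data frame containing the model's input columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the trait's raw scale.
#' @export
predict.ann_surrogate <- function(object, newdata, ...) {
  missing <- setdiff(object$inputs, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata lacks input column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  X <- normalize_matrix(newdata, object$normalization, object$inputs)
  denormalize_values(forward(object, X), object$normalization, object$trait)
}

#' @export
print.ann_surrogate <- function(x, ...) {
  cat(sprintf(
    "<ann_surrogate> trait=%s inputs=%s hidden=%d epochs=%d train MSE=%.4g%s\n",
    x$trait, paste(x$inputs, collapse = ","), x$n_hidden, x$n_epochs,
    x$final_mse,
    if (x$converged) " (goal reached)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ann_surrogate <- function(x, ...) {
  bind_rows(
    tibble(term = sprintf("W1[%d,%d]",
                          rep(seq_len(x$n_hidden), length(x$inputs)),
                          rep(seq_along(x$inputs), each = x$n_hidden)),
           estimate = as.vector(x$W1)),
    tibble(term = sprintf("b1[%d]", seq_len(x$n_hidden)), estimate = x$b1),
    tibble(term = sprintf("w2[%d]", seq_len(x$n_hidden)), estimate = x$w2),
    tibble(term = "b2", estimate = x$b2)
  )
}

#' @exportS3Method generics::glance
glance.ann_surrogate <- function(x, ...) {
  tibble(trait = x$trait, n_inputs = length(x$inputs), n_hidden = x$n_hidden,
         n_train = x$n_train, n_epochs = x$n_epochs, final_mse = x$final_mse,
         converged = x$converged, aborted = x$aborted, seed = x$seed)
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a surrogate as JSON
#'
#' Writes weights, biases, normalization spec, control settings and seed to
#' a versioned JSON document; `read_surrogate()` restores an equivalent
#' model (identical predictions).
#'
#' @param model An `ann_surrogate`.
#' @param path JSON file path.
#' @return `path` (write) or an `ann_surrogate` (read).
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "ann_surrogate"))
  doc <- list(
    schema = "hormonet/ann_surrogate/1",
    trait = model$trait, inputs = model$inputs, n_hidden = model$n_hidden,
    W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    normalization = as.data.frame(model$normalization),
    control = unclass(model$control), seed = model$seed,
    n_epochs = model$n_epochs, final_mse = model$final_mse,
    converged = model$converged, aborted = model$aborted,
    n_train = model$n_train
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "hormonet/ann_surrogate/1")) {
    abort(sprintf("unrecognized surrogate schema '%s'", doc$schema))
  }
  norm <- as_tibble(doc$normalization)
  structure(list(
    trait = doc$trait, inputs = doc$inputs, n_hidden = doc$n_hidden,
    W1 = matrix(doc$W1, nrow = doc$n_hidden), b1 = doc$b1,
    w2 = doc$w2, b2 = doc$b2,
    normalization = structure(norm, class = c("normalizer", class(norm))),
    control = do.call(ann_control, doc$control), seed = doc$seed,
    history = NULL, n_epochs = doc$n_epochs, final_mse = doc$final_mse,
    converged = doc$converged, aborted = doc$aborted, n_train = doc$n_train
  ), class = "ann_surrogate")
}
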