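#' Rank hormone importance by variable sensitivity error/ratio
#'
#' For each input hormone, the variable sensitivity error (VSE) is the
#' model's test-set RMSE when that variable is unavailable, and the
#' variable sensitivity ratio VSR = VSE / (test RMSE of the full model).
#' A higher VSR means removing the hormone hurts more, i.e. the hormone
#' matters more; inputs are ranked 1 (most important) by descending VSR,
#' ties broken alphabetically.
#'
#' "Unavailable" is implemented by retraining the network without the
#' column (default), or, with `method = "mean_substitute"`, by fixing the
#' column at its training mean in the full model (cheaper, no refit).
#' Because a single fit depends noticeably on its weight initialization,
#' both the baseline and each VSE are averaged over `n_restarts` seeded
#' restarts; test rows are never used during any refit.
#'
#' @param data Replicate tibble with a `.split` column.
#' @param trait Output trait.
#' @param inputs Candidate input columns (default the five hormones).
#' @param n_hidden,control,seed Passed to [train_surrogate()]; restart `i`
#'   uses `seed + i - 1`.
#' @param n_restarts Number of seeded restarts averaged (>= 1, default 5).
#' @param method `"retrain"` (default) or `"mean_substitute"`.
#' @return A `sensitivity_report`: tibble of per-hormone `vse`, `vsr`,
#'   `rank` plus attributes (`trait`, `baseline_error`, `n_restarts`,
#'   `seed`, `method`), with [tidy()] and [glance()] methods.
#' @export
variable_sensitivity <- function(data, trait, inputs = hormone_cols(),
                                 n_hidden = 10, control = ann_control(),
                                 n_restarts = 5, seed = 1,
                                 method = c("retrain", "mean_substitute")) {
  method <- match.arg(method)
  trait <- match_trait(trait)
  stopifnot(n_restarts >= 1)
  if (!".split" %in% names(data)) abort("data needs a .split column")
  test <- filter(data, .data$.split == "test")
  if (nrow(test) < 2) abort("test split too small for sensitivity analysis")
  if (min(data[[trait]]) == max(data[[trait]])) {
    abort(sprintf("trait '%s' is constant; sensitivity undefined", trait))
  }

  seeds <- seed + seq_len(n_restarts) - 1
  test_rmse <- function(model, rows = test) {
    rmse(rows[[model$trait]], predict(model, rows))
  }

  per_seed <- purrr::map(seeds, function(s) {
    full <- train_surrogate(data, trait, inputs = inputs,
                            n_hidden = n_hidden, control = control, seed = s)
    base <- test_rmse(full)
    vse <- vapply(inputs, function(h) {
      if (method == "retrain") {
        drop_fit <- train_surrogate(data, trait, inputs = setdiff(inputs, h),
                                    n_hidden = n_hidden, control = control,
                                    seed = s)
        test_rmse(drop_fit)
      } else {
        train <- filter(data, .data$.split == "train")
        subbed <- test
        subbed[[h]] <- mean(train[[h]])
        test_rmse(full, subbed)
      }
    }, numeric(1))
    list(base = base, vse = vse)
  })

  baseline <- mean(purrr::map_dbl(per_seed, "base"))
  vse <- colMeans(do.call(rbind, purrr::map(per_seed, "vse")))
  tab <- tibble(hormone = inputs, vse = unname(vse),
                vsr = unname(vse) / baseline)
  tab <- arrange(tab, dplyr::desc(.data$vsr), .data$hormone)
  tab$rank <- seq_len(nrow(tab))
  tab <- arrange(tab, match(.data$hormone, inputs))

  structure(tab, class = c("sensitivity_report", class(tab)),
            trait = trait, baseline_error = baseline,
            n_restarts = n_restarts, seed = seed, method = method)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> trait=%s baseline RMSE=%.4g (%d restarts, %s)\n",
              attr(x, "trait"), attr(x, "baseline_error"),
              attr(x, "n_restarts"), attr(x, "method")))
  print(as_tibble(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sensitivity_report <- function(x, ...) {
  mutate(as_tibble(x), trait = attr(x, "trait"),
         baseline_error = attr(x, "baseline_error"))
}

#' @exportS3Method generics::glance
glance.sensitivity_report <- function(x, ...) {
  tibble(trait = attr(x, "trait"),
         baseline_error = attr(x, "baseline_error"),
         n_inputs = nrow(x), n_restarts = attr(x, "n_restarts"),
         seed = attr(x, "seed"), method = attr(x, "method"))
}
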