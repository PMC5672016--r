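#' Coefficient of determination (squared product-moment correlation)
#'
#' Computed from the product-moment formula
#' `R2 = (n*sum(xy) - sum(x)*sum(y))^2 / ((n*sum(x^2) - sum(x)^2) *
#' (n*sum(y^2) - sum(y)^2))`, i.e. the squared Pearson correlation between
#' observed and predicted values. It is invariant under affine rescaling of
#' either argument, so it takes the same value on the raw and normalized
#' scales, and it equals 1 when predicted = -observed (the sign cancels in
#' the square); it is not `1 - SSres/SStot`.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2, neither
#'   constant.
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' r_squared(1:4, c(1.1, 1.9, 3.2, 3.8))
r_squared <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2)
  if (min(observed) == max(observed)) abort("observed vector is constant")
  if (min(predicted) == max(predicted)) abort("predicted vector is constant")
  n <- length(observed)
  num <- n * sum(observed * predicted) - sum(observed) * sum(predicted)
  den <- (n * sum(observed^2) - sum(observed)^2) *
    (n * sum(predicted^2) - sum(predicted)^2)
  num^2 / den
}

#' Root mean square error
#'
#' `sqrt(sum((predicted - observed)^2) / n)`, in the trait's units.
#'
#' @inheritParams r_squared
#' @return A non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 1)
  sqrt(mean((predicted - observed)^2))
}

#' Two-sided paired t-test p-value on observed - predicted
#'
#' The model-adequacy check reported alongside R2 and RMSE: a paired t-test
#' of the null that observed and predicted values share a mean.
#'
#' @inheritParams r_squared
#' @return A p-value in \[0, 1\].
#' @export
paired_t_pvalue <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2)
  d <- observed - predicted
  if (stats::sd(d) == 0) {
    abort("differences have zero variance; paired t-test is undefined")
  }
  t.test(observed, predicted, paired = TRUE)$p.value
}

check_pair <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted)) {
    abort(sprintf("length mismatch: %d observed vs %d predicted",
                  length(observed), length(predicted)))
  }
  if (length(observed) < min_n) {
    abort(sprintf("need at least %d value pair(s)", min_n))
  }
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    abort("inputs must be finite")
  }
  invisible(TRUE)
}

#' Evaluate a surrogate on both data splits
#'
#' Computes R2, RMSE and the paired t statistic/p-value on the raw
#' (denormalized) trait scale for the training and testing rows.
#'
#' @param model An `ann_surrogate`.
#' @param data Replicate tibble with a `.split` column (rows without one
#'   are evaluated as a single `"train"` split).
#' @return A tibble with one row per split: `trait`, `split`, `n`,
#'   `r_squared`, `rmse`, `t_stat`, `t_p_value`.
#' @export
evaluate_surrogate <- function(model, data) {
  stopifnot(inherits(model, "ann_surrogate"))
  if (!".split" %in% names(data)) data$.split <- factor("train", levels = "train")
  purrr::map_dfr(levels(droplevels(data$.split)), function(sp) {
    rows <- filter(data, .data$.split == sp)
    obs <- rows[[model$trait]]
    pred <- predict(model, rows)
    tt <- t.test(obs, pred, paired = TRUE)
    tibble(trait = model$trait, split = sp, n = nrow(rows),
           r_squared = r_squared(obs, pred), rmse = rmse(obs, pred),
           t_stat = unname(tt$statistic), t_p_value = tt$p.value)
  })
}
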