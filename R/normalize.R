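#' Fit a min-max normalizer to [-1, 1]
#'
#' Linear per-variable map sending the observed minimum to -1 and maximum
#' to +1, as used to condition both the hormone inputs and the trait output
#' before network training. A constant (degenerate) variable maps to 0 and
#' is flagged.
#'
#' @param data A data frame of numeric variables.
#' @param cols Columns to fit; defaults to all columns of `data`.
#' @return A `normalizer` object: a tibble with `variable`, `min`, `max`,
#'   `degenerate`.
#' @export
fit_normalizer <- function(data, cols = names(data)) {
  if (nrow(data) == 0) abort("fit_normalizer() needs at least one row")
  spec <- purrr::map_dfr(cols, function(cl) {
    x <- data[[cl]]
    if (!is.numeric(x)) abort(sprintf("column '%s' is not numeric", cl))
    tibble(variable = cl, min = min(x), max = max(x),
           degenerate = min(x) == max(x))
  })
  structure(spec, class = c("normalizer", class(spec)))
}

norm_row <- function(spec, variable) {
  i <- match(variable, spec$variable)
  if (is.na(i)) abort(sprintf("no normalization fitted for '%s'", variable))
  spec[i, ]
}

#' Apply / invert a fitted normalizer
#'
#' `normalize_values()` maps raw values of one variable onto the \[-1, 1\]
#' training scale; `denormalize_values()` inverts it. Values outside the
#' fitted range are mapped by the same linear rule (they may exceed ±1);
#' a degenerate variable normalizes to 0 and denormalizes to its constant.
#'
#' @param x Numeric vector.
#' @param spec A `normalizer` from [fit_normalizer()].
#' @param variable Variable name within `spec`.
#' @return Numeric vector of the same length.
#' @export
normalize_values <- function(x, spec, variable) {
  r <- norm_row(spec, variable)
  if (r$degenerate) return(rep(0, length(x)))
  2 * (x - r$min) / (r$max - r$min) - 1
}

#' @rdname normalize_values
#' @export
denormalize_values <- function(x, spec, variable) {
  r <- norm_row(spec, variable)
  if (r$degenerate) return(rep(r$min, length(x)))
  (x + 1) / 2 * (r$max - r$min) + r$min
}

normalize_matrix <- function(data, spec, cols) {
  out <- vapply(cols, function(cl) normalize_values(data[[cl]], spec, cl),
                numeric(nrow(data)))
  matrix(out, nrow = nrow(data), dimnames = list(NULL, cols))
}
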