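#' Observed vs predicted diagnostic plot for a surrogate
#'
#' Scatter of observed against predicted trait values, faceted by data
#' split, with the identity line; the standard adequacy plot for the
#' trained networks.
#'
#' @param object An `ann_surrogate`.
#' @param data Replicate tibble (with `.split` column) to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ann_surrogate <- function(object, data, ...) {
  d <- tibble(
    observed = data[[object$trait]],
    predicted = predict(object, data),
    split = if (".split" %in% names(data)) data$.split else "train"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(
      title = sprintf("Surrogate fit for %s", toupper(object$trait)),
      x = "observed", y = "predicted"
    )
}

#' Fitness-history plot for a genetic search
#'
#' Per-generation best and mean response together with the best-so-far
#' envelope (monotone when elitism is on).
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ga_result <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean", "best_so_far"),
                           names_to = "series", values_to = "response")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$response,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("GA search over %s (%s)",
                      paste(object$active, collapse = " + "), object$sense),
      x = "generation", y = "predicted response"
    )
}

#' Importance-ranking plot for a sensitivity report
#'
#' Bar chart of the variable sensitivity ratio per hormone; the dashed
#' line at VSR = 1 marks "no worse than the full model".
#'
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_report <- function(object, ...) {
  d <- mutate(as_tibble(object),
              hormone = stats::reorder(toupper(.data$hormone), .data$vsr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hormone, y = .data$vsr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("Hormone importance for %s", toupper(attr(object, "trait"))),
      x = NULL, y = "variable sensitivity ratio (VSR)"
    )
}
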