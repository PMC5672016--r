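#' Genetic-algorithm control settings
#'
#' Defaults follow the published search protocol: 50 individuals, 500
#' generations, per-gene mutation rate 0.1, crossover rate 0.85, roulette
#' wheel selection, one elite carried over unchanged.
#'
#' @param population_size Number of individuals (>= 2).
#' @param generations Number of generational cycles.
#' @param mutation_rate Per-gene probability of a uniform-reset mutation.
#' @param crossover_rate Per-pair probability of blend crossover.
#' @param elitism Number of best individuals copied unchanged (>= 0,
#'   < `population_size`).
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(population_size = 50, generations = 500,
                       mutation_rate = 0.1, crossover_rate = 0.85,
                       elitism = 1) {
  stopifnot(population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elitism >= 0, elitism < population_size)
  structure(list(population_size = population_size, generations = generations,
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elitism = elitism),
            class = "ga_control")
}

#' Roulette-wheel (fitness-proportional) selection
#'
#' Samples `k` indices with replacement, each with probability proportional
#' to the shifted fitness `f - min(f) + eps`; the shift keeps the wheel
#' defined for negative fitness, and an all-equal fitness vector yields
#' uniform sampling. Consumes the current RNG stream (seed it with
#' [withr::with_seed()] or `set.seed()` for reproducibility).
#'
#' @param fitness Finite numeric vector (larger = fitter).
#' @param k Number of draws.
#' @param eps Positive wheel shift; default `1e-9 * (max - min + 1)`.
#' @return Integer vector of `k` selected indices.
#' @export
#' @examples
#' withr::with_seed(1, roulette_select(c(5, 1, 0), 10))
roulette_select <- function(fitness, k,
                            eps = 1e-9 * (max(fitness) - min(fitness) + 1)) {
  if (!all(is.finite(fitness))) abort("fitness values must be finite")
  stopifnot(k >= 1, eps > 0)
  w <- fitness - min(fitness) + eps
  sample.int(length(fitness), k, replace = TRUE, prob = w)
}

#' Optimize a predictor over bounded hormone space with a real-coded GA
#'
#' Generational loop: evaluate fitness, carry over the elite, draw parents
#' by roulette-wheel selection, apply per-gene blend (arithmetic) crossover
#' at the crossover rate, mutate genes by uniform reset within their
#' bounds, and clip to bounds. Only the hormones in `active` vary; all
#' others are pinned to 0, restricting the search to one cytokinin-auxin
#' subspace. For `sense = "minimize"` (used for callus weight) the fitness
#' is negated internally.
#'
#' @param predictor An `ann_surrogate`, or a function mapping a hormone
#'   tibble (five columns, mg/l) to a numeric response vector.
#' @param active Character vector of hormones allowed to vary (non-empty
#'   subset of [hormone_cols()]).
#' @param bounds Tibble with `hormone`, `low`, `high` columns; defaults to
#'   the factorial design limits ([hormone_bounds()]).
#' @param sense `"maximize"` (default) or `"minimize"`.
#' @param control A [ga_control()] list.
#' @param seed Integer seed; same seed, same trajectory.
#' @return A `ga_result`: best point, best predicted response, and a
#'   per-generation history tibble (`generation`, `best`, `mean`,
#'   `best_so_far`, on the response scale).
#' @export
#' @examples
#' peak <- function(d) -(d$bap - 1)^2
#' ga_optimize(peak, active = "bap",
#'             control = ga_control(generations = 60), seed = 1)
ga_optimize <- function(predictor, active, bounds = hormone_bounds(),
                        sense = c("maximize", "minimize"),
                        control = ga_control(), seed = 1) {
  sense <- match.arg(sense)
  stopifnot(inherits(control, "ga_control"))
  if (length(active) == 0) abort("active hormone set must be non-empty")
  if (!all(active %in% hormone_cols())) {
    abort(sprintf("unknown hormone(s): %s",
                  paste(setdiff(active, hormone_cols()), collapse = ", ")))
  }
  if (!all(bounds$low <= bounds$high)) abort("bounds must satisfy low <= high")
  fn <- if (inherits(predictor, "ann_surrogate")) {
    function(d) predict(predictor, d)
  } else {
    predictor
  }
  lo <- bounds$low[match(active, bounds$hormone)]
  hi <- bounds$high[match(active, bounds$hormone)]
  if (anyNA(lo) || anyNA(hi)) abort("bounds must cover every active hormone")
  sgn <- if (sense == "maximize") 1 else -1
  np <- control$population_size
  ng <- length(active)

  as_points <- function(pop) {
    d <- tibble(.rows = nrow(pop))
    for (h in hormone_cols()) d[[h]] <- 0
    for (j in seq_along(active)) d[[active[j]]] <- pop[, j]
    d
  }

  withr::with_seed(seed, {
    pop <- matrix(runif(np * ng, rep(lo, each = np), rep(hi, each = np)),
                  nrow = np)
    best_theta <- NULL
    best_fit <- -Inf
    history <- vector("list", control$generations)
    for (gen in seq_len(control$generations)) {
      resp <- fn(as_points(pop))
      fit <- sgn * resp
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best_theta <- pop[gi, ]
      }
      history[[gen]] <- tibble(generation = gen,
                               best = sgn * max(fit),
                               mean = sgn * mean(fit),
                               best_so_far = sgn * best_fit)

      nxt <- matrix(0, np, ng)
      n_elite <- control$elitism
      if (n_elite > 0) {
        nxt[seq_len(n_elite), ] <- pop[order(fit, decreasing = TRUE)[seq_len(n_elite)], , drop = FALSE]
      }
      n_off <- np - n_elite
      parents <- roulette_select(fit, 2 * n_off)
      p1 <- pop[parents[seq_len(n_off)], , drop = FALSE]
      p2 <- pop[parents[n_off + seq_len(n_off)], , drop = FALSE]
      cross <- runif(n_off) < control$crossover_rate
      u <- matrix(runif(n_off * ng), n_off, ng)
      child <- ifelse(matrix(cross, n_off, ng), u * p1 + (1 - u) * p2, p1)
      mut <- matrix(runif(n_off * ng) < control$mutation_rate, n_off, ng)
      reset <- matrix(runif(n_off * ng, rep(lo, each = n_off),
                            rep(hi, each = n_off)), n_off, ng)
      child[mut] <- reset[mut]
      child <- pmin(pmax(child, rep(lo, each = n_off)), rep(hi, each = n_off))
      nxt[n_elite + seq_len(n_off), ] <- child
      pop <- nxt
    }
  })

  best_point <- as_points(matrix(best_theta, nrow = 1))
  structure(list(
    best_point = best_point,
    best_predicted = sgn * best_fit,
    history = bind_rows(history),
    active = active, bounds = bounds, sense = sense,
    control = control, seed = seed
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  pt <- paste(sprintf("%s=%.3g", x$active,
                      unlist(x$best_point[1, x$active])), collapse = ", ")
  cat(sprintf("<ga_result> %s %s -> %.4g at %s (%d generations)\n",
              x$sense, paste(x$active, collapse = "+"),
              x$best_predicted, pt, nrow(x$history)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ga_result <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.ga_result <- function(x, ...) {
  dplyr::bind_cols(
    x$best_point,
    tibble(best_predicted = x$best_predicted, sense = x$sense,
           generations = nrow(x$history), seed = x$seed)
  )
}

#' Dense grid search over a predictor (reference optimizer)
#'
#' Exhaustive evaluation on a regular grid over the active hormones,
#' used as the deterministic cross-check for the genetic search.
#'
#' @inheritParams ga_optimize
#' @param step Grid spacing as a fraction of each gene's range.
#' @return A one-row tibble: the grid-optimal hormone point and `value`.
#' @export
grid_optimize <- function(predictor, active, bounds = hormone_bounds(),
                          sense = c("maximize", "minimize"), step = 0.001) {
  sense <- match.arg(sense)
  fn <- if (inherits(predictor, "ann_surrogate")) {
    function(d) predict(predictor, d)
  } else predictor
  lo <- bounds$low[match(active, bounds$hormone)]
  hi <- bounds$high[match(active, bounds$hormone)]
  axes <- purrr::map2(lo, hi, function(l, h) {
    if (h == l) l else seq(l, h, by = (h - l) * step)
  })
  names(axes) <- active
  grid <- tidyr::expand_grid(!!!axes)
  d <- tibble(.rows = nrow(grid))
  for (h in hormone_cols()) d[[h]] <- 0
  for (a in active) d[[a]] <- grid[[a]]
  v <- fn(d)
  i <- if (sense == "maximize") which.max(v) else which.min(v)
  mutate(d[i, ], value = v[i])
}
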