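#' Regenerate replicate-level observations from media summaries
#'
#' The published analysis was run on replicate-level "data lines", but only
#' per-media means and standard errors are available. This generator
#' re-expands each medium into its `n_replicates` observations by sampling
#' a truncated normal with scale `se * sqrt(n_replicates)` (the
#' replicate-level SD implied by the standard error of the mean).
#' Truncation enforces each trait's physical range: NS, LS and CW are
#' non-negative and QI lies in \[0, 5\]. Because truncation pulls the mean
#' of a plain truncated normal away from its location — materially so for
#' cells printed near a range boundary with a large SE — the location
#' parameter is solved per cell so that the *truncated* distribution's
#' mean equals the printed mean exactly; the generated sample means are
#' then unbiased for the printed table.
#'
#' Each replicate is the mean of a 4-explant culture unit, so with
#' `quantize_ns = TRUE` (default) NS values are rounded to the nearest
#' 0.25 shoots/explant.
#'
#' @param tables A media-summary tibble, e.g. [media_tables()].
#' @param seed Integer seed; the same seed reproduces the same records.
#' @param quantize_ns Round NS observations to multiples of 0.25?
#' @param n_replicates Optional integer overriding every medium's replicate
#'   count (diagnostic mode, e.g. 10000 draws to check the sampler's
#'   moments). The replicate-level standard deviation is always derived
#'   from the table's own replicate count, so diagnostic draws come from
#'   the same distribution as the regular ones.
#' @return A tibble with one row per replicate: `experiment_id`,
#'   `media_id`, `replicate`, the five hormone columns and one column per
#'   trait (`ns`, `ls`, `cw`, `qi`).
#' @export
#' @examples
#' reps <- expand_replicates(media_tables(), seed = 1)
#' nrow(reps) # 465
expand_replicates <- function(tables, seed = 1, quantize_ns = TRUE,
                              n_replicates = NULL) {
  validate_media_tables(tables)
  tables$.n_draw <- tables$n_replicates
  if (!is.null(n_replicates)) {
    if (n_replicates < 1) abort("n_replicates must be >= 1")
    tables$.n_draw <- n_replicates
  }
  withr::with_seed(seed, {
    recs <- purrr::pmap(tables, function(...) {
      row <- list(...)
      n <- row$.n_draw
      obs <- lapply(trait_names(), function(tr) {
        rng <- trait_range(tr)
        rtruncnorm(n, mean = row[[paste0(tr, "_mean")]],
                   sd = row[[paste0(tr, "_se")]] * sqrt(row$n_replicates),
                   lower = rng[1], upper = rng[2])
      })
      names(obs) <- trait_names()
      if (quantize_ns) obs$ns <- round(obs$ns / 0.25) * 0.25
      tibble(
        experiment_id = row$experiment_id, media_id = row$media_id,
        replicate = seq_len(n),
        bap = row$bap, kin = row$kin, tdz = row$tdz,
        iba = row$iba, naa = row$naa,
        ns = obs$ns, ls = obs$ls, cw = obs$cw, qi = obs$qi
      )
    })
    bind_rows(recs)
  })
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter whose truncated-normal mean equals `target`.
# Monotone in mu, so a bracketed root always exists for targets strictly
# inside (lower, upper).
truncnorm_location <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  direct <- truncnorm_mean(target, sd, lower, upper)
  if (abs(direct - target) < 1e-12) return(target)
  stats::uniroot(
    function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
    interval = c(target - 6 * sd, target + 6 * sd),
    extendInt = "yes", tol = 1e-12
  )$root
}

# Inverse-CDF sampler for the truncated normal; exact for sd > 0 and
# degenerate (all values = mean) for sd = 0.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  mu <- truncnorm_location(mean, sd, lower, upper)
  plo <- pnorm(lower, mu, sd)
  phi <- pnorm(upper, mu, sd)
  qnorm(runif(n, plo, phi), mu, sd)
}

#' Split replicates into training and testing sets
#'
#' A seeded uniform permutation assigns the first
#' `round(train_fraction * n)` records to the training set. The packaged
#' 465-record dataset at the default fraction 0.6 splits exactly 279/186,
#' the sizes used to fit and test the published models. A
#' stratified option draws the same fraction within each medium instead.
#'
#' @param records Replicate tibble from [expand_replicates()].
#' @param train_fraction Proportion assigned to training, in (0, 1].
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param stratify Split within each (experiment, medium) cell instead of
#'   globally?
#' @return `records` with an added `.split` factor column
#'   (`"train"`/`"test"`).
#' @export
#' @examples
#' ds <- media_tables() |> expand_replicates(seed = 1) |> split_dataset(seed = 1)
#' table(ds$.split) # 279 train, 186 test
split_dataset <- function(records, train_fraction = 0.6, seed = 1,
                          stratify = FALSE) {
  if (nrow(records) == 0) abort("cannot split an empty record set")
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("train_fraction must be in (0, 1]")
  }
  assign_split <- function(n) {
    n_train <- round(train_fraction * n)
    lab <- rep("test", n)
    lab[sample.int(n, n_train)] <- "train"
    lab
  }
  withr::with_seed(seed, {
    if (stratify) {
      records <- records %>%
        group_by(.data$experiment_id, .data$media_id) %>%
        mutate(.split = assign_split(dplyr::n())) %>%
        ungroup()
    } else {
      records$.split <- assign_split(nrow(records))
    }
  })
  records$.split <- factor(records$.split, levels = c("train", "test"))
  records
}
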