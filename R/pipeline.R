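#' Run the full surrogate-modelling and optimization pipeline
#'
#' End-to-end analysis: load the factorial tables, regenerate replicate
#' observations, split train/test, train one surrogate per trait (best of
#' `n_restarts` seeded fits by test R2), evaluate fit statistics, rank
#' hormone importance, and run the genetic search over each cytokinin-auxin
#' subspace for each trait. Callus weight is minimized; the other traits
#' are maximized. Reported predicted responses at the optima are clamped to
#' each trait's physical scale (counts and weights >= 0, quality index in
#' \[0, 5\]); raw `predict()` output is not.
#'
#' Fully deterministic for a given `seed`. With `out_dir` set, writes
#' `fit_stats.csv`, `optima.csv`, `sensitivity.csv`, `best_observed.csv`
#' and `manifest.json`; on any stage failure partial outputs are removed.
#'
#' @param tables Media-summary tibble (default: all builtin tables).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param traits Traits to model (default all four).
#' @param subspaces Named list of hormone pairs to optimize over
#'   (default [default_subspaces()]).
#' @param train_fraction Train proportion for the split (default 0.6).
#' @param n_hidden Hidden units per surrogate.
#' @param control [ann_control()] settings shared by all fits.
#' @param ga [ga_control()] settings shared by all searches.
#' @param n_restarts Seeded restarts for model selection and sensitivity.
#' @param quantize_ns Passed to [expand_replicates()].
#' @param out_dir Optional output directory.
#' @return A list with elements `fit_stats`, `optima`, `sensitivity`,
#'   `best_observed`, `models`, `dataset` and `manifest`.
#' @export
run_pipeline <- function(tables = media_tables(), seed = 1,
                         traits = trait_names(),
                         subspaces = default_subspaces(),
                         train_fraction = 0.6, n_hidden = 10,
                         control = ann_control(), ga = ga_control(),
                         n_restarts = 3, quantize_ns = TRUE,
                         out_dir = NULL) {
  traits <- vapply(traits, match_trait, "")
  written <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(stage, e) {
    unlink(written)
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }

  message(sprintf("[simulate] expanding %d media into replicates (seed %d)",
                  nrow(tables), seed))
  dataset <- stage("simulate", {
    tables %>%
      expand_replicates(seed = seed, quantize_ns = quantize_ns) %>%
      split_dataset(train_fraction = train_fraction, seed = seed + 1)
  })

  models <- list()
  fit_stats <- list()
  for (tr in traits) {
    models[[tr]] <- stage("train", {
      fits <- purrr::map(seed + seq_len(n_restarts) - 1, function(s) {
        train_surrogate(dataset, tr, n_hidden = n_hidden,
                        control = control, seed = s)
      })
      r2 <- purrr::map_dbl(fits, function(m) {
        ev <- evaluate_surrogate(m, dataset)
        ev$r_squared[ev$split == "test"]
      })
      message(sprintf("[train] %s: best test R2 = %.3f over %d seeds",
                      tr, max(r2), n_restarts))
      fits[[which.max(r2)]]
    })
    fit_stats[[tr]] <- stage("evaluate", evaluate_surrogate(models[[tr]], dataset))
  }
  fit_stats <- bind_rows(fit_stats)

  sens <- stage("sensitivity", {
    purrr::map_dfr(traits, function(tr) {
      message(sprintf("[sensitivity] ranking hormones for %s", tr))
      tidy(variable_sensitivity(dataset, tr, n_hidden = n_hidden,
                                control = control, n_restarts = n_restarts,
                                seed = seed))
    })
  })

  optima <- stage("optimize", {
    purrr::map_dfr(traits, function(tr) {
      sense <- if (tr == "cw") "minimize" else "maximize"
      purrr::imap_dfr(subspaces, function(active, nm) {
        res <- ga_optimize(models[[tr]], active = active, sense = sense,
                           control = ga, seed = seed + 100)
        rng <- trait_range(tr)
        obs <- best_medium(filter_subspace(tables, active), tr,
                           direction = if (sense == "minimize") "min" else "max")
        message(sprintf("[optimize] %s over %s: predicted %.3f", tr, nm,
                        res$best_predicted))
        dplyr::bind_cols(
          tibble(trait = tr, subspace = nm, sense = sense),
          res$best_point,
          tibble(predicted = pmin(pmax(res$best_predicted, rng[1]), rng[2]),
                 observed_best = obs$value,
                 observed_experiment = obs$experiment_id,
                 observed_media = obs$media_id)
        )
      })
    })
  })

  best_obs <- purrr::map_dfr(traits, function(tr) {
    best_medium(tables, tr, direction = if (tr == "cw") "min" else "max")
  })

  manifest <- list(
    seed = seed, train_fraction = train_fraction, n_hidden = n_hidden,
    n_restarts = n_restarts, quantize_ns = quantize_ns,
    traits = traits, subspaces = subspaces,
    control = unclass(control), ga = unclass(ga),
    n_records = nrow(dataset),
    n_train = sum(dataset$.split == "train"),
    n_test = sum(dataset$.split == "test"),
    package_version = as.character(utils::packageVersion("hormonet"))
  )

  if (!is.null(out_dir)) {
    stage("write", {
      paths <- file.path(out_dir, c("fit_stats.csv", "optima.csv",
                                    "sensitivity.csv", "best_observed.csv",
                                    "manifest.json"))
      written <<- paths
      readr::write_csv(fit_stats, paths[1])
      readr::write_csv(optima, paths[2])
      readr::write_csv(sens, paths[3])
      readr::write_csv(best_obs, paths[4])
      jsonlite::write_json(manifest, paths[5], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
  }

  list(fit_stats = fit_stats, optima = optima, sensitivity = sens,
       best_observed = best_obs, models = models, dataset = dataset,
       manifest = manifest)
}

# Media whose nonzero hormones are within the given subspace.
filter_subspace <- function(tables, active) {
  inactive <- setdiff(hormone_cols(), active)
  keep <- rowSums(as.matrix(tables[, inactive, drop = FALSE]) != 0) == 0
  out <- tables[keep, , drop = FALSE]
  if (nrow(out) == 0) tables else out
}
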