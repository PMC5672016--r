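#' Published factorial dose-response tables
#'
#' Loads the five media-level factorial tables shipped with the package:
#' 20 BAP x IBA media, 20 BAP x NAA media, 15 KIN x IBA, 15 KIN x NAA and
#' 15 TDZ x IBA media (85 in total), each with the per-trait mean, standard
#' error and replicate count (6 replicates for experiments 1-2, 5 for 3-5).
#'
#' @param experiment Optional integer vector restricting to one or more of
#'   experiments 1-5.
#' @return A tibble of media summaries with columns
#'   `experiment_id`, `media_id`, the five hormone columns (mg/l),
#'   `<trait>_mean`, `<trait>_se` for each trait and `n_replicates`.
#' @export
#' @examples
#' media_tables()
#' media_tables(experiment = 1)
media_tables <- function(experiment = NULL) {
  path <- system.file("extdata", "media_tables.csv", package = "hormonet",
                      mustWork = TRUE)
  tab <- read_media_tables(path)
  if (!is.null(experiment)) {
    tab <- filter(tab, .data$experiment_id %in% .env$experiment)
  }
  tab
}

#' Wet-lab validation experiment
#'
#' The follow-up completely randomized experiment that re-tested the best
#' observed media alongside the surrogate-optimized combinations. Shipped
#' as a comparison fixture only; nothing in the package recomputes it.
#'
#' @return A tibble with one row per treatment: hormone concentrations and
#'   per-trait mean and standard error.
#' @export
validation_experiment <- function() {
  path <- system.file("extdata", "validation_experiment.csv",
                      package = "hormonet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

media_summary_cols <- function() {
  c("experiment_id", "media_id", hormone_cols(),
    paste0(rep(trait_names(), each = 2), c("_mean", "_se")),
    "n_replicates")
}

#' Read a media-summary CSV
#'
#' Accepts either the canonical layout (separate `<trait>_mean` /
#' `<trait>_se` columns) or the printed-table style where a trait column
#' holds `"mean ± se"` strings (column named after the trait, e.g.
#' `ns`), which is split on read. Hormone columns absent from the file are
#' filled with 0, matching the factorial designs where a hormone was not
#' applied.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble of media summaries (see [media_tables()]).
#' @export
read_media_tables <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    out <- tibble()
    for (cl in media_summary_cols()) out[[cl]] <- numeric(0)
    return(out)
  }
  names(raw) <- tolower(names(raw))

  # split printed-style "m ± s" trait columns
  for (tr in trait_names()) {
    if (tr %in% names(raw) && !paste0(tr, "_mean") %in% names(raw)) {
      parts <- parse_pm_column(raw[[tr]], tr)
      raw[[paste0(tr, "_mean")]] <- parts$mean
      raw[[paste0(tr, "_se")]] <- parts$se
      raw[[tr]] <- NULL
    }
  }
  for (h in hormone_cols()) {
    if (!h %in% names(raw)) raw[[h]] <- "0"
  }
  missing <- setdiff(media_summary_cols(), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("media table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }

  out <- raw
  for (cl in media_summary_cols()) {
    vals <- suppressWarnings(as.numeric(out[[cl]]))
    bad <- which(is.na(vals) & !is.na(out[[cl]]))
    if (length(bad) > 0) {
      abort(sprintf("cannot parse value '%s' in column '%s', row %d",
                    out[[cl]][bad[1]], cl, bad[1]))
    }
    if (anyNA(vals)) {
      abort(sprintf("missing value in column '%s', row %d", cl,
                    which(is.na(vals))[1]))
    }
    out[[cl]] <- vals
  }
  out <- select(as_tibble(out), all_of(media_summary_cols()))

  dup <- duplicated(out[, c("experiment_id", "media_id")])
  if (any(dup)) {
    abort(sprintf("duplicate (experiment_id, media_id) pair: (%g, %g)",
                  out$experiment_id[dup][1], out$media_id[dup][1]))
  }
  validate_media_tables(out)
  out
}

parse_pm_column <- function(x, col) {
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*±\\s*([0-9.eE+-]+)\\s*$", x))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad) > 0) {
    abort(sprintf("cannot parse '%s ± %s' cell '%s' in column '%s', row %d",
                  "mean", "se", x[bad[1]], col, bad[1]))
  }
  list(mean = as.numeric(vapply(m, `[`, "", 2L)),
       se = as.numeric(vapply(m, `[`, "", 3L)))
}

validate_media_tables <- function(tab) {
  stopifnot(is.data.frame(tab))
  num <- as.matrix(tab[, c(hormone_cols(),
                           paste0(trait_names(), "_mean"),
                           paste0(trait_names(), "_se"))])
  if (!all(is.finite(num))) abort("media table contains non-finite values")
  if (any(num[, hormone_cols()] < 0)) abort("hormone concentrations must be >= 0")
  if (any(tab$ns_se < 0 | tab$ls_se < 0 | tab$cw_se < 0 | tab$qi_se < 0)) {
    abort("standard errors must be >= 0")
  }
  if (any(tab$ns_mean < 0) || any(tab$cw_mean < 0)) {
    abort("NS and CW means must be >= 0")
  }
  if (any(tab$qi_mean < 0 | tab$qi_mean > 5)) {
    abort("QI means must lie in [0, 5]")
  }
  if (any(tab$n_replicates < 1 | tab$n_replicates != round(tab$n_replicates))) {
    abort("n_replicates must be a positive integer")
  }
  invisible(tab)
}

#' Write media summaries to CSV
#'
#' Canonical-layout counterpart of [read_media_tables()]; a written file
#' reloads to the same values.
#'
#' @param tables A media-summary tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_media_tables <- function(tables, path) {
  validate_media_tables(tables)
  readr::write_csv(select(tables, all_of(media_summary_cols())), path)
  invisible(path)
}

#' Extreme medium for a trait
#'
#' Finds the medium whose printed trait mean is largest (or smallest). Ties
#' are broken by the lowest `experiment_id`, then lowest `media_id`, so the
#' answer is deterministic.
#'
#' @param tables A media-summary tibble (one or more experiments).
#' @param trait One of `"ns"`, `"ls"`, `"cw"`, `"qi"`.
#' @param direction `"max"` (default) or `"min"`.
#' @return A one-row tibble: the winning medium's row plus `trait` and
#'   `value` columns.
#' @export
#' @examples
#' best_medium(media_tables(experiment = 1), "ns")
best_medium <- function(tables, trait, direction = c("max", "min")) {
  direction <- match.arg(direction)
  trait <- match_trait(trait)
  if (nrow(tables) == 0) abort("best_medium() needs a non-empty table")
  vals <- tables[[paste0(trait, "_mean")]]
  target <- if (direction == "max") max(vals) else min(vals)
  hit <- tables[vals == target, , drop = FALSE]
  hit <- arrange(hit, .data$experiment_id, .data$media_id)[1, ]
  mutate(hit, trait = trait, value = target)
}
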