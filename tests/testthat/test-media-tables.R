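test_that("builtin fixtures have the full factorial layout", {
  tab <- media_tables()
  expect_equal(nrow(tab), 85)
  expect_equal(as.vector(table(tab$experiment_id)), c(20, 20, 15, 15, 15))
  expect_equal(unique(tab$n_replicates[tab$experiment_id <= 2]), 6)
  expect_equal(unique(tab$n_replicates[tab$experiment_id >= 3]), 5)
  # hormones outside each experiment's design are exactly zero
  expect_true(all(tab$kin[tab$experiment_id %in% 1:2] == 0))
  expect_true(all(tab$tdz[tab$experiment_id != 5] == 0))
  expect_true(all(tab$naa[tab$experiment_id %in% c(1, 3, 5)] == 0))
})

test_that("spot values match the printed tables", {
  t1 <- media_tables(experiment = 1)
  m11 <- t1[t1$media_id == 11, ]
  expect_equal(unlist(m11[, c("bap", "iba", "kin", "tdz", "naa")]),
               c(bap = 1, iba = 0.1, kin = 0, tdz = 0, naa = 0))
  expect_equal(m11$ns_mean, 10.67)
  expect_equal(m11$ns_se, 0.21)
  t2 <- media_tables(experiment = 2)
  expect_equal(t2$cw_mean[t2$media_id == 1], 0)
  expect_equal(t2$ls_mean[t2$media_id == 1], 2.67)
  t5 <- media_tables(experiment = 5)
  expect_equal(t5$qi_mean[t5$media_id == 15], 0.5)
})

test_that("best_medium reproduces the headline extrema", {
  cases <- list(
    list(exp = 1, trait = "ns", media = 11, value = 10.67),
    list(exp = 2, trait = "ns", media = 11, value = 8.5),
    list(exp = 3, trait = "ns", media = 10, value = 7),
    list(exp = 4, trait = "ns", media = 11, value = 9.80),
    list(exp = 5, trait = "ns", media = 11, value = 5),
    list(exp = 1, trait = "ls", media = 10, value = 3.03)
  )
  for (cs in cases) {
    hit <- best_medium(media_tables(experiment = cs$exp), cs$trait)
    expect_equal(hit$media_id, cs$media, info = paste("exp", cs$exp, cs$trait))
    expect_equal(hit$value, cs$value, info = paste("exp", cs$exp, cs$trait))
  }
  ctrl <- best_medium(media_tables(experiment = 2), "cw", direction = "min")
  expect_equal(ctrl$media_id, 1)
  expect_equal(ctrl$value, 0)
})

test_that("best_medium extremum dominates every mean, all tables and traits", {
  for (e in 1:5) {
    tab <- media_tables(experiment = e)
    for (tr in trait_names()) {
      expect_gte(best_medium(tab, tr, "max")$value,
                 max(tab[[paste0(tr, "_mean")]]))
      expect_lte(best_medium(tab, tr, "min")$value,
                 min(tab[[paste0(tr, "_mean")]]))
    }
  }
})

test_that("best_medium handles single rows, ties and empty input", {
  tab <- media_tables(experiment = 3)
  one <- tab[7, ]
  expect_equal(best_medium(one, "ns")$media_id, one$media_id)
  # exact tie broken by lowest media_id
  tie <- tab[tab$media_id %in% 7:9, ]
  tie$ns_mean <- 5
  expect_equal(best_medium(tie, "ns")$media_id, 7)
  expect_error(best_medium(tab[0, ], "ns"), "non-empty")
  expect_error(best_medium(tab, "yield"), "unknown trait")
})

test_that("CSV round trip preserves every value exactly", {
  tab <- media_tables()
  path <- withr::local_tempfile(fileext = ".csv")
  write_media_tables(tab, path)
  expect_equal(as.data.frame(read_media_tables(path)), as.data.frame(tab),
               tolerance = 0)
})

test_that("printed-style 'mean ± se' cells are parsed and hormones zero-filled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "experiment_id,media_id,bap,iba,ns,ls,cw,qi,n_replicates",
    "1,11,1,0.1,10.67 ± 0.21,2.63 ± 0.02,0.22 ± 0.03,3.41 ± 0.15,6"
  ), path)
  tab <- read_media_tables(path)
  expect_equal(tab$ns_mean, 10.67)
  expect_equal(tab$ns_se, 0.21)
  expect_equal(tab$kin, 0)
  expect_equal(tab$tdz, 0)
  expect_equal(tab$naa, 0)
})

test_that("malformed and duplicate rows are rejected with row/column context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "experiment_id,media_id,bap,iba,ns,ls,cw,qi,n_replicates",
    "1,1,0,0,oops,2.53 ± 0.06,0.01 ± 0.01,4.83 ± 0.11,6"
  ), path)
  expect_error(read_media_tables(path), "column 'ns', row 1")

  dup <- withr::local_tempfile(fileext = ".csv")
  tab <- media_tables(experiment = 1)[c(1, 1), ]
  readr::write_csv(tab, dup)
  expect_error(read_media_tables(dup), "duplicate")
})

test_that("a header-only CSV loads as an empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("experiment_id", "media_id", hormone_cols(),
                     "ns_mean", "ns_se", "ls_mean", "ls_se", "cw_mean",
                     "cw_se", "qi_mean", "qi_se", "n_replicates"),
                   collapse = ","), path)
  expect_equal(nrow(read_media_tables(path)), 0)
})

test_that("the validation fixture ships unchanged", {
  v <- validation_experiment()
  expect_equal(nrow(v), 10)
  expect_equal(max(v$pr_mean), 10.80)
})
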