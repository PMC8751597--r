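test_that("cohort round-trips through CSV exactly", {
  co <- make_toy_cohort(30, seed = 5)
  co$education_years[3] <- NA
  co$read[7] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 30)
  for (col in names(co)[-1]) {
    expect_equal(back[[col]], co[[col]], info = col)
  }
  expect_true(is.na(back$education_years[3]))
  expect_true(is.na(back$read[7]))
})

test_that("out-of-range and unparseable cells become missing with a warning", {
  co <- make_toy_cohort(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  raw <- as.data.frame(co)
  raw$recall_immediate_w1 <- as.character(raw$recall_immediate_w1)
  raw$recall_immediate_w1[2] <- "25"
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  warns <- capture_warnings(back <- read_cohort(path))
  expect_length(warns, 1)
  expect_match(warns, "recall_immediate_w1")
  expect_true(is.na(back$recall_immediate_w1[2]))
  expect_equal(nrow(back), 5)

  raw$word_games <- as.character(raw$word_games)
  raw$word_games[1] <- "often"
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  warns <- capture_warnings(back <- read_cohort(path))
  expect_length(warns, 2)
  expect_true(is.na(back$word_games[1]))
})

test_that("missing required columns raise a schema error naming the column", {
  co <- make_toy_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(co)[setdiff(names(co), "age_years")],
                   path, row.names = FALSE)
  expect_error(read_cohort(path), "age_years")
  expect_error(read_cohort("no-such-file.csv"), "not found")
})

test_that("schema mapping renames arbitrary export dialects", {
  co <- make_toy_cohort(4, seed = 3)
  raw <- as.data.frame(co)
  names(raw)[names(raw) == "age_years"] <- "AGE"
  names(raw)[names(raw) == "word_games"] <- "Q11_WORDGAMES"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE)
  back <- read_cohort(path, schema = c(age_years = "AGE",
                                       word_games = "Q11_WORDGAMES"))
  expect_equal(back$age_years, co$age_years)
  expect_equal(back$word_games, co$word_games)
})

test_that("precomputed wave totals are accepted in place of components", {
  co <- make_toy_cohort(6, seed = 4)
  raw <- as.data.frame(co)
  raw <- raw[setdiff(names(raw), c("recall_immediate_w1", "recall_delayed_w1",
                                   "recall_immediate_w2", "recall_delayed_w2"))]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE)
  back <- read_cohort(path)
  expect_equal(back$memory_w1, co$memory_w1)
  pp <- preprocess_cohort(back, run_config())
  expect_equal(pp$records$memory_change, co$memory_w2 - co$memory_w1)
})

test_that("write_report flags p-values at the significance level and is deterministic", {
  acts <- c("read", "word_games")
  mk <- function(v) matrix(v, 2, 5, dimnames = list(acts, age_groups()))
  p_dcor <- mk(c(0.05, 0.60, rep(0.5, 8)))
  p_rf <- mk(rep(0.9, 10))
  sel <- select_features(p_dcor, p_rf, alpha = 0.05)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_report(list(selection = sel, config = run_config()), d1)
  write_report(list(selection = sel, config = run_config()), d2)
  tab <- utils::read.csv(file.path(d1, "selection_pvalues_dcor.csv"),
                         check.names = FALSE)
  expect_true(tab[tab$activity == "read", "sig_65-69"])
  expect_false(tab[tab$activity == "read", "sig_70-74"])
  expect_true("selection_pvalues_dcor.csv" %in% m1$file)
  for (f in m1$file) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
})

test_that("write_report warns on empty importance results but still writes files", {
  d <- withr::local_tempdir()
  expect_warning(m <- write_report(list(importance = list()), d), "empty")
  expect_true(file.exists(file.path(d, "importance_summary.csv")))
  expect_true(file.exists(file.path(d, "run_summary.json")))
})

test_that("child seeds are deterministic, distinct by stage, and in range", {
  expect_identical(child_seed(1, "stage-a"), child_seed(1, "stage-a"))
  expect_false(child_seed(1, "stage-a") == child_seed(1, "stage-b"))
  expect_false(child_seed(1, "stage-a") == child_seed(2, "stage-a"))
  seeds <- vapply(letters, function(s) child_seed(123, s), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
})

test_that("run_config validates counts, fractions and alpha", {
  expect_error(run_config(n_reps_sa = 0), "positive count")
  expect_error(run_config(subsample_fraction = 1), "must lie in")
  expect_error(run_config(alpha = 1), "alpha")
  cfg <- run_config(alpha = 0)  # degenerate but legal: selects nothing
  expect_equal(cfg$alpha, 0)
})

test_that("YAML config files round-trip through read_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.1", "n_reps_sa: 17", "seed: 99"), path)
  cfg <- read_config(path)
  expect_equal(cfg$alpha, 0.1)
  expect_equal(cfg$n_reps_sa, 17L)
  expect_equal(cfg$seed, 99L)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown config keys")
})

test_that("an exclusion-flag column marks records for exclusion upstream", {
  co <- make_toy_cohort(6, seed = 8)
  raw <- as.data.frame(co)
  raw$hearing_problem <- c("0", "1", "no", "yes", "", "0")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE)
  back <- read_cohort(path, exclusion_flag = "hearing_problem")
  expect_equal(back$excluded, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  pp <- preprocess_cohort(back, run_config())
  expect_equal(pp$counts$after_exclusion_flag, 4)
  expect_false(any(c("T002", "T004") %in% pp$records$id))
  expect_error(read_cohort(path, exclusion_flag = "no_such_col"),
               "exclusion-flag")
})
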