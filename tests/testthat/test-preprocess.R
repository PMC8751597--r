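test_that("memory scores add the two recall components", {
  expect_equal(compute_memory_score(10, 10), 20L)
  expect_equal(compute_memory_score(0, 0), 0L)
  expect_equal(compute_memory_score(7, 4), 11L)
  expect_equal(compute_memory_score(c(3, NA), c(2, 5)), c(5L, NA))
  expect_error(compute_memory_score(11, 0), "outside 0-10")
  expect_error(compute_memory_score(3, -1), "outside 0-10")
})

test_that("memory change is follow-up minus baseline", {
  expect_equal(compute_memory_change(12, 9), -3L)
  expect_equal(compute_memory_change(9, 12), 3L)
  expect_equal(compute_memory_change(20, 0), -20L)
  expect_error(compute_memory_change(21, 5), "outside 0-20")
})

test_that("age binning is inclusive on both endpoints and rejects out-of-range", {
  expect_equal(as.character(assign_age_group(65)), "65-69")
  expect_equal(as.character(assign_age_group(69)), "65-69")
  expect_equal(as.character(assign_age_group(70)), "70-74")
  expect_equal(as.character(assign_age_group(85)), "85-89")
  expect_equal(as.character(assign_age_group(89)), "85-89")
  expect_true(is.na(assign_age_group(90)))
  expect_true(is.na(assign_age_group(64)))
})

test_that("missingness filter drops records strictly above the threshold", {
  co <- make_toy_cohort(3, seed = 6)
  cat33 <- activity_catalog()
  co[1, cat33$key[1:5]] <- NA        # 5/36 ~ 13.9% -> retained
  co[2, cat33$key[1:6]] <- NA        # 6/36 ~ 16.7% -> dropped
  kept <- filter_missingness(co, 0.15)
  expect_equal(kept$id, c("T001", "T003"))
  expect_equal(filter_missingness(make_toy_cohort(4))$id,
               sprintf("T%03d", 1:4))
})

test_that("median imputation follows the round-half-up rule and never touches scores", {
  co <- make_toy_cohort(5, seed = 7)
  co$read <- c(1L, 2L, 2L, NA, 3L)          # median 2 -> 2
  co$word_games <- c(1L, 2L, 3L, 4L, NA)    # median 2.5 -> 3
  co$memory_w1[1] <- NA                     # scores are not imputed
  out <- impute_median(co)
  expect_equal(out$read[4], 2L)
  expect_equal(out$word_games[5], 3L)
  expect_true(is.na(out$memory_w1[1]))
  expect_identical(impute_median(out), out)  # idempotent
  co$read <- rep(NA_integer_, 5)
  expect_error(impute_median(co), "'read'")
})

test_that("imputation and filtering satisfy their invariants on random fixtures", {
  cat33 <- activity_catalog()
  for (s in 1:5) {
    co <- make_toy_cohort(40, seed = s)
    set.seed(100 + s)
    for (k in cat33$key) {
      co[[k]][runif(40) < 0.15] <- NA
    }
    co$education_years[runif(40) < 0.1] <- NA
    # monotone in the threshold
    n_at <- vapply(c(0.05, 0.1, 0.15, 0.3, 0.6),
                   function(th) nrow(filter_missingness(co, th)), numeric(1))
    expect_true(all(diff(n_at) >= 0))
    # idempotent and complete
    once <- impute_median(co)
    expect_identical(impute_median(once), once)
    expect_false(anyNA(once[c(cat33$key, "education_years")]))
    # imputed values are valid categories
    for (i in seq_len(33)) {
      v <- once[[cat33$key[i]]]
      expect_true(all(v >= 0 & v <= cat33$n_levels[i] - 1L))
    }
  }
})

test_that("the preprocessing chain yields complete tables with correct shapes", {
  co <- make_grouped_cohort(10, seed = 9)
  cat33 <- activity_catalog()
  co$read[2] <- NA
  pp <- preprocess_cohort(co, run_config())
  expect_false(anyNA(pp$records[c(cat33$key, "education_years",
                                  "memory_w1", "memory_w2",
                                  "memory_change")]))
  expect_equal(pp$counts$input, 50)
  tabs <- build_tables(pp$records, c("read", "use_computer", "word_games"))
  tab <- tabs[["65-69"]]
  expect_s3_class(tab, "analysis_table")
  expect_equal(dim(tab$X), c(10, 5))
  expect_equal(tab$feature_names,
               c("read", "use_computer", "word_games",
                 "education_years", "baseline_memory"))
  expect_equal(length(tab$y), 10)
  expect_equal(tab$n_activities, 3L)
  expect_equal(unname(tab$X[, "baseline_memory"]),
               pp$records$memory_w1[pp$records$age_group == "65-69"])
})

test_that("build_tables reports an empty age group by name", {
  co <- make_grouped_cohort(5, seed = 10)
  co <- co[co$age_years != 87, ]
  co$age_group <- assign_age_group(co$age_years)
  co$memory_change <- compute_memory_change(co$memory_w1, co$memory_w2)
  expect_error(build_tables(co, "read"), "85-89")
  expect_error(build_tables(co, "not_an_activity"), "unknown activities")
})

test_that("records lacking either wave score are excluded before filtering", {
  co <- make_grouped_cohort(4, seed = 11)
  co$recall_immediate_w2[1] <- NA
  co$memory_w2[1] <- NA
  pp <- preprocess_cohort(co, run_config())
  expect_equal(pp$counts$with_both_waves, 19)
  expect_false("T001" %in% pp$records$id)
})
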