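test_that("generation is deterministic given config and seed", {
  cfg <- trend_preset("paper-like", n_per_group = rep(40L, 5), seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(generate_null_cohort(cfg), generate_null_cohort(cfg))
})

test_that("zero coefficients and vanishing noise give deltaM = round(mu_g)", {
  # group means chosen away from .5 so rounding is stable under tiny noise
  cfg <- synthetic_config(n_per_group = setNames(rep(60L, 5), age_groups()),
                          mu = setNames(c(-0.4, -0.9, -1.2, -1.7, -2.1),
                                        age_groups()),
                          noise_sd = 1e-9, missing_rate = 0, seed = 2)
  co <- generate_cohort(cfg)
  pp <- preprocess_cohort(co, run_config())
  rec <- pp$records
  mu <- cfg$mu[as.character(rec$age_group)]
  # away from the floor the change is exactly the rounded group mean
  ok <- rec$memory_w1 >= ceiling(abs(mu))
  expect_true(all(rec$memory_change[ok] == round(mu[ok])))
})

test_that("cohorts respect score bounds and configured group sizes", {
  cfg <- trend_preset("paper-like", n_per_group = c(50L, 60L, 70L, 40L, 30L),
                      seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 250)
  expect_true(all(co$memory_w1 >= 0 & co$memory_w1 <= 20))
  expect_true(all(co$memory_w2 >= 0 & co$memory_w2 <= 20))
  comp <- co[c("recall_immediate_w1", "recall_delayed_w1",
               "recall_immediate_w2", "recall_delayed_w2")]
  expect_true(all(comp >= 0 & comp <= 10))
  expect_equal(co$recall_immediate_w1 + co$recall_delayed_w1, co$memory_w1)
  dm <- co$memory_w2 - co$memory_w1
  expect_true(all(dm >= -20 & dm <= 20))
  grp <- table(assign_age_group(co$age_years))
  expect_equal(unname(as.integer(grp)), c(50L, 60L, 70L, 40L, 30L))
  cat33 <- activity_catalog()
  for (i in seq_len(33)) {
    v <- co[[cat33$key[i]]]
    expect_true(all(is.na(v) | (v >= 0 & v <= cat33$n_levels[i] - 1L)))
  }
})

test_that("trend presets encode the stated coefficient monotonicities", {
  pl <- trend_preset("paper-like")
  expect_true(all(diff(rowSums(abs(pl$gamma))) > 0))
  expect_true(all(diff(abs(pl$alpha)) < 0))
  expect_true(all(diff(abs(pl$beta)) < 0))

  nl <- trend_preset("null")
  expect_true(all(apply(nl$gamma, 2, function(x) length(unique(x)) == 1)))
  expect_equal(length(unique(nl$alpha)), 1)
  expect_equal(length(unique(nl$beta)), 1)

  rv <- trend_preset("reversed")
  expect_true(all(diff(rowSums(abs(rv$gamma))) < 0))
  expect_true(all(diff(abs(rv$alpha)) > 0))

  expect_error(trend_preset("sideways"))
})

test_that("null cohorts carry an all-zero coefficient ledger", {
  cfg <- trend_preset("paper-like", n_per_group = rep(30L, 5), seed = 7)
  co <- generate_null_cohort(cfg)
  gt <- attr(co, "ground_truth")
  expect_true(all(unlist(gt$alpha) == 0))
  expect_true(all(unlist(gt$beta) == 0))
  expect_true(all(gt$gamma == 0))
})

test_that("the ground-truth ledger round-trips through the report writer", {
  cfg <- trend_preset("paper-like", n_per_group = rep(30L, 5), seed = 8)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_report(list(config = run_config(),
                    truth = attr(co, "ground_truth")), d)
  back <- jsonlite::read_json(file.path(d, "run_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(unlist(back$ground_truth$alpha),
               unlist(attr(co, "ground_truth")$alpha), tolerance = 1e-12)
  expect_equal(back$ground_truth$seed, 8)
})

test_that("OLS on generated groups recovers the configured coefficients", {
  # pooled 95%-CI coverage across a group's coefficients stays >= 90%;
  # a high-concentration recall draw keeps scores away from the 0/20 bounds,
  # isolating linear recovery from the (documented) boundary censoring
  cfg0 <- trend_preset("paper-like", seed = 1)
  active <- colnames(cfg0$gamma)[colSums(abs(cfg0$gamma)) > 0]
  n_rep <- 50
  cover <- matrix(0, n_rep, 5)
  total <- matrix(0, n_rep, 5)
  for (r in seq_len(n_rep)) {
    cfg <- trend_preset("paper-like", seed = 1000 + r)
    cfg$baseline_dispersion <- 12
    co <- generate_cohort(cfg)
    pp <- preprocess_cohort(co, run_config())
    tabs <- build_tables(pp$records, active)
    for (g in seq_along(tabs)) {
      tab <- tabs[[g]]
      grp <- names(tabs)[g]
      mom <- memtrend:::synthetic_moments(cfg, grp)
      cat33 <- activity_catalog()
      sd_act <- sqrt((cat33$n_levels^2 - 1) / 12)
      names(sd_act) <- cat33$key
      m_act <- (cat33$n_levels - 1) / 2
      names(m_act) <- cat33$key
      Z <- tab$X
      Z[, active] <- sweep(sweep(Z[, active], 2, m_act[active]), 2,
                           sd_act[active], "/")
      Z[, "education_years"] <- (Z[, "education_years"] -
        mom$education["mean"]) / mom$education["sd"]
      Z[, "baseline_memory"] <- (Z[, "baseline_memory"] -
        mom$baseline["mean"]) / mom$baseline["sd"]
      fit <- stats::lm(tab$y ~ Z)
      ci <- stats::confint(fit)[-1, , drop = FALSE]
      truth <- c(cfg$gamma[grp, active], cfg$beta[[grp]], cfg$alpha[[grp]])
      inside <- truth >= ci[, 1] & truth <= ci[, 2]
      cover[r, g] <- sum(inside)
      total[r, g] <- length(inside)
    }
  }
  pooled <- colSums(cover) / colSums(total)
  expect_true(all(pooled >= 0.9),
              info = paste("per-group pooled coverage:",
                           paste(round(pooled, 3), collapse = " ")))
})
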