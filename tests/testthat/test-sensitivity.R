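test_that("SVR fits a noiseless linear surface accurately and deterministically", {
  set.seed(21)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * X[, 1] + X[, 2]
  tab <- analysis_table("65-69", colnames(X), X, y, n_activities = 2L)
  r2 <- holdout_r2(tab, run_config(r2_repeats = 5L), seed = 3)
  expect_gte(r2$mean, 0.95)
  f1 <- fit_svr(X, y, seed = 12)
  f2 <- fit_svr(X, y, seed = 12)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("SVR validates its inputs and grid", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(svr_grid_spec(n_widths = 0), "at least one width")
  expect_error(fit_svr(X, rep(1, 20)), "constant")
  expect_error(fit_svr(X[1:5, ], rnorm(5)), "at least 10 rows")
})

test_that("sensitivity importance is a normalized dispersion over probe levels", {
  set.seed(22)
  X <- matrix(rnorm(150 * 3), 150, 3, dimnames = list(NULL, c("a", "b", "c")))
  # a model that ignores a feature assigns it exactly zero importance
  r <- sa_importance(fn_model(function(M) M[, 1]^2), X, L = 7)
  expect_equal(unname(r), c(1, 0, 0))
  # symmetric model with identical probe grids splits importance evenly
  Xs <- X
  Xs[, 2] <- Xs[, 1]
  r2 <- sa_importance(fn_model(function(M) M[, 1] + M[, 2]), Xs, L = 7)
  expect_lt(abs(r2[1] - r2[2]), 1e-6)
  expect_equal(unname(r2[3]), 0)
  expect_equal(sum(r2), 1, tolerance = 1e-9)
  # degenerate constant model is flagged
  expect_error(sa_importance(fn_model(function(M) rep(1, nrow(M))), X),
               "degenerate")
  expect_error(sa_importance(fn_model(function(M) M[, 1]), X, L = 1), "L >= 2")
})

test_that("ordinal features are probed exactly on their categories", {
  X <- cbind(ord = rep(0:4, each = 6), cont = rnorm(30))
  seen <- new.env()
  seen$levels <- NULL
  m <- fn_model(function(M) {
    seen$levels <- union(seen$levels, unique(M[, "ord"]))
    M[, "ord"] + M[, "cont"]
  })
  sa_importance(m, X, L = 7)
  expect_setequal(seen$levels, 0:4)
})

test_that("the RBF fast path agrees with the generic predict path", {
  set.seed(23)
  X <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] - 0.5 * X[, 3]^2 + rnorm(120, 0, 0.2)
  fit <- fit_svr(X, y, seed = 2)
  slow <- fn_model(function(M) predict(fit, M))  # routes around the fast path
  expect_equal(sa_importance(fit, X, L = 7), sa_importance(slow, X, L = 7),
               tolerance = 1e-8)
})

test_that("importance is equivariant under feature permutation", {
  set.seed(24)
  X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  m <- fn_model(function(M) 2 * M[, "a"] + M[, "c"] - 0.5 * M[, "d"])
  r <- sa_importance(m, X)
  perm <- c(3, 1, 4, 2)
  r_perm <- sa_importance(m, X[, perm])
  expect_equal(r_perm, r[perm], tolerance = 1e-12)
})

test_that("the repetition distribution has the right shape and normalization", {
  set.seed(25)
  n <- 80
  X <- cbind(act1 = sample(0:6, n, TRUE), act2 = sample(0:6, n, TRUE),
             education_years = sample(8:20, n, TRUE),
             baseline_memory = sample(0:20, n, TRUE))
  y <- 1.5 * X[, "act1"] - 0.2 * X[, "baseline_memory"] + rnorm(n, 0, 0.5)
  tab <- analysis_table("70-74", colnames(X), X, y, n_activities = 2L)
  cfg <- run_config(n_reps_sa = 20L, seed = 6)
  dist <- importance_distribution(tab, cfg)
  expect_equal(dim(dist$values), c(20L, 4L))
  expect_true(all(dist$values >= 0))
  expect_equal(unname(rowSums(dist$values)), rep(1, 20), tolerance = 1e-9)
  # combined = sum of activity entries = 1 - (education + baseline)
  expect_equal(dist$combined_activity,
               unname(rowSums(dist$values[, 1:2])), tolerance = 1e-12)
  expect_equal(dist$combined_activity,
               1 - rowSums(dist$values[, 3:4]), tolerance = 1e-9)
  expect_identical(combined_activity_importance(dist), dist$combined_activity)
  # dominant activity has the largest mean importance among activities
  expect_equal(which.max(dist$summary$mean[1:2]), 1L)
  expect_equal(dist$summary$se,
               unname(apply(dist$values, 2, sd)) / sqrt(20))
  # subsamples below 10 rows are rejected
  tiny <- analysis_table("70-74", colnames(X), X[1:11, ], y[1:11],
                         n_activities = 2L)
  expect_error(importance_distribution(tiny, cfg), "smaller than 10")
})

test_that("repeated importance estimation is deterministic under the master seed", {
  set.seed(26)
  n <- 60
  X <- cbind(act1 = sample(0:6, n, TRUE),
             education_years = sample(8:20, n, TRUE),
             baseline_memory = sample(0:20, n, TRUE))
  y <- X[, "act1"] + rnorm(n, 0, 0.3)
  tab <- analysis_table("75-79", colnames(X), X, y, n_activities = 1L)
  cfg <- run_config(n_reps_sa = 8L, seed = 11)
  expect_identical(importance_distribution(tab, cfg)$values,
                   importance_distribution(tab, cfg)$values)
})

test_that("holdout accuracy behaves at both extremes and is seeded", {
  set.seed(27)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tab_null <- analysis_table("65-69", colnames(X), X, rnorm(500),
                             n_activities = 1L)
  r2_null <- holdout_r2(tab_null, run_config(r2_repeats = 10L), seed = 4)
  expect_lte(abs(r2_null$mean), 0.05)
  expect_identical(holdout_r2(tab_null, run_config(r2_repeats = 3L), seed = 9)$mean,
                   holdout_r2(tab_null, run_config(r2_repeats = 3L), seed = 9)$mean)
  tiny <- analysis_table("65-69", colnames(X), X[1:20, ], rnorm(20) + X[1:20, 1],
                         n_activities = 1L)
  expect_error(holdout_r2(tiny, run_config(), split = 0.9), "fewer than 5")
})

test_that("the reference-only repetition variant keeps one model per group", {
  set.seed(28)
  n <- 70
  X <- cbind(act1 = sample(0:6, n, TRUE),
             education_years = sample(8:20, n, TRUE),
             baseline_memory = sample(0:20, n, TRUE))
  y <- X[, "act1"] - 0.1 * X[, "baseline_memory"] + rnorm(n, 0, 0.4)
  tab <- analysis_table("70-74", colnames(X), X, y, n_activities = 1L)
  cfg <- run_config(n_reps_sa = 10L, seed = 13, sa_refit = FALSE)
  dist <- importance_distribution(tab, cfg)
  expect_equal(dim(dist$values), c(10L, 3L))
  expect_equal(unname(rowSums(dist$values)), rep(1, 10), tolerance = 1e-9)
  expect_identical(importance_distribution(tab, cfg)$values, dist$values)
})
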