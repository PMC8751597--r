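#' Data-based sensitivity-analysis importance
#'
#' Probes a fitted model one feature at a time: feature `j` is swept over `L`
#' probe levels spanning its observed range in the reference matrix (for an
#' ordinal feature with at most `L` distinct observed values, the probes are
#' exactly those values), the whole reference matrix is overwritten at column
#' `j` with each level, predictions are averaged over rows, and the feature's
#' sensitivity is the dispersion of the `L` averaged predictions (variance by
#' default, range as an alternative). Relative importance is each
#' sensitivity divided by the sum over features, so the result is
#' nonnegative and sums to one.
#'
#' Works with any model that has a `predict(model, newdata)` method (see
#' [fn_model()] for analytic stand-ins). For Gaussian-kernel [fit_svr()]
#' models an algebraically identical fast path factorizes the RBF kernel
#' over the single modified column.
#'
#' @param model fitted model.
#' @param X_ref reference matrix on the original feature scale (typically the
#'   training rows).
#' @param L number of probe levels (default 7).
#' @param measure `"variance"` (default) or `"range"`.
#' @return Named numeric vector of relative importances summing to 1.
#' @export
sa_importance <- function(model, X_ref, L = 7L, measure = c("variance", "range")) {
  measure <- match.arg(measure)
  X_ref <- as.matrix(X_ref)
  if (L < 2L) stop("sa_importance: need L >= 2 probe levels")
  p <- ncol(X_ref)
  probes <- lapply(seq_len(p), function(j) {
    v <- X_ref[, j]
    u <- sort(unique(v))
    if (length(u) <= L) u else seq(min(v), max(v), length.out = L)
  })
  level_means <- if (inherits(model, "svr_fit") &&
                     inherits(model$model, "svm")) {
    sa_level_means_rbf(model, X_ref, probes)
  } else {
    sa_level_means_generic(model, X_ref, probes)
  }
  s <- vapply(level_means, function(m) {
    if (measure == "variance") stats::var(m) else diff(range(m))
  }, numeric(1))
  total <- sum(s)
  if (total <= 0) stop("sa_importance: model is constant over all probes ",
                       "(degenerate model)")
  r <- s / total
  names(r) <- colnames(X_ref)
  r
}

# Mean prediction per probe level via repeated predict() calls (one batched
# call per feature).
sa_level_means_generic <- function(model, X_ref, probes) {
  n <- nrow(X_ref)
  lapply(seq_along(probes), function(j) {
    lv <- probes[[j]]
    big <- X_ref[rep(seq_len(n), times = length(lv)), , drop = FALSE]
    big[, j] <- rep(lv, each = n)
    pred <- stats::predict(model, big)
    colMeans(matrix(pred, nrow = n))
  })
}

# RBF factorization: with x' equal to x except column j set to level l,
#   ||x' - s||^2 = ||x - s||^2 - (x_j - s_j)^2 + (l - s_j)^2,
# so exp(-g ||x'-s||^2) = E_is * F_is * G_s(l) and the row-averaged
# prediction at level l is  sum_s coef_s G_s(l) H_s / n - rho  with
# H_s = sum_i E_is F_is. Exact, and linear instead of quadratic in probes.
sa_level_means_rbf <- function(fit, X_ref, probes) {
  Xs <- sweep(sweep(as.matrix(X_ref), 2, fit$center), 2, fit$scale, "/")
  svm <- fit$model
  SV <- as.matrix(svm$SV)
  coefs <- as.numeric(svm$coefs)
  rho <- svm$rho
  g <- fit$gamma
  n <- nrow(Xs)
  d0 <- outer(rowSums(Xs^2), rep(1, nrow(SV))) +
    outer(rep(1, n), rowSums(SV^2)) - 2 * Xs %*% t(SV)
  E <- exp(-g * pmax(d0, 0))
  lapply(seq_along(probes), function(j) {
    lv_scaled <- (probes[[j]] - fit$center[j]) / fit$scale[j]
    Fj <- exp(g * (outer(Xs[, j], SV[, j], "-"))^2)
    H <- colSums(E * Fj)
    vapply(lv_scaled, function(l) {
      G <- exp(-g * (l - SV[, j])^2)
      sum(coefs * G * H) / n - rho
    }, numeric(1))
  })
}

#' Repeated-subsample importance distribution for one age group
#'
#' Runs the study's repetition scheme on one analysis table: the Gaussian
#' kernel width is selected once on the full group by the 10-candidate grid
#' search; then for each of `n_reps_sa` repetitions a random subsample
#' (fraction `subsample_fraction`, without replacement) is drawn, the SVR is
#' refit on it with the selected hyper-parameters (set `sa_regrid = TRUE` in
#' the config to re-run the grid search per repetition, or `sa_refit = FALSE`
#' to keep the single full-group fit and only resample the reference matrix),
#' and [sa_importance()] is computed with the subsample as reference matrix. Rows
#' are stacked into a repetitions-by-predictors matrix; the combined-activity
#' importance of each repetition is the arithmetic sum of its activity
#' entries.
#'
#' @param table an [analysis_table()].
#' @param cfg a [run_config()].
#' @return An object of class `importance_distribution`: list with
#'   `age_group`, `predictor_names`, `values` (R x p matrix, every row sums
#'   to 1), `combined_activity` (length-R vector), and `summary` (per
#'   predictor mean and standard error across repetitions,
#'   `se = sd / sqrt(R)`).
#' @export
importance_distribution <- function(table, cfg = run_config()) {
  stopifnot(inherits(table, "analysis_table"))
  n <- nrow(table$X)
  m <- floor(cfg$subsample_fraction * n)
  if (m < 10L) stop("importance_distribution: subsample smaller than 10 rows")
  R <- cfg$n_reps_sa
  base_seed <- child_seed(cfg$seed, paste0("importance-", table$age_group))
  grid <- svr_grid_spec(n_widths = cfg$svr_grid_size,
                        val_fraction = cfg$svr_val_fraction)
  base_fit <- fit_svr(table$X, table$y, grid, seed = base_seed)
  rep_seeds <- with_seed(base_seed, sample.int(2147483646L, R))

  values <- matrix(NA_real_, R, ncol(table$X),
                   dimnames = list(NULL, table$feature_names))
  for (r in seq_len(R)) {
    rows <- with_seed(rep_seeds[r], sample.int(n, m))
    Xsub <- table$X[rows, , drop = FALSE]
    ysub <- table$y[rows]
    fit <- if (!cfg$sa_refit) {
      base_fit
    } else if (cfg$sa_regrid) {
      fit_svr(Xsub, ysub, grid, seed = rep_seeds[r])
    } else {
      refit_svr(base_fit, Xsub, ysub)
    }
    values[r, ] <- sa_importance(fit, Xsub, L = cfg$sa_levels,
                                 measure = cfg$sa_measure)
  }
  acts <- seq_len(table$n_activities)
  combined <- rowSums(values[, acts, drop = FALSE])
  summary <- data.frame(
    predictor = table$feature_names,
    mean = colMeans(values),
    se = apply(values, 2, stats::sd) / sqrt(R),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(age_group = table$age_group,
                 predictor_names = table$feature_names,
                 n_activities = table$n_activities,
                 values = values, combined_activity = combined,
                 summary = summary),
            class = "importance_distribution")
}

#' Combined daily-activity importance per repetition
#'
#' The combined importance is the arithmetic sum of the individual activity
#' importances within each repetition; because every repetition's importances
#' sum to one, it equals one minus the education and baseline-memory
#' importances.
#'
#' @param dist an [importance_distribution()].
#' @return Numeric vector, one value per repetition.
#' @export
combined_activity_importance <- function(dist) {
  stopifnot(inherits(dist, "importance_distribution"))
  dist$combined_activity
}

#' Repeated-holdout predictive accuracy
#'
#' Estimates out-of-sample accuracy of the per-group SVR by repeated random
#' splitting: per repeat a seeded `split` fraction trains a fresh [fit_svr()]
#' (grid search included) and the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} is computed on the held-out rows.
#'
#' @param table an [analysis_table()].
#' @param cfg a [run_config()].
#' @param split training fraction (default from `cfg$r2_split`).
#' @param repeats number of repeats (default from `cfg$r2_repeats`).
#' @param seed seed (default from `cfg$seed`).
#' @return List with `mean` (mean R-squared over repeats) and `values`
#'   (per-repeat R-squared).
#' @export
holdout_r2 <- function(table, cfg = run_config(), split = cfg$r2_split,
                       repeats = cfg$r2_repeats, seed = cfg$seed) {
  stopifnot(inherits(table, "analysis_table"))
  n <- nrow(table$X)
  n_train <- floor(split * n)
  if (n - n_train < 5L) stop("holdout_r2: test split has fewer than 5 rows")
  grid <- svr_grid_spec(n_widths = cfg$svr_grid_size,
                        val_fraction = cfg$svr_val_fraction)
  base <- child_seed(seed, paste0("holdout-", table$age_group))
  vals <- vapply(seq_len(repeats), function(r) {
    rs <- child_seed(base, paste0("split", r))
    tr <- with_seed(rs, sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    fit <- fit_svr(table$X[tr, , drop = FALSE], table$y[tr], grid, seed = rs)
    pred <- stats::predict(fit, table$X[te, , drop = FALSE])
    ss_res <- sum((table$y[te] - pred)^2)
    ss_tot <- sum((table$y[te] - mean(table$y[te]))^2)
    1 - ss_res / ss_tot
  }, numeric(1))
  list(mean = mean(vals), values = vals)
}
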