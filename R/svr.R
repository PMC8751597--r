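#' Gaussian-kernel SVR hyper-parameter grid specification
#'
#' The grid holds 10 kernel-width candidates by default. Widths are
#' log-spaced between the `q_range` quantiles (default 0.1 and 0.9) of the
#' pairwise Euclidean distances of the standardized inputs, a standard
#' data-driven bracket for the RBF bandwidth. The regularization constant
#' defaults to the Cherkassky-Ma heuristic
#' \eqn{C = \max(|\bar y + 3 s_y|, |\bar y - 3 s_y|)} and the tube width to
#' \eqn{\epsilon = 0.1 s_y}; both can be fixed explicitly.
#'
#' @param n_widths number of kernel-width candidates (default 10).
#' @param q_range two quantiles of the pairwise-distance distribution
#'   bracketing the widths.
#' @param val_fraction inner validation fraction used to score candidates.
#' @param cost optional fixed regularization constant.
#' @param epsilon optional fixed tube width.
#' @return An object of class `svr_grid_spec`.
#' @export
svr_grid_spec <- function(n_widths = 10L, q_range = c(0.1, 0.9),
                          val_fraction = 1 / 3, cost = NULL, epsilon = NULL) {
  if (n_widths < 1L) stop("svr_grid_spec: need at least one width candidate")
  stopifnot(length(q_range) == 2L, all(q_range > 0), all(q_range < 1),
            q_range[1] <= q_range[2],
            val_fraction > 0, val_fraction < 1)
  structure(list(n_widths = as.integer(n_widths), q_range = q_range,
                 val_fraction = val_fraction, cost = cost, epsilon = epsilon),
            class = "svr_grid_spec")
}

# Kernel-width candidates from the standardized design.
svr_width_candidates <- function(Xs, grid) {
  n <- nrow(Xs)
  take <- if (n > 400) Xs[seq(1, n, length.out = 400), , drop = FALSE] else Xs
  d <- as.numeric(stats::dist(take))
  d <- d[d > 0]
  if (length(d) == 0L) stop("fit_svr: all rows identical, no distance scale")
  q <- stats::quantile(d, grid$q_range, names = FALSE)
  if (q[1] <= 0) q[1] <- min(d)
  if (grid$n_widths == 1L) return(sqrt(q[1] * q[2]))
  exp(seq(log(q[1]), log(q[2]), length.out = grid$n_widths))
}

# e1071 fit on an already-standardized design with fixed hyper-parameters.
svm_fixed <- function(Xs, y, sigma, cost, epsilon) {
  e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
             gamma = 1 / (2 * sigma^2), cost = cost, epsilon = epsilon,
             scale = FALSE)
}

# Wrap a fitted e1071 model plus the standardization into an svr_fit.
new_svr_fit <- function(model, center, scale, sigma, cost, epsilon,
                        feature_names) {
  structure(list(model = model, center = center, scale = scale,
                 sigma = sigma, gamma = 1 / (2 * sigma^2),
                 cost = cost, epsilon = epsilon,
                 feature_names = feature_names),
            class = "svr_fit")
}

#' Fit a Gaussian-kernel support-vector regression with width selection
#'
#' Standardizes the predictor columns (fit-time means and scales are stored
#' and applied at prediction), builds the kernel-width candidate list from
#' the grid specification, scores each candidate by mean squared error on a
#' seeded inner holdout split, refits the winner on all rows, and returns the
#' fitted model. Ties break to the smallest width. Selection is deterministic
#' given the seed.
#'
#' @param X complete numeric predictor matrix, `n >= 10` rows.
#' @param y numeric target (non-constant).
#' @param grid an [svr_grid_spec()].
#' @param seed seed for the inner validation split.
#' @return An object of class `svr_fit`; use `predict(fit, newdata)` on the
#'   original (unstandardized) feature scale.
#' @export
fit_svr <- function(X, y, grid = svr_grid_spec(), seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("fit_svr: need at least 10 rows")
  if (length(y) != nrow(X)) stop("fit_svr: length mismatch")
  s_y <- stats::sd(y)
  if (s_y == 0) stop("fit_svr: constant target (degenerate)")
  stopifnot(inherits(grid, "svr_grid_spec"))

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  cost <- grid$cost %||% max(abs(mean(y) + 3 * s_y), abs(mean(y) - 3 * s_y))
  epsilon <- grid$epsilon %||% (0.1 * s_y)
  sigmas <- svr_width_candidates(Xs, grid)

  best <- 1L
  if (length(sigmas) > 1L) {
    n <- nrow(Xs)
    n_val <- max(1L, round(grid$val_fraction * n))
    val <- with_seed(seed, sample.int(n, n_val))
    tr <- setdiff(seq_len(n), val)
    errs <- vapply(sigmas, function(s) {
      m <- svm_fixed(Xs[tr, , drop = FALSE], y[tr], s, cost, epsilon)
      mean((y[val] - stats::predict(m, Xs[val, , drop = FALSE]))^2)
    }, numeric(1))
    best <- which.min(errs)
  }
  model <- svm_fixed(Xs, y, sigmas[best], cost, epsilon)
  new_svr_fit(model, center, scale, sigmas[best], cost, epsilon, colnames(X))
}

# Refit with hyper-parameters carried over from an existing fit (used by the
# repetition loop of the sensitivity analysis: grid search once per group,
# refit per subsample). Standardization is recomputed on the new rows.
refit_svr <- function(reference_fit, X, y) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  model <- svm_fixed(Xs, y, reference_fit$sigma, reference_fit$cost,
                     reference_fit$epsilon)
  new_svr_fit(model, center, scale, reference_fit$sigma, reference_fit$cost,
              reference_fit$epsilon, colnames(X))
}

#' Predict from a fitted SVR
#'
#' @param object an `svr_fit` from [fit_svr()].
#' @param newdata numeric matrix on the original feature scale.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(stats::predict(object$model, Xs))
}

#' Analytic stand-in model for sensitivity-analysis checks
#'
#' Wraps an arbitrary vectorized function of the predictor matrix as a model
#' with a `predict` method, so known closed-form response surfaces can be fed
#' to [sa_importance()] in tests and self-checks.
#'
#' @param f a function taking a numeric matrix and returning one prediction
#'   per row.
#' @return An object of class `fn_model`.
#' @export
#' @examples
#' m <- fn_model(function(X) X[, 1] + X[, 2])
#' predict(m, cbind(1:3, 4:6))
fn_model <- function(f) {
  stopifnot(is.function(f))
  structure(list(f = f), class = "fn_model")
}

#' @rdname fn_model
#' @param object an `fn_model`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @export
predict.fn_model <- function(object, newdata, ...) {
  as.numeric(object$f(as.matrix(newdata)))
}
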