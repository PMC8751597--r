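#' Fit a regression random forest with impurity importance
#'
#' Thin, seeded wrapper over [ranger::ranger()] with the pipeline's forest
#' settings (trees, minimum leaf size, features-per-split defaulting to
#' `ceiling(p/3)`), exposing per-feature impurity importance and out-of-bag
#' predictions.
#'
#' @param X complete numeric matrix or data.frame of predictors.
#' @param y numeric target (non-constant).
#' @param settings a [run_config()] supplying `rf_num_trees`, `rf_min_node`,
#'   `rf_mtry`.
#' @param seed forest seed.
#' @return A list of class `rf_fit` with `model` (the ranger object),
#'   `importance` (named numeric) and `predictions_oob`.
#' @export
rf_fit_predict <- function(X, y, settings = run_config(), seed = 1L) {
  X <- as.data.frame(X)
  if (nrow(X) < 2L) stop("rf_fit_predict: need at least 2 rows")
  if (length(y) != nrow(X)) stop("rf_fit_predict: length mismatch")
  if (stats::sd(y) == 0) stop("rf_fit_predict: constant target (degenerate)")
  mtry <- settings$rf_mtry %||% ceiling(ncol(X) / 3)
  dat <- X
  dat$.target <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = dat,
    num.trees = settings$rf_num_trees,
    min.node.size = settings$rf_min_node,
    mtry = min(mtry, ncol(X)),
    importance = "impurity", seed = seed, num.threads = 1,
    respect.unordered.factors = "order"
  )
  structure(list(model = fit,
                 importance = fit$variable.importance,
                 predictions_oob = fit$predictions),
            class = "rf_fit")
}

#' Permutation p-values for random-forest feature importance
#'
#' For each permutation the target is randomly shuffled and the forest refit,
#' giving a per-feature null distribution of impurity importances; each
#' feature's add-one p-value is
#' \eqn{p_j = (1 + \#\{I_j^{null} \ge I_j^{obs}\}) / (1 + n_{perm})}.
#'
#' @param X complete numeric matrix or data.frame of predictors.
#' @param y numeric target.
#' @param n_perm number of permutations (default 300).
#' @param settings a [run_config()] with the forest settings.
#' @param seed seed for both the permutations and the forests.
#' @return Named numeric vector of p-values in (0, 1], one per feature.
#' @export
rf_permutation_pvalues <- function(X, y, n_perm = 300L,
                                   settings = run_config(), seed = 1L) {
  if (n_perm < 1L) stop("rf_permutation_pvalues: n_perm must be >= 1")
  obs <- rf_fit_predict(X, y, settings, seed = seed)$importance
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(k) sample.int(length(y)))
  })
  exceed <- numeric(length(obs))
  for (k in seq_len(n_perm)) {
    null_imp <- rf_fit_predict(X, y[perms[[k]]], settings,
                               seed = child_seed(seed, paste0("perm", k))
    )$importance
    exceed <- exceed + (null_imp >= obs)
  }
  stats::setNames((1 + exceed) / (1 + n_perm), names(obs))
}
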