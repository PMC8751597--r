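#' Union selection of activities across methods and age groups
#'
#' An activity is selected if it is significant at level `alpha` in at least
#' one age group by at least one method, i.e. if the minimum over both
#' p-value matrices and all groups is at or below `alpha` (the comparison is
#' inclusive: a p-value printed as .05 counts as significant at .05). One
#' union set is returned and used for every age group downstream.
#'
#' @param p_dcor,p_rf numeric activity-by-age-group p-value matrices with
#'   identical row and column names.
#' @param alpha significance level (default 0.05).
#' @return An object of class `feature_selection`: list with `p_dcor`,
#'   `p_rf`, `p_min` (elementwise minimum), `alpha`, and `selected`
#'   (character vector of activity keys, in catalogue order).
#' @export
select_features <- function(p_dcor, p_rf, alpha = 0.05) {
  if (!identical(dim(p_dcor), dim(p_rf)) ||
      !identical(dimnames(p_dcor), dimnames(p_rf))) {
    stop("select_features: p-value matrices must have identical dimnames")
  }
  if (any(p_dcor <= 0 | p_dcor > 1, na.rm = TRUE) ||
      any(p_rf <= 0 | p_rf > 1, na.rm = TRUE)) {
    stop("select_features: p-values must lie in (0, 1]")
  }
  p_min <- pmin(p_dcor, p_rf)
  min_over_groups <- apply(p_min, 1, min)
  selected <- rownames(p_dcor)[min_over_groups <= alpha + 1e-12]
  structure(list(p_dcor = p_dcor, p_rf = p_rf, p_min = p_min,
                 alpha = alpha, selected = selected),
            class = "feature_selection")
}

#' Stage-1 screening of activities against memory change
#'
#' Runs both screening tests per age group: the distance-correlation
#' permutation test of each activity against memory change (pairwise), and
#' the random-forest permutation importance test with all activities plus
#' education and baseline memory as predictors (p-values retained for the
#' activity features). The two activity-by-age-group p-value matrices are
#' then combined by [select_features()]. Every test draws its own child seed
#' from the config's master seed. In total `33 x 5` distance-correlation
#' tests and `5` forest permutation tests are performed; no multiple-testing
#' correction is applied (the union rule is the selection criterion).
#'
#' @param tables named list of [analysis_table()]s holding all 33 activities
#'   (as from `build_tables(records, activity_catalog()$key)`).
#' @param cfg a [run_config()].
#' @return A `feature_selection` object.
#' @export
screen_activities <- function(tables, cfg = run_config()) {
  groups <- names(tables)
  acts <- tables[[1]]$feature_names[seq_len(tables[[1]]$n_activities)]
  p_dcor <- matrix(NA_real_, length(acts), length(groups),
                   dimnames = list(acts, groups))
  p_rf <- p_dcor
  for (g in groups) {
    tab <- tables[[g]]
    log_info("screen", "age group ", g, ": dCor tests on ", length(acts),
             " activities (", cfg$n_resamples_dcor, " resamples)")
    for (a in acts) {
      p_dcor[a, g] <- dcor_resample_test(
        tab$X[, a], tab$y, n_resamples = cfg$n_resamples_dcor,
        seed = child_seed(cfg$seed, paste0("dcor-", g, "-", a)))
    }
    log_info("screen", "age group ", g, ": RF permutation test (",
             cfg$n_perm_rf, " permutations)")
    prf <- rf_permutation_pvalues(
      tab$X, tab$y, n_perm = cfg$n_perm_rf, settings = cfg,
      seed = child_seed(cfg$seed, paste0("rf-", g)))
    p_rf[, g] <- prf[acts]
  }
  select_features(p_dcor, p_rf, cfg$alpha)
}
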