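#' Run configuration for the two-step importance pipeline
#'
#' Collects every tunable count, fraction and threshold used by the pipeline
#' stages. Defaults follow the study conditions: permutation/resampling tests
#' on ~300 samples, 200 sensitivity-analysis repetitions per age group,
#' 80/20 holdout repeated 100 times, selection at the 95% confidence level,
#' and a 15% per-record missingness cap.
#'
#' @param alpha significance level for activity selection (default 0.05).
#' @param n_resamples_dcor permutation resamples for the distance-correlation
#'   test (default 300).
#' @param n_perm_rf permutations for the random-forest importance test
#'   (default 300).
#' @param n_reps_sa sensitivity-analysis repetitions per age group
#'   (default 200).
#' @param sa_levels number of probe levels per feature in the sensitivity
#'   analysis (default 7, the maximum ordinal category count, so ordinal
#'   features are probed exactly on their categories).
#' @param sa_measure dispersion measure over probe-level mean predictions:
#'   `"variance"` (default) or `"range"`.
#' @param sa_regrid if `TRUE`, rerun the kernel-width grid search on every
#'   subsample repetition; if `FALSE` (default) the grid search is run once
#'   per age group and repetitions refit the SVR with the selected
#'   hyper-parameters.
#' @param sa_refit if `TRUE` (default) every repetition refits the SVR on its
#'   subsample; if `FALSE` the model is fit once per age group and the
#'   repetitions only resample the reference matrix fed to the sensitivity
#'   probes (the cheaper variant of the repetition scheme).
#' @param subsample_fraction fraction of rows drawn (without replacement) for
#'   each sensitivity-analysis repetition (default 0.8).
#' @param r2_split training fraction for holdout R-squared estimation
#'   (default 0.8).
#' @param r2_repeats holdout repetitions (default 100).
#' @param rf_num_trees trees per random forest (default 500).
#' @param rf_min_node minimum terminal node size (default 5).
#' @param rf_mtry features tried per split; `NULL` means `ceiling(p/3)`.
#' @param svr_grid_size number of Gaussian kernel-width candidates
#'   (default 10).
#' @param svr_val_fraction inner validation fraction for kernel-width
#'   selection (default 1/3).
#' @param missingness_threshold per-record missing-data cap (default 0.15).
#' @param seed master seed; every stage derives its own child seed from it
#'   via [child_seed()].
#' @return An object of class `run_config` (a validated named list).
#' @export
#' @examples
#' cfg <- run_config(seed = 42)
#' cfg$alpha
run_config <- function(alpha = 0.05,
                       n_resamples_dcor = 300L,
                       n_perm_rf = 300L,
                       n_reps_sa = 200L,
                       sa_levels = 7L,
                       sa_measure = c("variance", "range"),
                       sa_regrid = FALSE,
                       sa_refit = TRUE,
                       subsample_fraction = 0.8,
                       r2_split = 0.8,
                       r2_repeats = 100L,
                       rf_num_trees = 500L,
                       rf_min_node = 5L,
                       rf_mtry = NULL,
                       svr_grid_size = 10L,
                       svr_val_fraction = 1 / 3,
                       missingness_threshold = 0.15,
                       seed = 1L) {
  sa_measure <- match.arg(sa_measure)
  cfg <- list(
    alpha = alpha,
    n_resamples_dcor = as.integer(n_resamples_dcor),
    n_perm_rf = as.integer(n_perm_rf),
    n_reps_sa = as.integer(n_reps_sa),
    sa_levels = as.integer(sa_levels),
    sa_measure = sa_measure,
    sa_regrid = isTRUE(sa_regrid),
    sa_refit = isTRUE(sa_refit),
    subsample_fraction = subsample_fraction,
    r2_split = r2_split,
    r2_repeats = as.integer(r2_repeats),
    rf_num_trees = as.integer(rf_num_trees),
    rf_min_node = as.integer(rf_min_node),
    rf_mtry = if (is.null(rf_mtry)) NULL else as.integer(rf_mtry),
    svr_grid_size = as.integer(svr_grid_size),
    svr_val_fraction = svr_val_fraction,
    missingness_threshold = missingness_threshold,
    seed = as.integer(seed)
  )
  counts <- c("n_resamples_dcor", "n_perm_rf", "n_reps_sa", "sa_levels",
              "r2_repeats", "rf_num_trees", "rf_min_node", "svr_grid_size")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("run_config: '", nm, "' must be a positive count")
  }
  fracs <- c("subsample_fraction", "r2_split", "svr_val_fraction",
             "missingness_threshold")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("run_config: '", nm, "' must lie in (0, 1)")
    }
  }
  if (cfg$alpha < 0 || cfg$alpha >= 1) stop("run_config: 'alpha' must lie in [0, 1)")
  if (cfg$sa_levels < 2L) stop("run_config: 'sa_levels' must be >= 2")
  class(cfg) <- "run_config"
  cfg
}

#' Reduced-count smoke profile
#'
#' A light configuration for quick end-to-end runs and continuous testing:
#' 50 permutations per test, 50 sensitivity repetitions, 200 forest trees,
#' 20 holdout repeats. Intended to be paired with small synthetic cohorts
#' (around 200 participants per age group).
#'
#' @param seed master seed.
#' @param ... overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
smoke_profile <- function(seed = 1L, ...) {
  args <- list(
    n_resamples_dcor = 50L, n_perm_rf = 50L, n_reps_sa = 50L,
    rf_num_trees = 200L, r2_repeats = 20L, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(run_config, args)
}

#' Read a run configuration from a YAML file
#'
#' The file holds a flat mapping whose keys are the arguments of
#' [run_config()]; absent keys take their defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Derive a per-stage child seed from the master seed
#'
#' Stages draw their randomness from seeds derived deterministically from the
#' master seed and the stage name, so any stage can be re-run in isolation.
#' The scheme is a 31-ary polynomial hash of the stage name added to the
#' master seed, reduced modulo 2^31 - 1.
#'
#' @param master master seed (integer).
#' @param stage stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "feature-selection")
child_seed <- function(master, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) + h) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(list = ".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Timestamped, stage-tagged log line to stderr and (if set) the run log file.
log_info <- function(stage, ...) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, paste0(...))
  message(line)
  logfile <- getOption("memtrend.log_file")
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
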