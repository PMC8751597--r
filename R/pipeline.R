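#' Run the full two-step analysis pipeline
#'
#' Orchestrates the stages as one reproducible run: ingest (read a cohort
#' CSV, or simulate one from a [trend_preset()]), preprocessing, stage-1
#' activity screening, stage-2 repeated sensitivity-analysis importance with
#' holdout accuracy, and stage-3 trend tests for the combined-activity,
#' education, and baseline-memory series. Every stage artifact is written to
#' `out_dir` as delimited text plus a structured JSON summary (see
#' [write_report()]) together with a `manifest.json` holding the config echo,
#' seeds, stage timings, and record counts at each filter. Reruns with the
#' same config and seed produce numerically identical stage artifacts.
#'
#' If no activity survives selection (e.g. `alpha = 0`), stage 2 runs on
#' education and baseline memory only and a warning is logged; the
#' combined-activity series is then identically zero and its trend tests are
#' reported as `NA`.
#'
#' @param config a [run_config()].
#' @param input path to a cohort CSV (takes precedence over `preset`).
#' @param preset a [trend_preset()] direction name, or a ready
#'   `synthetic_config`.
#' @param n_per_group optional per-group sizes for the simulated cohort.
#' @param out_dir output directory.
#' @param schema optional column schema for [read_cohort()].
#' @return Invisibly, a list with `manifest`, `counts`, `selection`,
#'   `importance`, `holdout_r2`, `trend`, and `timings`.
#' @export
run_pipeline <- function(config = run_config(), input = NULL,
                         preset = "paper-like", n_per_group = NULL,
                         out_dir, schema = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_log <- getOption("memtrend.log_file")
  options(memtrend.log_file = file.path(out_dir, "run.log"))
  on.exit(options(memtrend.log_file = old_log))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[3] - t0, 2)
    res
  }

  truth <- NULL
  records <- clock("ingest", {
    if (!is.null(input)) {
      log_info("ingest", "reading cohort from ", input)
      read_cohort(input, schema = schema)
    } else {
      syn_cfg <- if (inherits(preset, "synthetic_config")) {
        preset
      } else {
        trend_preset(preset, n_per_group = n_per_group,
                     seed = child_seed(config$seed, "simulate"))
      }
      log_info("ingest", "simulating '",
               attr(syn_cfg, "preset") %||% "custom", "' cohort (",
               sum(syn_cfg$n_per_group), " participants)")
      cohort <- generate_cohort(syn_cfg)
      truth <<- attr(cohort, "ground_truth")
      cohort
    }
  })

  pp <- clock("preprocess", {
    log_info("preprocess", "filtering and imputing ", nrow(records), " records")
    preprocess_cohort(records, config)
  })

  selection <- clock("feature_selection", {
    tables_all <- build_tables(pp$records, activity_catalog()$key)
    screen_activities(tables_all, config)
  })
  if (length(selection$selected) == 0L) {
    warning("run_pipeline: no activity selected; stage 2 runs on education ",
            "and baseline memory only", call. = FALSE)
    log_info("feature_selection", "WARNING: empty selection")
  } else {
    log_info("feature_selection", length(selection$selected),
             " activities selected")
  }

  stage2 <- clock("importance", {
    tables_sel <- build_tables(pp$records, selection$selected)
    imp <- lapply(tables_sel, importance_distribution, cfg = config)
    r2 <- vapply(tables_sel, function(tab) {
      holdout_r2(tab, config)$mean
    }, numeric(1))
    list(importance = imp, holdout_r2 = r2)
  })
  log_info("importance", "mean holdout R2 across groups: ",
           sprintf("%.3f", mean(stage2$holdout_r2)))

  trend <- clock("trend", {
    imp <- stage2$importance
    series_of <- function(extract, name) {
      trend_summary(lapply(imp, extract), series_name = name)
    }
    list(
      combined_activities = series_of(
        function(d) d$combined_activity, "combined_activities"),
      education = series_of(
        function(d) d$values[, "education_years"], "education"),
      baseline_memory = series_of(
        function(d) d$values[, "baseline_memory"], "baseline_memory")
    )
  })

  manifest <- clock("report", {
    write_report(list(selection = selection, importance = stage2$importance,
                      trend = trend, holdout_r2 = stage2$holdout_r2,
                      config = config, truth = truth),
                 out_dir)
  })
  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed, counts = pp$counts,
         n_selected = length(selection$selected),
         stage_timings_sec = timings,
         artifacts = manifest$file),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  log_info("report", "wrote ", nrow(manifest) + 1L, " artifacts to ", out_dir)

  invisible(list(manifest = manifest, counts = pp$counts,
                 selection = selection, importance = stage2$importance,
                 holdout_r2 = stage2$holdout_r2, trend = trend,
                 timings = timings))
}

# Naive O(n^2) distance correlation straight from the double-centering
# definition; reference implementation for self-checks.
dcor_reference <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
      B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
    }
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

#' Pipeline self-test
#'
#' Runs a battery of fast internal checks: the distance-correlation
#' implementation against a naive double-centering reference, importance
#' normalization and degeneracy on analytic stand-in models, a reduced-count
#' null-calibration smoke test of the distance-correlation permutation test,
#' and a reduced-scale "paper-like" trend-recovery run. Failures are reported
#' in the returned table, not raised.
#'
#' @param out_dir optional directory; when given, a structured JSON report is
#'   written there.
#' @param dcor_impl the distance-correlation function to check (exposed so a
#'   deliberately corrupted implementation can be shown to fail the oracle
#'   check).
#' @param seed seed for the checks.
#' @return Data.frame with columns `check`, `tolerance`, `pass`.
#' @export
selftest <- function(out_dir = NULL, dcor_impl = distance_correlation,
                     seed = 1L) {
  checks <- list()
  add <- function(check, tolerance, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, tolerance = tolerance, pass = isTRUE(pass),
      stringsAsFactors = FALSE)
  }

  # distance-correlation oracle
  ok <- with_seed(child_seed(seed, "selftest-dcor"), {
    all(vapply(1:20, function(k) {
      n <- sample(3:20, 1)
      x <- stats::rnorm(n)
      y <- if (k %% 2) stats::rnorm(n) else x^2 + stats::rnorm(n, 0, 0.1)
      abs(dcor_impl(x, y) - dcor_reference(x, y)) < 1e-10
    }, logical(1)))
  })
  add("distance correlation matches naive double-centering reference",
      "1e-10 on 20 random pairs, n in 3..20", ok)

  # importance normalization and degeneracy on analytic models
  Xr <- with_seed(child_seed(seed, "selftest-sa"),
                  matrix(stats::rnorm(200 * 3), 200, 3,
                         dimnames = list(NULL, c("f1", "f2", "f3"))))
  r1 <- sa_importance(fn_model(function(X) X[, 1]), Xr, L = 7)
  add("single-active-feature model concentrates importance",
      "r = (1, 0, 0) exactly", all(abs(r1 - c(1, 0, 0)) < 1e-12))
  Xs <- Xr
  Xs[, 2] <- Xs[, 1]  # identical probe grids for the two active features
  r2 <- sa_importance(fn_model(function(X) X[, 1] + X[, 2]), Xs, L = 7)
  add("symmetric two-feature model splits importance evenly",
      "|r1 - r2| < 1e-6 and r3 = 0",
      abs(r2[1] - r2[2]) < 1e-6 && r2[3] < 1e-12)
  add("importance normalization", "sum = 1 +/- 1e-9",
      abs(sum(r1) - 1) < 1e-9 && abs(sum(r2) - 1) < 1e-9)

  # null-calibration smoke test for the dCor permutation test
  rate <- with_seed(child_seed(seed, "selftest-null"), {
    mean(vapply(1:60, function(k) {
      x <- stats::rnorm(120)
      y <- stats::rnorm(120)
      dcor_resample_test(x, y, n_resamples = 60,
                         seed = child_seed(seed, paste0("st-null-", k))) <= 0.05
    }, logical(1)))
  })
  add("dCor permutation test null rejection rate near nominal",
      "rate in [0, 0.13] at alpha = 0.05, 60 null pairs", rate <= 0.13)

  # reduced-scale trend recovery
  run_dir <- file.path(tempdir(), paste0("memtrend-selftest-", seed))
  res <- run_pipeline(
    smoke_profile(seed = seed, n_perm_rf = 25L, n_reps_sa = 12L,
                  rf_num_trees = 150L, n_resamples_dcor = 40L,
                  r2_repeats = 5L),
    preset = "paper-like", n_per_group = rep(150L, 5), out_dir = run_dir)
  cm <- res$trend$combined_activities$means
  add("paper-like preset: combined-activity importance rises with age",
      "oldest group mean > youngest group mean and rank correlation >= 0.6",
      cm[5] > cm[1] && res$trend$combined_activities$rank_correlation >= 0.6)
  bm <- res$trend$baseline_memory$means
  add("paper-like preset: baseline-memory importance falls with age",
      "oldest group mean < youngest group mean", bm[5] < bm[1])

  report <- do.call(rbind, checks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "selftest_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
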