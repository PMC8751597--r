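#' Read a participant cohort from a delimited text file
#'
#' Ingests a comma-separated, UTF-8, header-row participant table into the
#' pipeline's canonical cohort form: one row per participant with columns
#' `id`, `age_years`, `education_years`, the four 10-word recall counts
#' (`recall_immediate_w1`, `recall_delayed_w1`, `recall_immediate_w2`,
#' `recall_delayed_w2`) or precomputed 0-20 wave totals (`memory_w1`,
#' `memory_w2`), and the 33 ordinal activity columns named by
#' `activity_catalog()$key`.
#'
#' Arbitrary export dialects are mapped onto the canonical names through
#' `schema`, a named character vector `c(canonical = "file column", ...)`;
#' canonical names absent from `schema` are looked up under their own name.
#' Unparseable or out-of-range cells (recall counts outside 0-10, wave totals
#' outside 0-20, activity codes outside their declared category range,
#' education outside 0-30, age outside 0-120) become missing values, with one
#' logged warning per affected column. Row count is preserved: every input
#' row becomes a record.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to file column names.
#' @param exclusion_flag optional name of a file column marking records that
#'   failed the survey's testing procedure (interrupted interview, hearing
#'   problems, ...). The flag's semantics are supplied by the user: any
#'   nonzero/"true"/"yes" value marks the record, which is carried in an
#'   `excluded` column and dropped at the start of preprocessing.
#' @return A data.frame cohort (class `memtrend_cohort`), one row per
#'   participant; missing values are `NA`.
#' @export
read_cohort <- function(path, schema = NULL, exclusion_flag = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  cat33 <- activity_catalog()

  resolve <- function(canonical) {
    if (!is.null(schema) && canonical %in% names(schema)) schema[[canonical]] else canonical
  }
  required <- c("id", "age_years", "education_years", cat33$key)
  for (canonical in required) {
    if (!resolve(canonical) %in% names(raw)) {
      stop("schema error: required column '", canonical, "' (file column '",
           resolve(canonical), "') not found in ", path)
    }
  }
  has_components <- all(vapply(
    c("recall_immediate_w1", "recall_delayed_w1",
      "recall_immediate_w2", "recall_delayed_w2"),
    function(x) resolve(x) %in% names(raw), logical(1)))
  has_totals <- all(vapply(c("memory_w1", "memory_w2"),
                           function(x) resolve(x) %in% names(raw), logical(1)))
  if (!has_components && !has_totals) {
    stop("schema error: need either the four recall component columns ",
         "(recall_immediate_w1, ...) or the two wave totals (memory_w1, memory_w2)")
  }

  n <- nrow(raw)
  out <- data.frame(id = as.character(raw[[resolve("id")]]),
                    stringsAsFactors = FALSE)

  parse_int <- function(canonical, lo, hi) {
    v <- raw[[resolve(canonical)]]
    num <- suppressWarnings(as.numeric(v))
    bad_parse <- !is.na(v) & nzchar(trimws(v)) & is.na(num)
    val <- suppressWarnings(as.integer(round(num)))
    out_of_range <- !is.na(val) & (val < lo | val > hi)
    val[out_of_range] <- NA_integer_
    n_bad <- sum(bad_parse) + sum(out_of_range)
    if (n_bad > 0) {
      warning("read_cohort: ", n_bad, " unparseable/out-of-range cell(s) in '",
              canonical, "' set to missing", call. = FALSE)
    }
    val
  }

  out$age_years <- parse_int("age_years", 0L, 120L)
  out$education_years <- parse_int("education_years", 0L, 30L)
  if (has_components) {
    out$recall_immediate_w1 <- parse_int("recall_immediate_w1", 0L, 10L)
    out$recall_delayed_w1 <- parse_int("recall_delayed_w1", 0L, 10L)
    out$recall_immediate_w2 <- parse_int("recall_immediate_w2", 0L, 10L)
    out$recall_delayed_w2 <- parse_int("recall_delayed_w2", 0L, 10L)
  } else {
    out$recall_immediate_w1 <- NA_integer_
    out$recall_delayed_w1 <- NA_integer_
    out$recall_immediate_w2 <- NA_integer_
    out$recall_delayed_w2 <- NA_integer_
  }
  if (has_totals) {
    out$memory_w1 <- parse_int("memory_w1", 0L, 20L)
    out$memory_w2 <- parse_int("memory_w2", 0L, 20L)
  } else {
    out$memory_w1 <- NA_integer_
    out$memory_w2 <- NA_integer_
  }
  for (i in seq_len(nrow(cat33))) {
    out[[cat33$key[i]]] <- parse_int(cat33$key[i], 0L, cat33$n_levels[i] - 1L)
  }
  if (!is.null(exclusion_flag)) {
    if (!exclusion_flag %in% names(raw)) {
      stop("schema error: exclusion-flag column '", exclusion_flag,
           "' not found in ", path)
    }
    v <- tolower(trimws(raw[[exclusion_flag]]))
    out$excluded <- v %in% c("1", "true", "yes", "y")
  }
  stopifnot(nrow(out) == n)
  class(out) <- c("memtrend_cohort", "data.frame")
  out
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: writes the canonical cohort columns as CSV
#' (UTF-8, header row, missing values as empty cells). Writing then reading a
#' cohort reproduces all non-missing values exactly.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write pipeline reports to a directory
#'
#' Emits every stage result as delimited text plus one structured JSON run
#' summary: the activity-by-age-group p-value matrices with entries at or
#' below the significance level flagged (mirroring a bold-entry selection
#' table), per-group importance means and standard errors with the
#' repetition-level values, the trend test tables, and a config/seed echo.
#' Given the same inputs the outputs are byte-identical across reruns.
#'
#' @param results a named list with any of: `selection` (a
#'   `feature_selection` object), `importance` (named list of
#'   `importance_distribution` by age group), `trend` (named list of
#'   `trend_summary`), `holdout_r2` (named numeric by age group), `config`
#'   (a `run_config`), `truth` (synthetic ground-truth list).
#' @param out_dir output directory; created if needed.
#' @return A data.frame manifest (`file`, `description`), invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("write_report: output directory is not writable: ", out_dir)
  }
  manifest <- list()
  add <- function(file, description) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, description = description, stringsAsFactors = FALSE)
  }

  sel <- results$selection
  if (!is.null(sel)) {
    flag <- function(p) ifelse(is.na(p), NA, p <= sel$alpha + 1e-12)
    wr <- function(mat, name, desc) {
      df <- data.frame(activity = rownames(mat), mat, check.names = FALSE,
                       stringsAsFactors = FALSE)
      fl <- flag(mat)
      colnames(fl) <- paste0("sig_", colnames(mat))
      df <- cbind(df, as.data.frame(fl, check.names = FALSE))
      f <- file.path(out_dir, name)
      utils::write.csv(df, f, row.names = FALSE, na = "")
      add(name, desc)
    }
    wr(sel$p_dcor, "selection_pvalues_dcor.csv",
       "distance-correlation permutation p-values per activity and age group")
    wr(sel$p_rf, "selection_pvalues_rf.csv",
       "random-forest permutation p-values per activity and age group")
    wr(pmin(sel$p_dcor, sel$p_rf), "selection_pvalues_min.csv",
       "elementwise minimum p-value across the two methods")
    f <- file.path(out_dir, "selected_activities.csv")
    utils::write.csv(
      data.frame(activity = sel$selected, stringsAsFactors = FALSE),
      f, row.names = FALSE)
    add("selected_activities.csv", "activities selected at the union rule")
  }

  imp <- results$importance
  if (!is.null(imp)) {
    if (length(imp) == 0L || all(vapply(imp, function(d) ncol(d$values) == 0L,
                                        logical(1)))) {
      warning("write_report: importance results are empty", call. = FALSE)
    }
    summ <- do.call(rbind, lapply(names(imp), function(g) {
      s <- imp[[g]]$summary
      cbind(data.frame(age_group = g, stringsAsFactors = FALSE), s)
    }))
    f <- file.path(out_dir, "importance_summary.csv")
    utils::write.csv(summ %||% data.frame(), f, row.names = FALSE)
    add("importance_summary.csv",
        "per-group mean and standard error of relative importances")
    for (g in names(imp)) {
      d <- imp[[g]]
      df <- as.data.frame(d$values, check.names = FALSE)
      df$combined_activity <- d$combined_activity
      name <- paste0("importance_reps_", gsub("-", "_", g), ".csv")
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
      add(name, paste0("repetition-level relative importances, age group ", g))
    }
  }

  trend <- results$trend
  if (!is.null(trend)) {
    tr <- do.call(rbind, lapply(trend, function(t) {
      data.frame(series = t$series_name, F = t$F, p_anova = t$p_anova,
                 rank_correlation = t$rank_correlation,
                 relative_change = t$relative_change,
                 stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "trend_tests.csv")
    utils::write.csv(tr, f, row.names = FALSE, na = "")
    add("trend_tests.csv",
        "ANOVA, rank correlation and youngest-to-oldest relative change per series")
    pw <- do.call(rbind, lapply(trend, function(t) {
      if (is.null(t$tukey)) return(NULL)
      cbind(data.frame(series = t$series_name, stringsAsFactors = FALSE), t$tukey)
    }))
    if (!is.null(pw)) {
      utils::write.csv(pw, file.path(out_dir, "trend_pairwise.csv"),
                       row.names = FALSE, na = "")
      add("trend_pairwise.csv", "Tukey HSD pairwise comparisons per series")
    }
    means <- do.call(rbind, lapply(trend, function(t) {
      data.frame(series = t$series_name, age_group = names(t$means),
                 mean = unname(t$means), stringsAsFactors = FALSE)
    }))
    utils::write.csv(means, file.path(out_dir, "trend_group_means.csv"),
                     row.names = FALSE)
    add("trend_group_means.csv", "group-mean importance per series")
  }

  if (!is.null(results$holdout_r2)) {
    utils::write.csv(
      data.frame(age_group = names(results$holdout_r2),
                 mean_r2 = unname(results$holdout_r2), stringsAsFactors = FALSE),
      file.path(out_dir, "holdout_r2.csv"), row.names = FALSE)
    add("holdout_r2.csv", "mean holdout R-squared per age group")
  }

  summary <- list(
    config = if (!is.null(results$config)) unclass(results$config) else NULL,
    n_selection_tests = if (!is.null(sel)) 2L * length(sel$p_dcor) else NULL,
    seed = results$config$seed,
    ground_truth = results$truth,
    selected = sel$selected,
    files = vapply(manifest, function(m) m$file, character(1))
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  add("run_summary.json", "structured run summary: config echo, seeds, artifacts")

  manifest <- do.call(rbind, manifest)
  invisible(manifest)
}
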