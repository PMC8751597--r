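#' Total memory score from the two recall components
#'
#' The memory score is the sum of words correctly remembered in the immediate
#' and delayed 10-word recall tests, ranging 0-20. Missing components
#' propagate to a missing score.
#'
#' @param immediate,delayed integer vectors of recall counts in 0-10.
#' @return Integer vector of totals in 0-20 (`NA` where a component is
#'   missing).
#' @export
#' @examples
#' compute_memory_score(7, 4)
compute_memory_score <- function(immediate, delayed) {
  chk <- function(v, nm) {
    bad <- !is.na(v) & (v < 0 | v > 10)
    if (any(bad)) stop("compute_memory_score: '", nm, "' outside 0-10")
  }
  chk(immediate, "immediate"); chk(delayed, "delayed")
  as.integer(immediate + delayed)
}

#' Memory change between waves
#'
#' Follow-up minus baseline memory score, so negative values mean decline.
#'
#' @param score_w1,score_w2 integer memory totals in 0-20 (baseline and
#'   follow-up waves).
#' @return Integer vector in -20..20.
#' @export
#' @examples
#' compute_memory_change(12, 9)  # declined by 3 words
compute_memory_change <- function(score_w1, score_w2) {
  chk <- function(v, nm) {
    bad <- !is.na(v) & (v < 0 | v > 20)
    if (any(bad)) stop("compute_memory_change: '", nm, "' outside 0-20")
  }
  chk(score_w1, "score_w1"); chk(score_w2, "score_w2")
  as.integer(score_w2 - score_w1)
}

#' Assign ages to 5-year age groups
#'
#' Inclusive binning into the five bins 65-69 .. 85-89. Ages outside 65-89
#' map to `NA` (the out-of-range signal; such records are excluded upstream).
#'
#' @param age_years integer vector of ages.
#' @return Factor with levels `age_groups()`, `NA` for out-of-range ages.
#' @export
#' @examples
#' assign_age_group(c(65, 69, 85, 90))
assign_age_group <- function(age_years) {
  cut(age_years, breaks = c(64.5, 69.5, 74.5, 79.5, 84.5, 89.5),
      labels = age_groups())
}

# Number of missing tracked cells per record: 33 activities + education +
# the two wave memory scores (36 cells total).
missing_cell_count <- function(records) {
  cat33 <- activity_catalog()
  cells <- cbind(
    is.na(as.matrix(records[cat33$key])),
    education = is.na(records$education_years),
    memory_w1 = is.na(records$memory_w1),
    memory_w2 = is.na(records$memory_w2)
  )
  rowSums(cells)
}

#' Drop records with too much missing data
#'
#' A record is dropped if and only if its missing fraction across the 36
#' tracked cells (33 activities, education, and the two wave memory scores)
#' exceeds `threshold`. Retention order is preserved.
#'
#' @param records a cohort data.frame (with `memory_w1`/`memory_w2` columns).
#' @param threshold maximum tolerated missing fraction, in (0, 1);
#'   default 0.15.
#' @return The retained records.
#' @export
filter_missingness <- function(records, threshold = 0.15) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- missing_cell_count(records) / 36
  records[frac <= threshold, , drop = FALSE]
}

#' Median imputation of activity and education cells
#'
#' Every missing activity or education cell is replaced by that variable's
#' median across participants with observed values, rounded to the nearest
#' valid ordinal category (ties round half up) and clamped into the
#' variable's category range. Wave memory scores are never imputed.
#'
#' @param records a cohort data.frame.
#' @return The completed records (idempotent: a second application is a
#'   no-op).
#' @export
impute_median <- function(records) {
  cat33 <- activity_catalog()
  round_half_up <- function(x) floor(x + 0.5)
  for (i in seq_len(nrow(cat33))) {
    key <- cat33$key[i]
    v <- records[[key]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0L) stop("impute_median: variable '", key,
                                  "' has no observed values")
      m <- round_half_up(stats::median(obs))
      m <- min(max(m, 0L), cat33$n_levels[i] - 1L)
      v[is.na(v)] <- as.integer(m)
      records[[key]] <- v
    }
  }
  v <- records$education_years
  if (anyNA(v)) {
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) stop("impute_median: variable 'education_years' ",
                                "has no observed values")
    v[is.na(v)] <- as.integer(round_half_up(stats::median(obs)))
    records$education_years <- v
  }
  records
}

#' Full preprocessing chain
#'
#' Applies, in order: wave memory-score construction (component sums where
#' the components are present, otherwise any precomputed totals), exclusion
#' of records lacking either wave's score (the change target cannot be
#' formed), age-range filtering and 5-year binning, the per-record
#' missing-data cap, and median imputation; finally computes the memory
#' change. Medians are computed over the full retained sample, not per age
#' group.
#'
#' @param records a cohort data.frame from [read_cohort()] or
#'   [generate_cohort()].
#' @param cfg a [run_config()] (supplies the missingness threshold).
#' @return A list with `records` (complete, with `age_group` and
#'   `memory_change` columns) and `counts` (record counts after each step).
#' @export
preprocess_cohort <- function(records, cfg = run_config()) {
  counts <- list(input = nrow(records))
  if (!is.null(records$excluded)) {
    records <- records[!records$excluded, , drop = FALSE]
    counts$after_exclusion_flag <- nrow(records)
  }
  comp_ok <- !is.na(records$recall_immediate_w1) & !is.na(records$recall_delayed_w1)
  records$memory_w1 <- ifelse(
    comp_ok, compute_memory_score(records$recall_immediate_w1,
                                  records$recall_delayed_w1),
    records$memory_w1)
  comp_ok2 <- !is.na(records$recall_immediate_w2) & !is.na(records$recall_delayed_w2)
  records$memory_w2 <- ifelse(
    comp_ok2, compute_memory_score(records$recall_immediate_w2,
                                   records$recall_delayed_w2),
    records$memory_w2)

  records <- records[!is.na(records$memory_w1) & !is.na(records$memory_w2), ,
                     drop = FALSE]
  counts$with_both_waves <- nrow(records)

  records$age_group <- assign_age_group(records$age_years)
  records <- records[!is.na(records$age_group), , drop = FALSE]
  counts$in_age_range <- nrow(records)

  records <- filter_missingness(records, cfg$missingness_threshold)
  counts$after_missingness_filter <- nrow(records)

  records <- impute_median(records)
  records$memory_change <- compute_memory_change(records$memory_w1,
                                                 records$memory_w2)
  counts$final <- nrow(records)
  list(records = records, counts = counts)
}

#' Construct an analysis table directly
#'
#' Low-level constructor for the per-age-group design used by the importance
#' stage: a complete numeric predictor matrix whose columns are ordered as
#' activities first, then education, then baseline memory, with the memory
#' change as target.
#'
#' @param age_group age-group label.
#' @param feature_names ordered character vector of column names.
#' @param X numeric matrix, `n x length(feature_names)`.
#' @param y numeric target vector of length `n`.
#' @param n_activities how many leading columns of `X` are activities;
#'   defaults to `ncol(X) - 2` (education and baseline are always last).
#' @return An object of class `analysis_table`.
#' @export
analysis_table <- function(age_group, feature_names, X, y,
                           n_activities = length(feature_names) - 2L) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(feature_names), nrow(X) == length(y),
            nrow(X) > 0, !anyNA(X), !anyNA(y),
            n_activities >= 0L, n_activities <= ncol(X))
  colnames(X) <- feature_names
  structure(list(age_group = age_group, feature_names = feature_names,
                 X = X, y = as.numeric(y),
                 n_activities = as.integer(n_activities)),
            class = "analysis_table")
}

#' Build per-age-group analysis tables
#'
#' For each age group, assembles the numeric predictor matrix (selected
#' activities as their integer ordinal codes, then education years, then
#' baseline memory) and the memory-change target.
#'
#' @param records preprocessed, complete records from [preprocess_cohort()].
#' @param selected_features ordered character vector of selected activity
#'   keys (may be empty: the tables then hold education and baseline only).
#' @return Named list of [analysis_table()] objects, one per age group.
#' @export
build_tables <- function(records, selected_features) {
  stopifnot(!is.null(records$age_group), !is.null(records$memory_change))
  cat33 <- activity_catalog()
  bad <- setdiff(selected_features, cat33$key)
  if (length(bad)) stop("build_tables: unknown activities: ",
                        paste(bad, collapse = ", "))
  if (any(records$memory_change < -20 | records$memory_change > 20)) {
    stop("build_tables: memory change outside -20..20")
  }
  feats <- c(selected_features, "education_years", "baseline_memory")
  out <- list()
  for (g in age_groups()) {
    rows <- records[records$age_group == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("build_tables: no records in age group ", g)
    X <- cbind(as.matrix(rows[selected_features]),
               education_years = rows$education_years,
               baseline_memory = rows$memory_w1)
    storage.mode(X) <- "numeric"
    if (any(X[, "baseline_memory"] < 0 | X[, "baseline_memory"] > 20)) {
      stop("build_tables: baseline memory outside 0-20 in age group ", g)
    }
    out[[g]] <- analysis_table(g, feats, X, rows$memory_change,
                               n_activities = length(selected_features))
  }
  out
}
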