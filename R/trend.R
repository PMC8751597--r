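#' One-way analysis of variance across age groups
#'
#' Classical between/within mean-square F statistic with its F-distribution
#' tail probability, computed by [stats::aov()] on the stacked values. The
#' repetition values of one importance series per group are treated as the
#' samples; because repetitions within a group share underlying data
#' (overlapping subsamples), the resulting p-values characterize estimator
#' dispersion, not population-level inference.
#'
#' @param groups named list of numeric vectors (at least 2 groups, each with
#'   at least 2 values).
#' @return List with `F`, `p`, `df` (between/within degrees of freedom).
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2), b = c(2, 3), c = c(3, 4)))
anova_oneway <- function(groups) {
  check_groups(groups)
  df <- stack_groups(groups)
  a <- suppressWarnings(stats::anova(stats::lm(value ~ group, data = df)))
  ssb <- a[["Sum Sq"]][1]
  ssw <- a[["Sum Sq"]][2]
  eps <- 1e-12 * (sum(df$value^2) + .Machine$double.xmin)
  if (ssw <= eps) {
    stop("anova_oneway: F statistic undefined (zero within-group variance)")
  }
  F_stat <- a[["F value"]][1]
  p <- a[["Pr(>F)"]][1]
  if (ssb <= eps) {
    F_stat <- 0
    p <- 1
  }
  list(F = F_stat, p = p, df = a$Df)
}

#' Tukey honest significant difference pairwise comparisons
#'
#' All-pairs mean comparisons with family-wise error control via the
#' studentized range distribution, computed by [stats::TukeyHSD()] on the
#' one-way fit. For each pair the mean difference (second group minus first,
#' groups in their natural order), the pooled-variance standard error of the
#' difference, and the adjusted p-value are reported; five groups give the
#' full 10 rows.
#'
#' @param groups named list of numeric vectors (at least 2 groups, each with
#'   at least 2 values).
#' @return Data.frame with columns `group_a`, `group_b`, `mean_diff`, `se`,
#'   `lwr`, `upr`, `p_adj`; `choose(k, 2)` rows for `k` groups.
#' @export
tukey_hsd <- function(groups) {
  check_groups(groups)
  df <- stack_groups(groups)
  # internal hyphen-free labels: group names themselves may contain "-"
  labs <- paste0("g", seq_along(groups))
  df$glab <- factor(labs[as.integer(df$group)], levels = labs)
  fit <- stats::aov(value ~ glab, data = df)
  tk <- stats::TukeyHSD(fit)$glab
  msw <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  ns <- vapply(groups, length, integer(1))
  pairs <- utils::combn(seq_along(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    row <- tk[paste0(labs[j], "-", labs[i]), ]
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               mean_diff = unname(row["diff"]),
               se = sqrt(msw * (1 / ns[i] + 1 / ns[j])),
               lwr = unname(row["lwr"]), upr = unname(row["upr"]),
               p_adj = unname(row["p adj"]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 values")
  }
  invisible(TRUE)
}

stack_groups <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
}

#' Monotone-trend summary of an importance series across age groups
#'
#' For one importance series (combined activities, education, or baseline
#' memory) reports the per-group means, the Spearman rank correlation of the
#' group means with the age-group index (+1 for a strictly increasing trend,
#' 0 when the means are constant), the relative change from the youngest to
#' the oldest group mean `(oldest - youngest) / youngest`, and the ANOVA and
#' Tukey HSD results. Degenerate series (zero variance everywhere, e.g. an
#' empty activity set) yield `NA` test results with a warning instead of an
#' error.
#'
#' @param series named list mapping the five age groups to their
#'   per-repetition importance values, in age order.
#' @param series_name label for reports.
#' @return An object of class `trend_summary`.
#' @export
trend_summary <- function(series, series_name = "series") {
  stopifnot(length(series) == 5L)
  means <- vapply(series, mean, numeric(1))
  rank_cor <- if (stats::sd(means) == 0) {
    0
  } else {
    # exact Spearman against the group index: means are tie-free in practice,
    # so the closed form avoids returning 1 - eps for a monotone series
    r <- rank(means)
    n <- length(means)
    if (anyDuplicated(r)) {
      stats::cor(means, seq_len(n), method = "spearman")
    } else {
      1 - 6 * sum((r - seq_len(n))^2) / (n * (n^2 - 1))
    }
  }
  rel_change <- if (means[1] != 0) {
    unname((means[length(means)] - means[1]) / means[1])
  } else {
    NA_real_
  }
  an <- tryCatch(anova_oneway(series), error = function(e) {
    warning("trend_summary (", series_name, "): ", conditionMessage(e),
            call. = FALSE)
    list(F = NA_real_, p = NA_real_, df = c(NA, NA))
  })
  tk <- tryCatch(suppressWarnings(tukey_hsd(series)),
                 error = function(e) NULL)
  structure(list(series_name = series_name, means = means,
                 rank_correlation = rank_cor, relative_change = rel_change,
                 F = an$F, p_anova = an$p, tukey = tk,
                 group_values = series),
            class = "trend_summary")
}
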