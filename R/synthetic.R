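#' Configuration for the synthetic cohort generator
#'
#' Describes an HRS-like cohort with a known linear-additive ground truth.
#' Within each age group g the (pre-rounding) memory change is
#' \deqn{\Delta M = \mu_g + \alpha_g z(B) + \beta_g z(E) +
#'   \sum_j \gamma_{g,j} z(A_j) + \epsilon,\quad \epsilon \sim N(0, \sigma^2),}
#' where `z()` is within-group standardization, `B` the baseline memory total
#' (0-20), `E` education in years, and `A_j` the ordinal activity codes.
#' Standardized predictors make relative importance analytically
#' anticipatable: importance should rank with the squared coefficients.
#'
#' @param n_per_group named integer vector of participants per age group;
#'   defaults to the study group sizes 757, 840, 800, 518, 295.
#' @param mu named numeric, per-group mean memory change (recall points).
#' @param alpha named numeric, per-group baseline-memory coefficient.
#' @param beta named numeric, per-group education coefficient.
#' @param gamma 5 x 33 numeric matrix of activity coefficients (rows = age
#'   groups, columns = activity keys); zero for inactive activities.
#' @param noise_sd standard deviation of the additive noise (recall points).
#' @param missing_rate probability that any single activity or education cell
#'   is set missing (missing completely at random).
#' @param baseline_p named numeric, per-group mean success probability of the
#'   beta-binomial baseline-recall draw (declining with age).
#' @param baseline_dispersion beta-binomial concentration `a + b` of the
#'   per-participant recall probability; smaller values give wider,
#'   overdispersed recall distributions (real recall totals are far wider
#'   than a binomial). Default 2.
#' @param seed generator seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c("65-69" = 757L, "70-74" = 840L,
                                             "75-79" = 800L, "80-84" = 518L,
                                             "85-89" = 295L),
                             mu = c("65-69" = -0.4, "70-74" = -0.5,
                                    "75-79" = -0.6, "80-84" = -0.7,
                                    "85-89" = -0.8),
                             alpha = NULL,
                             beta = NULL,
                             gamma = NULL,
                             noise_sd = 0.3,
                             missing_rate = 0.05,
                             baseline_p = c("65-69" = 0.58, "70-74" = 0.54,
                                            "75-79" = 0.50, "80-84" = 0.46,
                                            "85-89" = 0.42),
                             baseline_dispersion = 2,
                             seed = 1L) {
  groups <- age_groups()
  cat33 <- activity_catalog()
  if (is.null(alpha)) alpha <- stats::setNames(rep(0, 5), groups)
  if (is.null(beta)) beta <- stats::setNames(rep(0, 5), groups)
  if (is.null(gamma)) {
    gamma <- matrix(0, 5, 33, dimnames = list(groups, cat33$key))
  }
  stopifnot(
    all(groups %in% names(n_per_group)), all(n_per_group > 0),
    all(groups %in% names(mu)), all(groups %in% names(alpha)),
    all(groups %in% names(beta)),
    identical(dim(gamma), c(5L, 33L)),
    noise_sd > 0, missing_rate >= 0, missing_rate < 1,
    all(groups %in% names(baseline_p)),
    all(baseline_p > 0 & baseline_p < 1),
    baseline_dispersion > 0
  )
  if (is.null(rownames(gamma))) rownames(gamma) <- groups
  if (is.null(colnames(gamma))) colnames(gamma) <- cat33$key
  cfg <- list(
    n_per_group = stats::setNames(as.integer(n_per_group[groups]), groups),
    mu = mu[groups], alpha = alpha[groups], beta = beta[groups],
    gamma = gamma[groups, cat33$key, drop = FALSE],
    noise_sd = noise_sd, missing_rate = missing_rate,
    baseline_p = baseline_p[groups],
    baseline_dispersion = baseline_dispersion, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Preset ground-truth trend configurations
#'
#' Returns a complete [synthetic_config()] encoding one of three ground
#' truths about how the combined daily-activity signal evolves across the
#' five age groups. Total signal variance is held at 2.5 in every group and
#' split between the combined activities, baseline memory (negative sign:
#' higher baseline, larger decline) and education (positive sign). For
#' `"paper-like"` the activity share rises across age groups
#' (`.05, .235, .42, .615, .81`) while the education share
#' (`.41, .315, .23, .145, .055`) and baseline share (the remainder,
#' `.54, .45, .35, .24, .135`) fall, so \eqn{\sum_j |\gamma_{g,j}|} strictly
#' increases while \eqn{|\alpha_g|} and \eqn{|\beta_g|} strictly decrease.
#' `"reversed"` flips the three share paths; `"null"` holds every group at
#' the middle group's shares (identical coefficient vectors in every group).
#' Eight activities carry the activity signal with fixed decaying weights.
#'
#' @param direction one of `"paper-like"`, `"null"`, `"reversed"`.
#' @param n_per_group optional named integer vector overriding group sizes
#'   (e.g. `rep(200, 5)` for smoke runs).
#' @param seed generator seed.
#' @return A `synthetic_config` with a `preset` attribute.
#' @export
#' @examples
#' cfg <- trend_preset("paper-like", seed = 7)
#' rowSums(abs(cfg$gamma))
trend_preset <- function(direction = c("paper-like", "null", "reversed"),
                         n_per_group = NULL, seed = 1L) {
  direction <- match.arg(direction)
  groups <- age_groups()
  cat33 <- activity_catalog()
  total_signal_var <- 2.5
  share_act <- c(0.05, 0.235, 0.42, 0.615, 0.81)
  share_edu <- c(0.41, 0.315, 0.23, 0.145, 0.055)
  if (direction == "reversed") {
    share_act <- rev(share_act)
    share_edu <- rev(share_edu)
  } else if (direction == "null") {
    share_act <- rep(share_act[3], 5)
    share_edu <- rep(share_edu[3], 5)
  }
  share_base <- 1 - share_act - share_edu
  active <- c("use_computer", "word_games", "read", "walk_20min",
              "sport_exercise", "meet_friends", "cards_games",
              "activities_grandchildren")
  w <- c(0.20, 0.18, 0.15, 0.13, 0.11, 0.09, 0.08, 0.06)
  u <- w / sqrt(sum(w^2))  # unit sum of squares

  alpha <- -sqrt(share_base * total_signal_var)
  beta <- sqrt(share_edu * total_signal_var)
  gamma <- matrix(0, 5, 33, dimnames = list(groups, cat33$key))
  for (g in 1:5) {
    gamma[g, active] <- sqrt(share_act[g] * total_signal_var) * u
  }

  args <- list(
    mu = stats::setNames(c(-0.4, -0.5, -0.6, -0.7, -0.8), groups),
    alpha = stats::setNames(alpha, groups),
    beta = stats::setNames(beta, groups),
    gamma = gamma, seed = seed
  )
  if (!is.null(n_per_group)) {
    if (is.null(names(n_per_group))) names(n_per_group) <- groups
    args$n_per_group <- n_per_group
  }
  cfg <- do.call(synthetic_config, args)
  attr(cfg, "preset") <- direction
  cfg
}

# Within-group standardization. The generator standardizes by the
# generating distribution's own (population) moments, not the sample's, so
# the ground-truth coefficients are seed-free quantities.
z_standardize <- function(v, mean, sd) {
  if (sd <= 0) return(rep(0, length(v)))
  (v - mean) / sd
}

# Population moments of the generator's predictor distributions for one
# age group: beta-binomial baseline recall, uniform education 8..20,
# uniform ordinal activities.
synthetic_moments <- function(cfg, group) {
  p <- cfg$baseline_p[[group]]
  rho <- 1 / (cfg$baseline_dispersion + 1)
  b_var <- 20 * p * (1 - p) * (1 + 19 * rho)
  cat33 <- activity_catalog()
  list(
    baseline = c(mean = 20 * p, sd = sqrt(b_var)),
    education = c(mean = 14, sd = sqrt((13^2 - 1) / 12)),
    activity_mean = (cat33$n_levels - 1) / 2,
    activity_sd = sqrt((cat33$n_levels^2 - 1) / 12)
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, for each age group: ages uniform within the bin; baseline recall
#' total `B` as a bounded integer in 0-20 from a beta-binomial (group mean
#' declining with age, overdispersed like real recall totals), split into
#' immediate/delayed components by a hypergeometric draw (each component at
#' most 10); education uniform integer in 8-20; 33 independent uniform
#' ordinal activity draws; memory change
#' `round(mu_g + alpha_g z(B) + beta_g z(E) + sum_j gamma_gj z(A_j) + eps)`
#' with Gaussian noise; follow-up total `clip(B + dM, 0, 20)` re-split into
#' components. Finally each activity/education cell is independently set
#' missing with probability `missing_rate`. The full coefficient ledger is
#' attached as attribute `"ground_truth"`.
#'
#' @param cfg a [synthetic_config()].
#' @return A cohort data.frame (as from [read_cohort()]) with attribute
#'   `ground_truth`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- age_groups()
  cat33 <- activity_catalog()
  bins <- list("65-69" = 65:69, "70-74" = 70:74, "75-79" = 75:79,
               "80-84" = 80:84, "85-89" = 85:89)
  with_seed(cfg$seed, {
    parts <- lapply(groups, function(g) {
      n <- cfg$n_per_group[[g]]
      age <- sample(bins[[g]], n, replace = TRUE)
      conc <- cfg$baseline_dispersion
      p_i <- stats::rbeta(n, cfg$baseline_p[[g]] * conc,
                          (1 - cfg$baseline_p[[g]]) * conc)
      B <- stats::rbinom(n, 20L, p_i)
      imm1 <- stats::rhyper(n, 10L, 10L, B)
      edu <- as.integer(sample(8:20, n, replace = TRUE))
      acts <- matrix(0L, n, 33, dimnames = list(NULL, cat33$key))
      for (j in seq_len(33)) {
        acts[, j] <- sample(0:(cat33$n_levels[j] - 1L), n, replace = TRUE)
      }
      mom <- synthetic_moments(cfg, g)
      signal <- cfg$mu[[g]] +
        cfg$alpha[[g]] * z_standardize(B, mom$baseline["mean"],
                                       mom$baseline["sd"]) +
        cfg$beta[[g]] * z_standardize(edu, mom$education["mean"],
                                      mom$education["sd"])
      for (j in seq_len(33)) {
        gcoef <- cfg$gamma[g, j]
        if (gcoef != 0) {
          signal <- signal + gcoef * z_standardize(acts[, j],
                                                   mom$activity_mean[j],
                                                   mom$activity_sd[j])
        }
      }
      dm <- as.integer(round(signal + stats::rnorm(n, 0, cfg$noise_sd)))
      w2 <- pmin(20L, pmax(0L, B + dm))
      imm2 <- stats::rhyper(n, 10L, 10L, w2)
      df <- data.frame(
        id = NA_character_, age_years = as.integer(age),
        education_years = edu,
        recall_immediate_w1 = as.integer(imm1),
        recall_delayed_w1 = as.integer(B - imm1),
        recall_immediate_w2 = as.integer(imm2),
        recall_delayed_w2 = as.integer(w2 - imm2),
        memory_w1 = as.integer(B), memory_w2 = as.integer(w2),
        stringsAsFactors = FALSE
      )
      cbind(df, as.data.frame(acts))
    })
    cohort <- do.call(rbind, parts)
    cohort$id <- sprintf("S%05d", seq_len(nrow(cohort)))
    # MCAR missingness on activity and education cells only
    if (cfg$missing_rate > 0) {
      for (col in c("education_years", cat33$key)) {
        miss <- stats::runif(nrow(cohort)) < cfg$missing_rate
        cohort[[col]][miss] <- NA_integer_
      }
    }
    class(cohort) <- c("memtrend_cohort", "data.frame")
    attr(cohort, "ground_truth") <- list(
      preset = attr(cfg, "preset"), mu = as.list(cfg$mu),
      alpha = as.list(cfg$alpha), beta = as.list(cfg$beta),
      gamma = cfg$gamma, noise_sd = cfg$noise_sd,
      missing_rate = cfg$missing_rate,
      n_per_group = as.list(cfg$n_per_group), seed = cfg$seed
    )
    cohort
  })
}

#' Generate a null cohort (no predictor effects)
#'
#' As [generate_cohort()] with all baseline, education and activity
#' coefficients forced to zero, so memory change is pure noise around the
#' group mean. Used for type-I-error calibration of the screening tests.
#'
#' @param cfg a [synthetic_config()]; its coefficients are ignored.
#' @return A cohort data.frame with a zero-coefficient ground-truth ledger.
#' @export
generate_null_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- age_groups()
  cfg$alpha[] <- 0
  cfg$beta[] <- 0
  cfg$gamma[] <- 0
  generate_cohort(cfg)
}
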