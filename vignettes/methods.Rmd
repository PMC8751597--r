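---
title: "Age-stratified importance of daily activities for memory change: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified importance of daily activities for memory change: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtrend)
```

## The estimand

For participants aged 65–89, split into five 5-year age groups, the pipeline
asks how much of the predictable variation in 6-year memory change
$\Delta M = B_{\text{follow-up}} - B_{\text{baseline}}$ (where $B$ is the
0–20 total of immediate plus delayed 10-word recall) is attributable to each
of three kinds of predictor: 33 ordinal daily-activity engagement levels,
years of education, and the baseline memory level itself — and how that
attribution changes with age. The answer is expressed as a *relative
importance*: a nonnegative share per predictor that sums to one within an
age group, with the activity shares additionally summed into a single
combined-activity importance.

## The two-step procedure

**Step 1 — screening.** Each activity is tested against $\Delta M$ per age
group two ways. The distance correlation
$\mathrm{dCor} = \mathrm{dCov}/\sqrt{\mathrm{dVar}_x\,\mathrm{dVar}_y}$,
computed from doubly-centered pairwise-distance matrices, is zero (in
population) only under independence, so it catches monotone and non-monotone
dependence alike; significance comes from a permutation null (300 resamples
by default) with the add-one estimate $p = (1 + \#\{T^{\text{null}} \ge
T^{\text{obs}}\})/(1 + R)$, which cannot be zero. In parallel, a regression
random forest is fit on all activities plus education and baseline memory,
and each feature's impurity importance is referred to its own permutation
null (the forest is refit on shuffled targets, 300 times by default).
An activity enters the model of Step 2 if *either* test is significant at
$\alpha = 0.05$ (inclusive) in *at least one* age group — a deliberately
liberal union rule whose purpose is screening, not inference; no
multiple-testing correction is applied, and the selected set is shared by
all groups so that importances are comparable across groups.

**Step 2 — importance.** Per age group, an $\varepsilon$-SVR with Gaussian
kernel predicts $\Delta M$ from the selected activities, education, and
baseline memory. Predictors are standardized at fit time; the kernel width
is chosen from 10 log-spaced candidates between the 0.1 and 0.9 quantiles of
the pairwise distances of the standardized design, scored by mean squared
error on a seeded inner holdout (one third of the rows); the regularization
constant uses the Cherkassky–Ma heuristic
$C = \max(|\bar y + 3s_y|, |\bar y - 3s_y|)$ and the tube width
$\varepsilon = 0.1\,s_y$. Importance is *data-based sensitivity analysis*:
feature $j$ is swept over $L = 7$ probe levels spanning its observed range
(for an ordinal feature with at most 7 categories, the probes are exactly
its categories), the whole reference matrix is overwritten at column $j$
with each level, predictions are averaged over rows, and the sensitivity
$s_j$ is the variance of the $L$ level means (a range measure is available
via `sa_measure = "range"`). Relative importance is $r_j = s_j / \sum_k
s_k$. The procedure is repeated 200 times per group on random 80%
subsamples drawn without replacement, each repetition refitting the SVR on
its subsample and using it as the reference matrix; means and standard
errors ($\mathrm{sd}/\sqrt{R}$) across repetitions are reported. The
kernel-width grid search runs once per age group on the full group table;
`sa_regrid = TRUE` re-runs it on every subsample instead (at ten times the
number of fits), and
`sa_refit = FALSE` goes the other way, keeping a single per-group fit and
resampling only the reference matrix fed to the probes.
Predictive accuracy is reported separately as the mean coefficient of
determination over 100 random 80/20 train/test splits.

**Step 3 — trends.** For each series (combined activities, education,
baseline memory) the $R$ repetition values per group are compared across the
five groups by one-way ANOVA and all-pairs Tukey HSD, and the trend is
summarized by the exact Spearman rank correlation of the five group means
with the age index and by the relative change from youngest to oldest mean.
Repetitions within a group are overlapping subsamples of the same data, so
these tests characterize the dispersion of the estimator, not
population-level inference — the classic pseudo-replication caveat; the
pairwise tables should be read as "the estimated importances differ by more
than their estimation noise", nothing stronger.

## The synthetic cohort and what it does (and does not) emulate

Real HRS extracts are restricted-access, so validation runs on synthetic
cohorts with known ground truth. Within each age group $g$ the generator
draws ages uniformly in the bin, education uniformly on 8–20 years, each
activity uniformly over its 6 or 7 ordinal categories, and the baseline
recall total from a beta-binomial on 0–20 with group mean declining with age
(concentration 2, i.e. strongly overdispersed — real recall totals are far
wider than a binomial, and full 0–20 support keeps the sensitivity-analysis
probe ranges stable across simulated cohorts). The planted change is

$$\Delta M = \operatorname{round}\!\big(\mu_g + \alpha_g z(B) + \beta_g z(E)
  + \textstyle\sum_j \gamma_{g,j}\, z(A_j) + \varepsilon\big),
  \qquad \varepsilon \sim N(0, \sigma^2),$$

followed by clipping of the follow-up total into 0–20 and a hypergeometric
re-split into immediate/delayed components; activity and education cells are
then masked missing completely at random (5% by default). Here $z(\cdot)$
standardizes by the generating distribution's *population* moments, so the
coefficients are seed-free quantities and recovery targets are exact.

The `trend_preset()` configurations hold the total signal variance at 2.5
(recall-points²) in every group and move its composition: under
`"paper-like"` the combined-activity share rises over the groups
(.05/.235/.42/.615/.81) while the education share (.41/.315/.23/.145/.055)
and the baseline share (the remainder) fall; `"reversed"` flips the paths and
`"null"` freezes all groups at the middle composition. Eight activities carry
the activity signal with fixed decaying weights. The noise scale
($\sigma = 0.3$) and these share paths were fixed once, by a power analysis
against the estimator's own sampling noise at 200 participants per group, so
that the planted monotone trends are recoverable with high probability at
desk scale; the generator is an *estimator-validation instrument*, tuned for
detectability, not a calibrated imitation of HRS marginals. In particular it
does not emulate: realistic activity marginals or inter-activity correlation
(activities are drawn independently, with an eye on the assumption that
daily activities are not strongly interconnected), informative missingness,
survey weights, practice effects in repeated recall testing, or realistic
noise levels — on real survey data the predictable share of $\Delta M$ is
far smaller, and correspondingly more repetitions/larger samples would be
needed to resolve group differences. Passing recovery tests therefore shows
the *pipeline* measures what it claims to measure, not that real data would
show any particular trend.

Two systematic properties of the importance definition, surfaced during
design and worth knowing when interpreting outputs on real data:

- **Probe-range inflation.** Because probe levels span the observed range,
  a predictor whose range is large relative to its standard deviation
  (thin-tailed, e.g. a binomial-like score) receives importance inflated by
  roughly $\mathrm{var(grid)}/\mathrm{var(data)}$ compared to a
  standardized-coefficient reading. Shares remain comparable across age
  groups (the factor is stable), but not across predictors with very
  different shapes.
- **Floor effects.** Clipping of the follow-up score at 0 creates genuine
  dependence of $\Delta M$ on $B$ for low-scoring participants; in data with
  strong floor effects, part of the baseline-memory importance is a bound
  artifact, not a mechanism.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | selection level (inclusive comparison) |
| `n_resamples_dcor`, `n_perm_rf` | 300 | permutations per screening test |
| `n_reps_sa` | 200 | sensitivity repetitions per age group |
| `sa_levels` | 7 | probe levels; equals the max ordinal category count |
| `subsample_fraction` | 0.8 | rows per repetition, without replacement |
| `r2_split`, `r2_repeats` | 0.8, 100 | holdout accuracy estimation |
| `rf_num_trees`, `rf_min_node`, `rf_mtry` | 500, 5, ⌈p/3⌉ | forest settings |
| `svr_grid_size` | 10 | Gaussian kernel-width candidates |
| `missingness_threshold` | 0.15 | per-record missing-cell cap (of 36 cells) |
| `seed` | 1 | master seed; stages derive child seeds by a name hash |

`smoke_profile()` scales the counts down (50/50/50, 200 trees, 20 holdout
repeats) for desk-scale runs; the analysis scripts and the acceptance script
use it with 200 participants per group so the whole workflow runs in about a
minute per stage on one CPU.

## Numerical and design choices

- **Missingness rule.** A record is dropped iff more than 15% of its 36
  tracked cells (33 activities, education, two wave scores) are missing;
  filtering precedes imputation, medians are computed on the full retained
  sample, and imputed ordinals round half up to the nearest valid category.
  Wave memory scores are never imputed: records lacking either wave are
  excluded because the target cannot be formed.
- **Sign convention.** $\Delta M$ = follow-up − baseline, so negative values
  mean decline. All downstream statistics are sign-symmetric; only labels
  depend on it.
- **dCor test.** The significance test permutes the response; because
  double-centering commutes with simultaneous row/column permutation, each
  resample costs one elementwise product of precomputed centered matrices.
- **Permutation p-values** use the add-one formula, so the smallest
  attainable p is $1/(R+1)$ and calibration under the null is conservative
  at finite $R$.
- **Ties.** The kernel-width grid search breaks ties toward the smaller
  width; the selection comparison `p <= alpha` is inclusive with a 1e-12
  guard so a p-value printed as .05 counts as significant.
- **RBF fast path.** Sensitivity probes change one column at a time, so the
  squared distance to a support vector updates by
  $(l - s_j)^2 - (x_j - s_j)^2$ and the kernel factorizes; the implementation
  exploits this exactly (a test pins it to the generic `predict()` path at
  1e-8), making the 200-repetition sweep linear rather than quadratic in the
  number of probes.
- **Degenerate inputs.** Constant targets, empty width grids, subsamples
  under 10 rows, all-missing variables, and models constant over all probes
  raise immediate, named errors. An empty selection (e.g. `alpha = 0`) is
  not an error: Step 2 runs on education and baseline only, the combined
  series is identically zero, and its trend tests are reported `NA` with a
  warning.
- **Exact rank correlation.** The trend summary computes Spearman's
  correlation by the closed form on ranks; the general-purpose routine
  returns $1 - 2^{-52}$ on a strictly monotone series, which would break the
  exact "+1" contract.

## Problem sizes used by the shipped checks

The test suite validates the screening tests' null calibration at $n = 500$
(100 permutations; 200 repetitions for dCor, 20 forests of 100 trees),
ranking recovery over 50 trials of 50 repetitions at $n = 200$, and the
end-to-end trend recovery on ten master seeds of the `"paper-like"` and
`"null"` presets at 200 participants per group with the smoke profile.
These sizes were chosen so the properties are sharp (binomial tolerance
bands of a few percent) while the whole suite stays comfortably runnable on
a laptop.

## Known limitations

- The importance measure is marginal per feature; interaction structure is
  averaged over the reference distribution (no higher-order sensitivity
  indices).
- The union screening rule controls nothing family-wise; it is a recall-
  oriented filter, and the per-cell p-value tables should be read as
  descriptive.
- ANOVA/Tukey on repetition values quantify estimator dispersion only
  (pseudo-replication; no correction for subsample overlap is attempted).
- Causal language is out of scope throughout: the pipeline quantifies
  predictive attribution under the observed joint distribution.
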