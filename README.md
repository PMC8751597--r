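# memtrend

Age-stratified importance of daily activities for predicting memory change
in older adults.

## The problem

Longitudinal aging surveys such as the Health and Retirement Study (HRS)
measure episodic memory with immediate and delayed 10-word recall tests
(baseline memory `B` = immediate + delayed, range 0–20) and record
self-reported engagement in dozens of daily activities on 6–7 level ordinal
scales. A central question in cognitive-aging epidemiology is how much these
*modifiable* activities matter for multi-year memory change
`ΔM = B(follow-up) − B(baseline)` relative to *historical* factors — years of
education and the baseline memory level itself — and whether that balance
shifts across the lifespan.

`memtrend` implements a two-step machine-learning pipeline for this question,
stratified into five 5-year age groups (65–69 … 85–89):

1. **Screening.** Each of 33 daily activities is tested against ΔM per age
   group with (a) a distance-correlation permutation test
   (`dCor = dCov/√(dVarₓ·dVar_y)` from doubly-centered pairwise distance
   matrices; zero only under independence) and (b) a random-forest
   permutation test on impurity importances. Activities significant at the
   95% level *in at least one age group by at least one method* form the
   union set used downstream.
2. **Importance.** Per age group, a Gaussian-kernel support-vector
   regression (10-candidate kernel-width grid search) predicts ΔM from the
   selected activities, education, and baseline memory. Each predictor's
   relative importance is measured by data-based sensitivity analysis:
   sweep one input over L = 7 probe levels spanning its observed range
   (ordinal inputs are probed on their exact categories), average the
   predictions over the reference rows, and take the variance of the level
   means, normalized so importances sum to 1. This is repeated over 200
   random 80% subsamples per group; the **combined activity importance** is
   the arithmetic sum of the activity importances within a repetition.
3. **Trends.** Per-repetition importances are compared across age groups by
   one-way ANOVA and pairwise Tukey HSD, with the monotone trend summarized
   by the rank correlation of group means with age and the relative change
   from the youngest to the oldest group.

Because the underlying HRS extracts are restricted-access, the package ships
a seeded synthetic-cohort generator with a known linear-additive ground
truth (`trend_preset()`), so every stage is verifiable by parameter
recovery: a "paper-like" preset plants a combined-activity signal share that
rises with age while the education and baseline shares fall, a "null" preset
holds all groups identical, and "reversed" flips the trend.

## Worked example

The numbered scripts under `analysis/` run the whole workflow at desk scale
(200 participants per age group, 50 permutations/repetitions), writing every
stage artifact under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_feature_selection.R
Rscript analysis/04_importance.R
Rscript analysis/05_trends.R
```

Stage 3 prints the screening outcome — with the default seed, 12 of 33
activities are selected, including all 8 activities that truly carry signal:

```
12 of 33 activities were associated with memory change in at
least one age group by at least one method (alpha = 0.05)
```

Stage 4 prints the importance decomposition per age group (education /
baseline memory / combined activities):

```
  65-69: 0.380 / 0.569 / 0.051
  70-74: 0.298 / 0.455 / 0.247
  75-79: 0.167 / 0.439 / 0.394
  80-84: 0.131 / 0.321 / 0.549
  85-89: 0.055 / 0.221 / 0.724
```

and stage 5 confirms the planted trend: combined-activity importance rises
monotonically with age (rank correlation +1, ANOVA p ≈ 9e-298), while
education (−85% youngest→oldest) and baseline memory (−61%) fall, with all
10 Tukey pairs significant for the combined series. Equivalently, one call
runs everything:

```r
library(memtrend)
res <- run_pipeline(smoke_profile(seed = 1), preset = "paper-like",
                    n_per_group = rep(200L, 5), out_dir = "results/run")
res$trend$combined_activities$means
```

Real data enter through the same path: `run_pipeline(config, input =
"cohort.csv", schema = ...)` ingests any delimited export whose columns map
onto the canonical activity names (`activity_catalog()`).

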