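# ckdprog

Time-dependent survival models for chronic kidney disease (CKD)
progression. The package is aimed at biostatisticians and nephrology
researchers who follow stage 3–5 CKD patients through ~90-day clinic visits
and want to predict progression to dialysis over a 3-year horizon from
longitudinal labs — eGFR, serum creatinine, log urine protein-to-creatinine
ratio (PCRln), HbA1c — together with static risk factors (age, gender,
hypertension, diabetes, cardiovascular disease).

## What it computes

**Trajectory characterization.** Each time-varying lab is summarized per
visit by a variability slope (units/day):

    γ_i = (v_{i+1} − v_i) / (t_{i+1} − t_i),                      i = 1, 2
    γ_i = Σ_{j≤i} (v_j − v̄_i)(t_j − t̄_i) / Σ_{j≤i} (t_j − t̄_i)²,  i ≥ 3

i.e. the least-squares slope of the lab on time over the history up to each
visit.

**Three time-dependent models**, all consuming counting-process
(start, stop] risk intervals or landmark features derived from them:

* a Cox proportional hazards model λ(t|v̄) = λ₀(t)·exp(β′v(t)), fitted by
  Newton–Raphson on the counting-process partial likelihood (Breslow ties,
  Efron optional), with Breslow baseline and individual survival curves;
* a random survival forest (100 trees) grown with the standardized log-rank
  split statistic

      L(v,c) = |Σ_i (d_i1 − n_i1 d_i/n_i)| /
               √(Σ_i (n_i1/n_i)(1 − n_i1/n_i)((n_i−d_i)/(n_i−1)) d_i),

  terminal Nelson–Aalen hazards, ensemble CHF averaging, out-of-bag error
  and permutation variable importance (VIMP);
* a pseudo-value neural regression: jackknife pseudo survival probabilities
  Ŝ_j(t) = N·Ŝ(t) − (N−1)·Ŝ₋ⱼ(t) on a 6-horizon grid, regressed by a small
  sigmoid multilayer perceptron (10 inputs, 3×3 hidden, 6 outputs, Adam,
  10 epochs) whose outputs are per-interval conditional survival
  probabilities.

**Evaluation battery:** 5-fold cross-validated concordance (Harrell-type
pairwise C-index), cut-off classification metrics
(sensitivity/specificity/accuracy/precision/F1 at survival-probability
cut-offs 0.65/0.70/0.75 over a 1095-day horizon), held-out individual
validation against the 0.70 rule, predicted-probability summaries, and a
descending VIMP ranking. Cohort-level association statistics
(Yates-corrected chi-square, two-group one-way F from summary statistics)
are included for baseline tables.

**Synthetic cohort generator:** stage 3–5 patients with linear lab
trajectories and event times drawn exactly from a log-linear hazard on the
covariate values in force, so the whole pipeline is testable without
clinical data.

## Worked example

```r
library(ckdprog)
co <- apply_exclusions(generate_cohort(cohort_config(300)))
#> apply_exclusions: removed 25 of 300 patients (< 3 visits)
co
#> ckd_cohort: 275 patients, 4479 visits, 76 dialysis events
#> stage mix: 3:202 4:26 5:47

cv <- kfold_cindex(co, K = 5, seed = 1)
cv
#> 5-fold cross-validated C-index (seed 1)
#>         1     2     3     4     5 average
#> ann 0.753 0.651 0.648 0.637 0.749   0.688
#> cox 0.750 0.725 0.661 0.576 0.759   0.694
#> rsf 0.868 0.767 0.766 0.721 0.741   0.773
```

The forest discriminates best on average (C = 0.77 vs 0.69 for the Cox
model and the network), the usual picture when the hazard is nonlinear in
the trajectories. Cut-off classification at the 3-year horizon
(`cutoff_table(cv)`):

```
 model cutoff sensitivity specificity accuracy precision    f1
   cox   0.65       0.561       0.935    0.867     0.657 0.605
   cox   0.70       0.561       0.935    0.867     0.657 0.605
   rsf   0.65       0.415       0.951    0.854     0.654 0.507
   rsf   0.70       0.439       0.930    0.841     0.581 0.500
   ann   0.70       0.000       1.000    0.819        NA    NA
```

(A sensitivity of 0 with specificity 1 means the network never predicts
below the cut-off: with 10 epochs on a small cohort it regresses toward the
cohort mean survival.) Variable importance from a full-data forest:

```r
fr <- fit_forest(landmark_features(co, feature_spec(use_gamma = TRUE)), seed = 1)
oob_error(fr)
#> 0.236
head(vimp_report(fr), 5)
#>         covariate   vimp
#>        creatinine 0.0470
#>  creatinine_gamma 0.0466
#>       hba1c_gamma 0.0296
#>             pcrln 0.0142
#>        egfr_gamma 0.0120
```

Serum creatinine — level and slope — dominates, matching the generator's
hazard, in which creatinine carries the largest coefficient.

## Layout

* `R/` — cohort generator, trajectory features, nonparametric estimators,
  the three models, evaluation, CSV/pipeline I/O
* `src/` — compiled log-rank split search
* `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles in `helper-oracles.R`)
* `vignettes/ckd-progression-models.Rmd` — the methods vignette
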