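# slesurv

Survival analysis for hospitalized systemic lupus erythematosus (SLE)
cohorts with heavy loss to follow-up.

Hospital SLE registries present three compounding problems: death is rare
(under one in five followed patients), roughly 44% of patients vanish from
follow-up with no recorded outcome, and the drop-out is informative —
associated with medication patterns, with deaths overrepresented among the
lost. `slesurv` implements a complete analysis scheme for such cohorts,
aimed at biostatisticians and clinical-ML researchers:

* **Synthetic cohort generator** — seeded cohorts whose group structure
  (per-feature prevalences in the survival and death groups, censoring
  fraction, class imbalance, feature-driven hazards) is calibrated to
  published hospitalized-SLE cohort summaries, so the whole pipeline is
  testable without access to any registry.
* **Cohort machinery** — one-hot encoding, min–max normalization,
  outcome-and-time-stratified train/test splitting, majority-class
  under-sampling, and baseline-characteristics tables (n (%), mean ± SD,
  Mann–Whitney U and χ² group comparisons).
* **Cost-sensitive semi-supervised classifier** — a feed-forward network
  (117–64–64–2, softmax head) trained with a dynamically weighted, delayed
  mean-squared-error loss

  $$\mathrm{Loss}=\mathrm{dynMSE}(y_1,\hat y_1)+\alpha(t)\,\mathrm{dynMSE}(y_2,\hat y_2),
  \qquad
  \mathrm{dynMSE}(y,\hat y)=\frac{1}{2B}\sum_i w_i\sum_k (y_{ik}-\hat y_{ik})^2,$$

  where batch 2 holds pseudo-labeled censored records, the per-batch class
  weights are $w=\mathrm{zero\_weight}=N_p/N$ for survivors and
  $\mathrm{one\_weight}=N_n/N$ for deaths (the rare class always costs
  more), and $\alpha(t)$ ramps linearly from 0 at epoch $T_1=100$ to
  $\alpha_f=3$ at epoch $T_2=600$. Training proceeds in the four classic
  steps: balanced supervised fit → pseudo-label the censored records →
  cost-sensitive retraining on labeled + pseudo data → final prediction.
* **Evaluation** — sensitivity/specificity/accuracy/F1 from confusion
  counts (death is the positive class), ROC/AUC, NRI and IDI against a
  reference model, and a six-classifier baseline harness (decision tree,
  random forest, gradient boosting, KNN, SVM, logistic regression).
* **Root-cause analysis** — per-record wrong-judgment rates over R = 20
  repeated trainings, the TNG/FPG/TPG/FNG subgroup partition, per-feature
  effective proportions, and death-threat coefficients
  $\mathrm{Dtc}_{\mathrm{FPG-TNG}}=\mathrm{Fep}_{\mathrm{FPG}}/\mathrm{Fep}_{\mathrm{TNG}}$,
  $\mathrm{Dtc}_{\mathrm{TPG-FNG}}=\mathrm{Fep}_{\mathrm{TPG}}/\mathrm{Fep}_{\mathrm{FNG}}$
  (both ≥ 1.5 flags a death-associated feature).
* **Survival factors** — LASSO screening (cross-validated penalty) feeding
  a forward-stepwise Cox model (likelihood-ratio entry at p < 0.05,
  removal at p > 0.10, ≤ 20 steps) and Kaplan–Meier curves.
* **Risk score** — logistic regression on balanced data; the per-patient
  score $z=\sum_{i\ge 0} w_i x_i$ (intercept included) classifies death
  when $z>0$; the zero survival threshold coincides with the logistic
  0.5-probability boundary by construction.

## Worked example

```r
library(slesurv)

spec   <- default_spec(seed = 42)      # 2444 patients, 1074 lost to follow-up
cohort <- generate_cohort(spec)
cohort
#> <sle_cohort> 2444 patients (1370 followed, 1074 lost to follow-up), 117 features
#>   followed outcomes: 1134 survival / 236 death

summarize_cohort(cohort, c("cardiopulmonary", "neuropsychiatric", "sledai_discharge"))
#> Variable                     Total          Survival       Death          P value
#> cardiopulmonary                305( 22.26)    220( 19.40)     85( 36.02)  0.0000
#> neuropsychiatric               107(  7.81)     77(  6.79)     30( 12.71)  0.0020
#> sledai_discharge               5.98±6.97     5.38±5.94     8.89±10.12  0.0000

X     <- normalize_features(cohort_features(cohort))$X
lab   <- cohort$followed == 1
split <- split_cohort(cohort$outcome[lab], cohort$time[lab], 0.8, seed = 1)
length(split$train_idx); length(split$test_idx)
#> [1] 1096
#> [1] 274

Xtr <- X[lab, ][split$train_idx, ]; ytr <- cohort$outcome[lab][split$train_idx]
Xte <- X[lab, ][split$test_idx, ];  yte <- cohort$outcome[lab][split$test_idx]

# steps (i)-(iii): balanced supervised fit, pseudo-labels, retraining
keep  <- undersample_majority(ytr, seed = 1)
cfg   <- net_config(input_dim = ncol(X), seed = 1)
m0    <- train_initial(Xtr[keep, ], ytr[keep], cfg)
pl    <- pseudo_label(m0, X[!lab, ])
sum(pl$label == 1); sum(pl$label == 0)
#> [1] 571     # pseudo-label deaths: the lost records are death-enriched
#> [1] 503
model <- train_cost_sensitive(Xtr, ytr, X[!lab, ], pl$label, net_cfg = cfg)

classification_metrics(yte, predict(model, Xte, type = "class"))
#> TP=41 TN=159 FP=68 FN=6 | sens=0.8723 spec=0.7004 acc=0.7299 f1=0.5256
roc_auc(yte, predict(model, Xte, type = "prob")[, "death"])$auc
#> [1] 0.8545318

# logistic survival-risk score with the zero threshold
keep2 <- undersample_majority(ytr, seed = 2)
risk  <- fit_risk_model(Xtr[keep2, ], ytr[keep2])
z     <- risk_score(risk, Xte)
threshold_separation_report(z, yte)[c("survivor_crossing_fraction",
                                      "death_crossing_fraction")]
#> $survivor_crossing_fraction
#> [1] 0.2288557   # survivors scoring above the zero line
#> $death_crossing_fraction
#> [1] 0.1914894   # deaths scoring below it
```

The sensitivity of 0.87 is the death recall rate — the quantity the
cost-sensitive loss is designed to protect — at an overall accuracy of
0.73 on a test set where only one patient in six dies. `run_pipeline()`
chains all stages (including the WJR/Dtc root-cause analysis, LASSO →
stepwise-Cox survival factors, and KM curves) and writes every artifact as
CSV/JSON into an output directory.

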