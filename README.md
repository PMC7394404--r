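# missvote

Missense variant deleteriousness prediction with a weighted soft-voting
ensemble of a random forest and a logistic regression, trained on a
113-feature panel spanning multi-ethnic minor allele frequencies,
evolutionary conservation, amino-acid substitution properties and
component predictor scores.

The package implements the full pipeline:

- **Feature model** — a validated 113-feature manifest (6 MAF, 8
  conservation, 92 functional including 90 AAindex-style substitution
  matrices, 7 component predictors), plus a reader/writer for the AAindex
  flat-file format.
- **Annotation** — missense-aware VCF ingestion (multi-allelic splitting,
  line-numbered validation) and keyed joins of annotation tables into a
  feature matrix with explicit coverage tracking and optional median
  imputation.
- **Dataset construction** — the clinical filter cascade: exact
  `Pathogenic` significance with high-confidence review status, exact `DM`
  disease-mutation status, strict MAF `< 1%` / depth `> 30` population
  filters, circularity exclusion lists with per-list accounting, balanced
  90/10 splitting, and nested MAF-bin subsets down to singletons.
- **Ensemble** — per-learner recursive feature elimination, randomized
  hyperparameter search over cross-validated AUC, the soft vote
  `(w_t * p_tree + w_l * p_linear) / (w_t + w_l)`, versioned model
  serialization, and per-learner feature-weight reports.
- **Evaluation** — a 12-metric confusion panel (sensitivity, specificity,
  precision, NPV, accuracy, F1, MCC, rank-statistic AUC, log loss,
  diagnostic odds ratio, FPR, FNR) with explicit `NA`/`Inf` semantics,
  repeated balanced evaluation across MAF bins, missing-score handling and
  model concordance.
- **Exome simulation** — spike-in disease exomes (~420 filtered background
  variants plus one causative), competition ranking of the causative
  variant, and exact-enumeration Mann-Whitney comparison of rank
  distributions.
- **Synthetic data** — seeded generators for labeled feature sets and
  background exomes emulating the statistical structure of curated
  clinical and population databases, so everything runs without licensed
  data.

## Quick start

```r
library(missvote)

# synthetic training and held-out sets over the full 113-feature manifest
train <- generate_labeled_features(400, effect_size = 3, seed = 11)
test  <- generate_labeled_features(400, effect_size = 3, seed = 12)

# randomized-search soft-voting fit (tree + linear members)
model <- fit_soft_voting(train, n_iter = 3, cv_folds = 3, seed = 2)

scores <- predict_score(model, test$matrix)
metric_panel(NULL, scores, test$labels)
#> sensitivity  1.0000
#> specificity  1.0000
#> precision    1.0000
#> npv          1.0000
#> accuracy     1.0000
#> f1           1.0000
#> mcc          1.0000
#> auc          1.0000
#> log_loss     0.0114
#> dor            Inf
#> fpr          0.0000
#> fnr          0.0000
#> log_loss_mode probability

# spike-in disease-exome ranking study
study <- simulate_exome_study(model, n_exomes = 10, seed = 4)
study$summary$median_rank
#> [1] 1
```

(Synthetic data at effect size 3 is nearly separable by construction;
real-data performance is a property of the annotation sources, not of the
package.)

## Command line

An installed CLI wraps the main stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "missvote.R", package = "missvote"))')
Rscript $CLI synth --n-per-class=500 --seed=1 --out train.rds
Rscript $CLI train --data train.rds --n-iter=20 --cv-folds=5 --seed=1 --out model.rds
Rscript $CLI score --model model.rds --data train.rds --out scores.tsv
Rscript $CLI evaluate --model model.rds --data train.rds --out metrics.tsv
Rscript $CLI simulate-exomes --model model.rds --n-exomes=50 --seed=1 --out ranks.tsv
```

Every stochastic step takes `--seed`; `--config file.cfg` supplies flag
defaults from `[subcommand]` sections of a flat key-value file.

## License

MIT
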