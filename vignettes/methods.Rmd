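---
title: "Methods: a soft-voting ensemble for missense variant deleteriousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a soft-voting ensemble for missense variant deleteriousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(missvote)
```

## Overview

`missvote` implements a complete pipeline for predicting whether a missense
variant is deleterious or benign:

1. **Feature model** — a 113-feature manifest spanning multi-ethnic minor
   allele frequencies, evolutionary conservation, amino-acid substitution
   properties and component predictor scores.
2. **Annotation** — VCF ingestion and keyed joins of annotation tables into
   a dense feature matrix with explicit coverage tracking.
3. **Dataset construction** — the clinical-significance, review-status,
   frequency, depth and circularity filter cascade, followed by balanced
   train/test splitting.
4. **Feature selection** — recursive feature elimination (RFE) run
   separately per learner.
5. **Ensemble** — a weighted soft-voting combination of a random forest and
   a logistic regression, tuned by randomized search over cross-validated
   AUC.
6. **Evaluation** — a 12-metric confusion-matrix panel plus repeated
   balanced evaluation over minor-allele-frequency bins.
7. **Exome simulation** — spike-in disease exomes for causative-variant
   ranking, with exact Mann-Whitney comparison of rank distributions.

Because the curated clinical and population databases that such models are
normally trained on are licensed and large, the package ships a synthetic
generator that reproduces their statistical structure, so every stage is
exercisable end to end on a laptop.

## The feature manifest

```{r manifest}
man <- default_manifest()
man
table(man$category)
```

The six MAF features are a global frequency plus five continental
populations (AFR, AMR, EAS, NFE, SAS). Two further populations commonly
present in annotation sources (ASJ, FIN) are deliberately absent: they are
dropped by feature selection in the modelled design. The 90 functional
substitution features are AAindex-style 20×20 amino-acid matrices, looked
up at each variant's `ref_aa → alt_aa` change; the package ships a
synthetic matrix set and a reader/writer for the AAindex flat-file format:

```{r aaindex}
path <- system.file("extdata", "synthetic_aaindex_example.txt",
                    package = "missvote")
aaset <- read_aaindex(path)
aaindex_substitution_value(aaset$SYNM001001, "A", "V")
```

## Synthetic data

`generate_labeled_features()` draws class-conditional feature values over a
manifest. Deleterious variants follow a rare-variant frequency profile
(mostly absent from the population, otherwise allele counts 1–3); benign
variants are rare but observed. Conservation and functional features are
unit-variance Gaussians whose class means differ by `effect_size`;
predictor features are logistic transforms of the same latent signal; a
`noise_fraction` of the columns is made label-independent.

One design decision deserves a note: at `effect_size = 0` the deleterious
frequency profile is *interpolated all the way to the benign profile*, so
the two classes are identically distributed in every feature — a true null
for calibration studies. The deleterious profile is fully expressed at
`effect_size >= 3`.

```{r synth}
d <- generate_labeled_features(250, effect_size = 3, seed = 42)
d
# single-feature separability under signal and under the null
null <- generate_labeled_features(250, effect_size = 0, seed = 42)
c(signal = auc_rank(d$matrix$values[, "phastcons_primates"], d$labels),
  null = auc_rank(null$matrix$values[, "phastcons_primates"], null$labels))
```

## Dataset construction

Positives come from clinically curated sources: records kept only when the
significance is exactly `"Pathogenic"` with a high-confidence review status
(multiple submitters without conflict, expert panel, or practice
guideline), or a disease-mutation status of exactly `"DM"`. Negatives come
from population data under *strict* inequalities — MAF `< 0.01` and depth
`> 30` — and a circularity filter removes any variant present in the
training sets of comparison tools:

```{r filters}
neg <- data.frame(chrom = "3", pos = 1:5, ref = "C", alt = "T",
                  MAF = c(0.009, 0.01, 0.005, 0.005, 0.002),
                  DP = c(45, 45, 30, 31, 45))
# MAF exactly 1% and depth exactly 30 are excluded by the strict bounds
select_population_negatives(neg)
```

`balance_and_split()` then draws a negative subset matching the positive
count and splits 90/10 into train and test with seeded reproducibility.

## Feature selection and the ensemble

RFE iteratively refits a learner, ranks features (mean decrease in Gini
impurity for the forest, absolute standardized coefficient for the
logistic), and removes the weakest — 7 at a time while more than 150
remain, then singly. Each learner gets its own elimination order, so the
two ensemble members can use different feature subsets.

```{r rfe}
small <- generate_labeled_features(150, manifest = feature_manifest(
  paste0("f", 1:10), "conservation"), noise_fraction = 0.3, seed = 9)
trace <- rfe_rank(small, learner = "linear", cv_folds = 3, seed = 1)
head(trace$performance_curve)
select_top_k(trace, 4)
```

`fit_soft_voting()` runs a randomized search (default 20 draws, 5-fold CV)
over forest size, `mtry`, node size and the two voting weights, scoring
each configuration by mean cross-validated AUC of the soft vote

$$\mathrm{score} = \frac{w_t\,p_\mathrm{tree} + w_l\,p_\mathrm{linear}}{w_t + w_l},$$

then refits the best configuration on the full training data. The
logistic member is fitted on features standardized by a scaler estimated
on the training folds only. Classification uses a strict threshold:
score `> 0.5` is deleterious, exactly `0.5` is benign.

```{r fit}
fit <- fit_soft_voting(small, n_iter = 2, cv_folds = 3, seed = 4)
heldout <- generate_labeled_features(150, manifest = feature_manifest(
  paste0("f", 1:10), "conservation"), noise_fraction = 0.3, seed = 10)
scores <- predict_score(fit, heldout$matrix)
auc_rank(scores, heldout$labels)
```

Models serialize with `save_model()` / `load_model()` under a versioned
format tag, and `feature_weight_report()` returns per-learner importances
normalized to 100%.

## Evaluation

`metric_panel()` reports sensitivity, specificity, precision, NPV,
accuracy, F1, MCC, AUC (rank statistic with midrank ties), log loss,
diagnostic odds ratio, FPR and FNR. Undefined ratios are `NA`; a DOR with
an empty error cell is `+Inf` unless the Haldane–Anscombe +0.5 correction
is requested. Log loss has two modes: `"probability"` scores the
continuous output, `"hard_label"` scores the thresholded classes, where
each misclassification contributes $-\log(10^{-15})$ — reproducing the
large magnitudes conventionally reported alongside thresholded calls.

```{r metrics}
labels <- rep(c(1, 0), each = 10)
preds <- c(rep(0.9, 9), 0.1, rep(0.9, 2), rep(0.1, 8))  # TP 9, FN 1, FP 2, TN 8
panel <- metric_panel(NULL, preds, labels)
panel
dor_from_rates(panel$sensitivity, panel$specificity)
```

`repeated_balanced_eval()` re-estimates the panel over repeated balanced
draws of benign variants, stratified into nested MAF bins
(`< 1%`, `< 0.5%`, `< 0.1%`, `< 0.01%`, singletons), reporting the mean
and sample standard deviation per metric.

## Spike-in exome simulation

`simulate_exome_study()` emulates a diagnostic scenario: for each simulated
exome, ~420 benign-profile background variants pass the clinical filters
(depth `> 10`, MAF `< 1%` with missing frequencies passing), one causative
deleterious variant is spiked in, everything is scored, and the causative
variant's rank is recorded (competition ranking: 1 plus the number of
strictly higher scores).

```{r exomes}
study <- simulate_exome_study(fit, n_exomes = 10, exome_size = 100,
                              manifest = feature_manifest(
                                paste0("f", 1:10), "conservation"),
                              seed = 5)
study$summary
```

Rank distributions from two tools are compared with a two-sided
Mann-Whitney test — exact enumeration of all group assignments for
combined samples up to 12 (valid under ties), the tie-corrected normal
approximation beyond:

```{r mw}
compare_rank_distributions(c(1, 1, 2), c(4, 9, 30))
```

## Command-line interface

The installed package carries a CLI at
`system.file("cli", "missvote.R", package = "missvote")` with subcommands
`synth`, `build-dataset`, `select-features`, `train`, `score`, `evaluate`,
`simulate-exomes` and `concordance`; every stochastic step takes `--seed`,
and `--config` supplies flag defaults from a sectioned key-value file. See
the README for a worked shell session.
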