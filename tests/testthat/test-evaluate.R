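test_that("confusion counts match hand tabulation", {
  labels <- c(1, 1, 0, 0, 1, 0)
  classes <- c(1, 0, 0, 1, 1, 0)
  cm <- confusion(labels, classes)
  expect_equal(cm$TP, 2L)
  expect_equal(cm$FN, 1L)
  expect_equal(cm$FP, 1L)
  expect_equal(cm$TN, 2L)
  expect_error(confusion(labels, classes[1:3]), "equal length")
  expect_error(confusion(c(0, 2), c(0, 1)), "binary")
})

test_that("metric panel reproduces hand-computed values on a worked example", {
  # TP=9 TN=8 FP=2 FN=1
  labels <- c(rep(1, 10), rep(0, 10))
  classes <- c(rep(1, 9), 0, rep(1, 2), rep(0, 8))
  scores <- ifelse(classes == 1, 0.9, 0.1)
  m <- metric_panel(NULL, scores, labels, classes = classes)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$f1, 2 * 9 / (2 * 9 + 2 + 1))
  expect_equal(m$mcc, (9 * 8 - 2 * 1) / sqrt(11 * 10 * 10 * 9))
  expect_equal(m$dor, (9 * 8) / (2 * 1))
  expect_equal(m$fpr, 0.2)
  expect_equal(m$fnr, 0.1)
})

test_that("metric panel agrees with the closed-form oracle on random inputs", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    classes <- classify(scores)
    cm <- confusion(labels, classes)
    m <- metric_panel(cm, scores, labels)
    o <- oracle_panel(cm$TP, cm$FP, cm$TN, cm$FN)
    for (k in names(o))
      expect_equal(m[[switch(k, f1 = "f1", k)]], o[[k]], tolerance = 1e-12,
                   info = k)
    expect_equal(m$auc, auc_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("degenerate confusion tables produce NA, Inf or corrected values", {
  # all correct
  perfect <- metric_panel(NULL, c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)
  expect_identical(perfect$dor, Inf)
  # all inverted
  inverted <- metric_panel(NULL, c(0.1, 0.1, 0.9, 0.9), c(1, 1, 0, 0))
  expect_equal(inverted$mcc, -1)
  expect_equal(inverted$auc, 0)
  expect_equal(inverted$dor, 0)  # TP*TN = 0 over FP*FN = 4
  # everything predicted positive: specificity/npv undefined markers
  allpos <- metric_panel(NULL, rep(0.9, 4), c(1, 1, 0, 0))
  expect_equal(allpos$specificity, 0)
  expect_true(is.na(allpos$npv))
  # single-class truth: AUC undefined
  onec <- metric_panel(NULL, c(0.9, 0.1), c(1, 1))
  expect_true(is.na(onec$auc))
  # Haldane-Anscombe correction replaces Inf with a finite estimate
  corr <- metric_panel(NULL, c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0),
                       dor_correction = TRUE)
  expect_equal(corr$dor, (2.5 * 2.5) / (0.5 * 0.5))
  expect_error(metric_panel(NULL, numeric(0), numeric(0)), "empty")
  cm <- confusion(c(1, 0), c(1, 0))
  expect_error(metric_panel(cm, c(0.9, 0.1, 0.5), c(1, 0, 1)), "sum")
})

test_that("rank AUC is invariant to monotone transforms and flips under negation", {
  set.seed(77)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
               auc_rank(pmin(pmax(scores, 0.01), 0.99), labels))
  expect_equal(auc_rank(scores * 10 + 3, labels), a)
  expect_equal(auc_rank(-scores, labels), 1 - a)
  # ties handled by midranks: all-equal scores give exactly 0.5
  expect_equal(auc_rank(rep(0.5, 40), labels), 0.5)
})

test_that("diagnostic odds ratio identities hold", {
  expect_equal(dor_from_rates(0.9, 0.8), (0.9 / 0.1) * (0.8 / 0.2))
  expect_identical(dor_from_rates(1, 0.8), Inf)
  expect_equal(dor_from_rates(0.5, 0.5), 1)
  # matches the count-based DOR from the corresponding table
  m <- oracle_panel(9, 2, 8, 1)
  expect_equal(dor_from_rates(m$sensitivity, m$specificity), m$dor)
})

test_that("log loss modes: probabilities vs thresholded classes", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.6, 0.4, 0.2)
  m <- metric_panel(NULL, scores, labels, log_loss_mode = "probability")
  expect_equal(m$log_loss,
               -mean(log(c(0.9, 0.6, 0.6, 0.8))), tolerance = 1e-12)
  # hard-label mode: each misclassification contributes -log(eps)
  scores2 <- c(0.9, 0.2, 0.4, 0.2)  # one false negative out of 4
  h <- metric_panel(NULL, scores2, labels, log_loss_mode = "hard_label")
  expect_equal(h$log_loss, -log(1e-15) / 4, tolerance = 1e-9)
  # perfect hard-label predictions cost only the clipping term
  p <- metric_panel(NULL, scores, labels, log_loss_mode = "hard_label")
  expect_lt(p$log_loss, 1e-12)
})

balanced_pool <- function(n = 400, seed = 9) {
  set.seed(seed)
  data.frame(score = runif(n, 0, 0.4),
             maf = exp(runif(n, log(1e-6), log(0.0099))),
             allele_count = c(rep(1L, n / 2), rep(5L, n / 2)))
}

test_that("repeated balanced evaluation is deterministic and well-shaped", {
  del <- seq(0.6, 0.99, length.out = 20)
  pool <- balanced_pool()
  r1 <- repeated_balanced_eval(del, pool, n_rep = 3, seed = 13)
  r2 <- repeated_balanced_eval(del, pool, n_rep = 3, seed = 13)
  expect_identical(r1, r2)
  expect_setequal(unique(r1$bin), c("maf_lt_0.01", "maf_lt_0.005", "maf_lt_0.001",
                                    "maf_lt_0.0001", "singleton"))
  expect_equal(nrow(r1), 5L * 12L)
  # deleterious scores all above threshold, benign all below: clean separation
  expect_true(all(r1$mean[r1$metric == "auc"] == 1))
  expect_true(all(r1$mean[r1$metric == "sensitivity"] == 1))
  # a single draw reports zero spread
  one <- repeated_balanced_eval(del, pool, n_rep = 1, seed = 13)
  expect_true(all(one$sd == 0))
})

test_that("repeated balanced evaluation on an uninformative pool centers near 0.5 AUC", {
  set.seed(21)
  del <- runif(40, 0, 0.4)                     # same distribution as the pool
  r <- repeated_balanced_eval(del, balanced_pool(800, seed = 22),
                              bins = c(0.01), n_rep = 20, seed = 3)
  expect_lt(abs(r$mean[r$metric == "auc"] - 0.5), 0.1)
})

test_that("a too-small benign bin raises an error naming the bin", {
  del <- runif(300, 0.6, 1)   # singleton bin holds only 200 benign variants
  expect_error(repeated_balanced_eval(del, balanced_pool(400),
                                      bins = "singleton", seed = 1),
               "singleton")
})

test_that("missing-score handling keeps fully scored variants and reports gaps", {
  tab <- data.frame(id = 1:5,
                    toolA = c(0.1, NA, 0.3, 0.4, 0.5),
                    toolB = c(0.2, 0.3, NA, NA, 0.6))
  out <- handle_missing_scores(tab, c("toolA", "toolB"))
  expect_equal(out$table$id, c(1L, 5L))
  expect_equal(out$missingness, c(toolA = 20, toolB = 40))
  # no missingness: table passes through intact
  full <- handle_missing_scores(tab[c(1, 5), ], c("toolA", "toolB"))
  expect_equal(nrow(full$table), 2L)
  expect_true(all(full$missingness == 0))
  expect_error(handle_missing_scores(tab, c("toolA", "toolC")), "toolC")
})

test_that("model concordance stratifies agreement by true label", {
  a <- c(1, 1, 0, 0, 1, 0)
  b <- c(1, 0, 0, 1, 1, 0)
  lab <- c(1, 1, 1, 0, 0, 0)
  conc <- model_concordance(a, b, lab)
  expect_equal(unname(conc["overall"]), 100 * 4 / 6)
  expect_equal(unname(conc["on_positives"]), 100 * 2 / 3)
  expect_equal(unname(conc["on_negatives"]), 100 * 2 / 3)
  expect_equal(unname(model_concordance(a, a, lab)["overall"]), 100)
  expect_true(is.na(model_concordance(1, 1, 0)["on_positives"]))
  expect_error(model_concordance(a, b[1:3], lab), "equal length")
})

test_that("score distribution export writes the long plotting layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- score_distribution_export(c(0.9, 0.5, 0.1), c(1, 0, 0), 0.5, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("score", "true_class", "predicted_class", "threshold"))
  expect_equal(tab$predicted_class, c("deleterious", "benign", "benign"))
  expect_equal(tab$true_class, c("deleterious", "benign", "benign"))
  expect_true(all(tab$threshold == 0.5))
  # empty input still yields a parseable header-only file
  score_distribution_export(numeric(0), integer(0), 0.5, path)
  empty <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(empty), 0L)
})
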