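# small but separable training sets keep these fits fast
train_fixture <- function(p = 12, n = 150, effect = 2.5, noise = 0.25, seed = 21) {
  generate_labeled_features(n, manifest = small_manifest(p),
                            effect_size = effect, noise_fraction = noise,
                            seed = seed)
}

light_space <- list(ntree = 60L, mtry = c(2L, 4L), nodesize = c(1L, 5L),
                    w_tree = c(0.25, 0.5, 0.75, 1), w_linear = c(0.25, 0.5, 0.75, 1))

test_that("recursive elimination discards noise features early", {
  # 10 informative + 5 pure-noise features; noise should dominate the first
  # third of eliminations in a majority of seeds
  hits <- vapply(1:5, function(s) {
    d <- generate_labeled_features(120, manifest = small_manifest(15),
                                   effect_size = 2.5, noise_fraction = 1 / 3,
                                   seed = 100 + s)
    # identify the noise columns: class-conditional mean difference near zero
    del <- d$labels == 1L
    diff <- abs(colMeans(d$matrix$values[del, ]) - colMeans(d$matrix$values[!del, ]))
    noise <- names(sort(diff))[1:5]
    tr <- rfe_rank(d, "linear", cv_folds = 3, seed = s)
    sum(noise %in% tr$elimination_order[1:5])
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.6)
})

test_that("elimination traces have the promised shape for both learners", {
  d <- train_fixture(p = 8, n = 80)
  for (learner in c("tree", "linear")) {
    tr <- rfe_rank(d, learner, cv_folds = 3, seed = 3)
    expect_length(tr$elimination_order, 8L)
    expect_false(any(duplicated(tr$elimination_order)))
    expect_equal(nrow(tr$performance_curve),
                 length(tr$elimination_order))  # step 1: one point per size
  }
  # a single elimination round yields exactly two curve points
  tr2 <- rfe_rank(d, "linear", step = 7, cv_folds = 3, seed = 3)
  expect_equal(nrow(tr2$performance_curve), 2L)
})

test_that("a duplicated feature column is eliminated in the first half of steps", {
  d <- train_fixture(p = 9, n = 120, noise = 0, seed = 77)
  d$matrix$values[, "f9"] <- d$matrix$values[, "f1"]  # exact duplicate
  tr <- rfe_rank(d, "linear", cv_folds = 3, seed = 4)
  first_half <- tr$elimination_order[1:4]
  expect_true(any(c("f1", "f9") %in% first_half))
})

test_that("top-k selection returns the longest survivors", {
  tr <- structure(list(elimination_order = paste0("f", 1:10),
                       performance_curve = data.frame(n_features = 10:1,
                                                      cv_auc = rep(0.9, 10)),
                       learner = "linear"), class = "rfe_trace")
  expect_setequal(select_top_k(tr, 10), paste0("f", 1:10))
  expect_equal(select_top_k(tr, 1), "f10")
  top4 <- select_top_k(tr, 4)
  expect_length(intersect(top4, tr$elimination_order[1:6]), 0L)
  expect_error(select_top_k(tr, 0), "k must lie")
  expect_error(select_top_k(tr, 11), "k must lie")
})

test_that("soft-vote arithmetic follows the weighted average", {
  expect_equal(soft_vote_score(0.8, 0.6, c(1, 1)), 0.7)
  expect_equal(soft_vote_score(0.8, 0.4, c(0.75, 0.25)), 0.7)
  expect_equal(soft_vote_score(0.8, 0.2, c(1, 0)), 0.8)
  expect_equal(soft_vote_score(0.8, 0.2, c(0, 1)), 0.2)
  # convex combination stays between the member probabilities
  for (i in 1:20) {
    p <- runif(2)
    w <- runif(2)
    s <- soft_vote_score(p[1], p[2], w)
    expect_gte(s, min(p))
    expect_lte(s, max(p))
  }
})

test_that("classification threshold is strict, with the boundary called benign", {
  expect_equal(classify(c(0.51, 0.5, 0, 1), 0.5), c(1L, 0L, 0L, 1L))
})

test_that("training is reproducible and predicts well on held-out data", {
  d <- train_fixture()
  fit <- fit_soft_voting(d, n_iter = 3, cv_folds = 3, seed = 11,
                         search_space = light_space)
  fit2 <- fit_soft_voting(d, n_iter = 3, cv_folds = 3, seed = 11,
                          search_space = light_space)
  test <- train_fixture(seed = 99)
  s <- predict_score(fit, test$matrix)
  expect_identical(s, predict_score(fit2, test$matrix))
  expect_identical(fit$train_metadata$best_config, fit2$train_metadata$best_config)
  expect_gt(auc_rank(s, test$labels), 0.9)
  expect_true(all(s >= 0 & s <= 1))
  # scores are a row-wise function: invariant to row order
  perm <- sample(nrow(test$matrix$values))
  s_perm <- predict_score(fit, test$matrix$values[perm, , drop = FALSE])
  expect_equal(s_perm, s[perm])
  # a minimal search (n_iter = 1) still yields a valid model
  fit1 <- fit_soft_voting(d, n_iter = 1, cv_folds = 2, seed = 1,
                          search_space = light_space)
  expect_s3_class(fit1, "soft_voting_model")
})

test_that("training validates its inputs", {
  d <- train_fixture(n = 40)
  bad <- d
  bad$matrix$values[1, 1] <- Inf
  expect_error(fit_soft_voting(bad, n_iter = 1, cv_folds = 2), "non-finite")
  one_class <- missvote:::subset_dataset(d, which(d$labels == 1L))
  expect_error(fit_soft_voting(one_class, n_iter = 1, cv_folds = 2),
               "both classes")
  expect_error(fit_soft_voting(d, features_tree = c("f1", "ghost"),
                               n_iter = 1, cv_folds = 2), "ghost")
  # strong imbalance is recorded, not fatal
  skewed <- missvote:::subset_dataset(d, c(which(d$labels == 1L)[1:3],
                                           which(d$labels == 0L)))
  fit <- fit_soft_voting(skewed, n_iter = 1, cv_folds = 2, seed = 2,
                         search_space = light_space)
  expect_match(fit$train_metadata$warnings, "imbalance")
})

test_that("scoring refuses uncovered or missing model features", {
  d <- train_fixture(n = 60)
  fit <- fit_soft_voting(d, n_iter = 1, cv_folds = 2, seed = 3,
                         search_space = light_space)
  test <- train_fixture(n = 20, seed = 42)
  gap <- test$matrix
  gap$coverage[1, "f3"] <- FALSE
  expect_error(predict_score(fit, gap), "f3")
  expect_error(predict_score(fit, test$matrix$values[, 1:5]), "f6")
})

test_that("feature weights normalize to 100% per learner and track signal", {
  d <- train_fixture(n = 100)
  fit <- fit_soft_voting(d, n_iter = 1, cv_folds = 2, seed = 6,
                         search_space = light_space)
  w <- feature_weight_report(fit)
  sums <- tapply(w$weight_percent, w$learner, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
  # lone informative feature dominates the tree learner in most seeds
  hits <- vapply(1:7, function(s) {
    man <- small_manifest(6)
    dd <- generate_labeled_features(100, manifest = man, effect_size = 3,
                                    noise_fraction = 5 / 6, seed = 200 + s)
    del <- dd$labels == 1L
    diffs <- abs(colMeans(dd$matrix$values[del, ]) -
                   colMeans(dd$matrix$values[!del, ]))
    signal <- names(which.max(diffs))
    f <- fit_soft_voting(dd, n_iter = 1, cv_folds = 2, seed = s,
                         search_space = light_space)
    ww <- feature_weight_report(f)
    tw <- ww[ww$learner == "tree", ]
    tw$feature[which.max(tw$weight_percent)] == signal
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("model persistence round-trips bit-identically", {
  d <- train_fixture(n = 60)
  fit <- fit_soft_voting(d, n_iter = 1, cv_folds = 2, seed = 8,
                         search_space = light_space)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  test <- train_fixture(n = 30, seed = 55)
  expect_identical(predict_score(back, test$matrix),
                   predict_score(fit, test$matrix))
  expect_identical(back$train_metadata, fit$train_metadata)
  # corruption and format mismatches are explicit errors
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "cannot read|not a model file")
  saveRDS(list(format = "missvote-model-99", model = fit), bad)
  expect_error(load_model(bad), "version mismatch")
})

test_that("score tables are written in the published layout", {
  v <- make_keys(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(v, c(0.9, 0.2, 0.5), path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("CHROM", "POS", "REF", "ALT", "score", "class"))
  expect_equal(tab$class, c("deleterious", "benign", "benign"))
})
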