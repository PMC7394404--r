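# soft-voting ensemble: feature selection, training, scoring, persistence

# extract a plain numeric matrix of feature values from the accepted inputs
feature_values <- function(data) {
  if (inherits(data, "labeled_dataset")) return(data$matrix$values)
  if (inherits(data, "feature_matrix")) return(data$values)
  if (is.data.frame(data)) return(as.matrix(data))
  if (is.matrix(data)) return(data)
  stop("expected a labeled_dataset, feature_matrix, data.frame or matrix",
       call. = FALSE)
}

# stratified fold assignment; assumes the RNG is already seeded
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center[colnames(X)], "-"), 2,
        scaler$scale[colnames(X)], "/")
}

# penalty-free logistic regression on a standardized design matrix;
# returns named coefficients (intercept first); aliased terms come back NA
fit_logistic <- function(X, y) {
  d <- cbind(1, X)
  colnames(d) <- c("(Intercept)", colnames(X))
  fit <- suppressWarnings(stats::glm.fit(d, y, family = stats::binomial()))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  coef
}

predict_logistic <- function(coef, X) {
  plogis(drop(coef[1] + X %*% coef[-1][colnames(X)]))
}

#' @importFrom randomForest randomForest
fit_tree <- function(X, y, ntree = 300, mtry = NULL, nodesize = 1) {
  randomForest::randomForest(
    x = X, y = factor(y, levels = c(0L, 1L)),
    ntree = ntree,
    mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(X)))) else min(mtry, ncol(X)),
    nodesize = nodesize)
}

predict_tree <- function(rf, X) {
  unname(predict(rf, X, type = "prob")[, "1"])
}

default_rfe_step <- function(n_remaining) if (n_remaining > 150L) 7L else 1L

#' Rank features by recursive elimination
#'
#' Iteratively trains a learner on the remaining features, records the
#' cross-validated AUC, ranks the features (impurity-based importance for
#' the tree learner, absolute coefficient on standardized inputs for the
#' linear learner) and removes the lowest-ranking ones, down to a single
#' feature. The default step removes 7 features per round while more than
#' 150 remain and 1 thereafter.
#'
#' @param data `labeled_dataset` with both classes present and at least two
#'   features.
#' @param learner `"tree"` (random forest) or `"linear"` (logistic
#'   regression).
#' @param step features removed per round: an integer, or a function of the
#'   number of remaining features; `NULL` for the default schedule.
#' @param cv_folds folds for the per-step AUC estimate.
#' @param seed integer seed.
#' @param ntree trees per forest for the tree learner.
#' @return An `rfe_trace`: list with `elimination_order` (all feature names
#'   in removal order, the last survivor last) and `performance_curve`
#'   (data.frame of `n_features`, `cv_auc`).
#' @export
rfe_rank <- function(data, learner = c("tree", "linear"), step = NULL,
                     cv_folds = 5L, seed = 1L, ntree = 100L) {
  learner <- match.arg(learner)
  X <- feature_values(data)
  y <- data$labels
  if (ncol(X) < 2L) stop("recursive elimination needs at least 2 features", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  step_fun <- if (is.null(step)) default_rfe_step
    else if (is.function(step)) step else function(n) as.integer(step)
  with_seed(seed, {
    remaining <- colnames(X)
    order_out <- character(0)
    curve <- data.frame(n_features = integer(), cv_auc = numeric())
    repeat {
      Xr <- X[, remaining, drop = FALSE]
      fold <- make_folds(y, cv_folds)
      aucs <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        if (learner == "tree") {
          rf <- fit_tree(Xr[tr, , drop = FALSE], y[tr], ntree = ntree)
          p <- predict_tree(rf, Xr[!tr, , drop = FALSE])
        } else {
          sc <- fit_scaler(Xr[tr, , drop = FALSE])
          coef <- fit_logistic(apply_scaler(Xr[tr, , drop = FALSE], sc), y[tr])
          p <- predict_logistic(coef, apply_scaler(Xr[!tr, , drop = FALSE], sc))
        }
        auc_rank(p, y[!tr])
      }, numeric(1))
      curve <- rbind(curve, data.frame(n_features = length(remaining),
                                       cv_auc = mean(aucs)))
      if (length(remaining) == 1L) {
        order_out <- c(order_out, remaining)
        break
      }
      if (learner == "tree") {
        rf <- fit_tree(Xr, y, ntree = ntree)
        imp <- rf$importance[, "MeanDecreaseGini"]
      } else {
        sc <- fit_scaler(Xr)
        coef <- fit_logistic(apply_scaler(Xr, sc), y)
        imp <- abs(coef[-1])[remaining]
      }
      k <- min(max(1L, step_fun(length(remaining))), length(remaining) - 1L)
      drop <- names(sort(imp))[seq_len(k)]
      order_out <- c(order_out, drop)
      remaining <- setdiff(remaining, drop)
    }
    structure(list(elimination_order = order_out, performance_curve = curve,
                   learner = learner),
              class = "rfe_trace")
  })
}

#' Select the k longest-surviving features of an elimination trace
#'
#' @param trace an `rfe_trace`.
#' @param k number of features to keep (`1 <= k <= total`).
#' @return character vector of `k` feature names, longest-surviving first.
#' @export
select_top_k <- function(trace, k) {
  stopifnot(inherits(trace, "rfe_trace"))
  total <- length(trace$elimination_order)
  if (k < 1 || k > total)
    stop(sprintf("k must lie in [1, %d]", total), call. = FALSE)
  rev(trace$elimination_order)[seq_len(k)]
}

default_search_space <- function(p) {
  list(ntree = c(100L, 300L),
       mtry = unique(pmax(1L, floor(c(sqrt(p), p / 4, p / 2)))),
       nodesize = c(1L, 5L, 10L),
       w_tree = c(0.25, 0.5, 0.75, 1),
       w_linear = c(0.25, 0.5, 0.75, 1))
}

#' Fit the soft-voting ensemble
#'
#' Trains a random forest on `features_tree` and a logistic regression on
#' standardized `features_linear`, combining their class-1 probabilities as
#' a weighted average. Hyper-parameters (forest size/shape and the two
#' voting weights) are chosen by randomized search: `n_iter` random draws
#' from `search_space`, each assessed by mean `cv_folds`-fold
#' cross-validated AUC of the soft vote, with standardization refitted on
#' the training folds only. The winning configuration is refitted on the
#' full training set.
#'
#' @param data `labeled_dataset` with finite values on the selected
#'   features.
#' @param features_tree,features_linear feature-name vectors per learner
#'   (default: all features for both; the two lists may differ but scoring
#'   requires both resolvable).
#' @param search_space named list of candidate values for `ntree`, `mtry`,
#'   `nodesize`, `w_tree`, `w_linear`; `NULL` for defaults.
#' @param n_iter randomized-search iterations (default 20).
#' @param cv_folds cross-validation folds per iteration (default 5).
#' @param seed integer seed governing search, folds and forest growth.
#' @param threshold decision cutoff on the voted score (default 0.5; scores
#'   strictly above are called deleterious).
#' @return A fitted `soft_voting_model`.
#' @export
fit_soft_voting <- function(data, features_tree = NULL, features_linear = NULL,
                            search_space = NULL, n_iter = 20L, cv_folds = 5L,
                            seed = 1L, threshold = 0.5) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  X <- feature_values(data)
  y <- data$labels
  features_tree <- features_tree %||% colnames(X)
  features_linear <- features_linear %||% colnames(X)
  miss <- setdiff(union(features_tree, features_linear), colnames(X))
  if (length(miss))
    stop(sprintf("selected features absent from data: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  used <- union(features_tree, features_linear)
  if (!all(is.finite(X[, used])))
    stop("non-finite feature values in the training data", call. = FALSE)
  warnings <- character(0)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (min(tab) == 0L) stop("both classes must be present", call. = FALSE)
  if (max(tab) / min(tab) > 10)
    warnings <- c(warnings, sprintf("class imbalance beyond 10:1 (%d:%d)",
                                    max(tab), min(tab)))
  space <- search_space %||% default_search_space(length(features_tree))
  with_seed(seed, {
    configs <- lapply(seq_len(n_iter), function(i)
      lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
    fold <- make_folds(y, cv_folds)
    cv_auc <- vapply(configs, function(cfg) {
      mean(vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        rf <- fit_tree(X[tr, features_tree, drop = FALSE], y[tr],
                       ntree = cfg$ntree, mtry = cfg$mtry, nodesize = cfg$nodesize)
        sc <- fit_scaler(X[tr, features_linear, drop = FALSE])
        coef <- fit_logistic(apply_scaler(X[tr, features_linear, drop = FALSE], sc), y[tr])
        p_t <- predict_tree(rf, X[!tr, features_tree, drop = FALSE])
        p_l <- predict_logistic(coef, apply_scaler(X[!tr, features_linear, drop = FALSE], sc))
        auc_rank(soft_vote_score(p_t, p_l, c(cfg$w_tree, cfg$w_linear)), y[!tr])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cv_auc)
    cfg <- configs[[best]]
    rf <- fit_tree(X[, features_tree, drop = FALSE], y,
                   ntree = cfg$ntree, mtry = cfg$mtry, nodesize = cfg$nodesize)
    scaler <- fit_scaler(X[, features_linear, drop = FALSE])
    lr_coef <- fit_logistic(apply_scaler(X[, features_linear, drop = FALSE], scaler), y)
    structure(list(
      rf = rf, lr_coef = lr_coef, scaler = scaler,
      features_tree = features_tree, features_linear = features_linear,
      weights = c(tree = cfg$w_tree, linear = cfg$w_linear),
      threshold = threshold,
      train_metadata = list(seed = seed, n_iter = n_iter, cv_folds = cv_folds,
                            best_config = cfg, best_cv_auc = cv_auc[best],
                            cv_auc = cv_auc,
                            class_counts = c(benign = unname(tab["0"]),
                                             deleterious = unname(tab["1"])),
                            warnings = warnings)),
      class = "soft_voting_model")
  })
}

#' Combine two learner probabilities by weighted soft vote
#'
#' @param p_tree,p_linear class-1 probabilities in `[0, 1]`.
#' @param weights nonnegative `(w_tree, w_linear)`, not both zero;
#'   normalized at scoring time.
#' @return `(w_tree * p_tree + w_linear * p_linear) / (w_tree + w_linear)`.
#' @export
soft_vote_score <- function(p_tree, p_linear, weights = c(1, 1)) {
  stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  (weights[1] * p_tree + weights[2] * p_linear) / sum(weights)
}

#' Score variants with a fitted soft-voting model
#'
#' @param model a `soft_voting_model`.
#' @param matrix a `feature_matrix`, data.frame or numeric matrix covering
#'   the model's selected features. For a `feature_matrix`, uncovered cells
#'   on selected features are an error (apply an imputation policy first).
#' @return numeric scores in `[0, 1]`, one per row.
#' @export
predict_score <- function(model, matrix) {
  stopifnot(inherits(model, "soft_voting_model"))
  needed <- union(model$features_tree, model$features_linear)
  if (inherits(matrix, "feature_matrix")) {
    miss <- setdiff(needed, colnames(matrix$values))
    if (length(miss))
      stop(sprintf("feature(s) required by the model are missing: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    uncov <- colSums(!matrix$coverage[, needed, drop = FALSE])
    if (any(uncov > 0))
      stop(sprintf("uncovered values on model feature(s): %s (apply imputation or full-coverage filtering first)",
                   paste(names(uncov)[uncov > 0], collapse = ", ")), call. = FALSE)
    X <- matrix$values
  } else {
    X <- feature_values(matrix)
    miss <- setdiff(needed, colnames(X))
    if (length(miss))
      stop(sprintf("feature(s) required by the model are missing: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(X) == 0L) return(numeric(0))
  p_t <- predict_tree(model$rf, X[, model$features_tree, drop = FALSE])
  p_l <- predict_logistic(model$lr_coef,
                          apply_scaler(X[, model$features_linear, drop = FALSE],
                                       model$scaler))
  soft_vote_score(p_t, p_l, unname(model$weights))
}

#' Binary classification at a threshold
#'
#' Scores strictly above the threshold are called deleterious (1); a score
#' exactly at the threshold is called benign (0) — the conservative choice
#' for clinical shortlists, since the stated rule assigns only the open
#' intervals on either side of 0.5.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision cutoff (default 0.5).
#' @return integer vector of 0/1 calls.
#' @export
classify <- function(scores, threshold = 0.5) {
  stopifnot(all(scores >= 0 & scores <= 1, na.rm = TRUE))
  as.integer(scores > threshold)
}

#' Per-feature relative weights of a fitted model
#'
#' Normalized importance per learner: impurity importance for the forest,
#' absolute standardized coefficient for the logistic regression; each
#' learner's weights sum to 100%.
#'
#' @param model a fitted `soft_voting_model`.
#' @return data.frame with columns `learner`, `feature`, `weight_percent`.
#' @export
feature_weight_report <- function(model) {
  stopifnot(inherits(model, "soft_voting_model"))
  imp <- model$rf$importance[, "MeanDecreaseGini"]
  tree_w <- if (sum(imp) > 0) 100 * imp / sum(imp) else
    rep(100 / length(imp), length(imp))
  coefs <- abs(model$lr_coef[-1])
  lin_w <- if (sum(coefs) > 0) 100 * coefs / sum(coefs) else
    rep(100 / length(coefs), length(coefs))
  rbind(data.frame(learner = "tree", feature = names(tree_w),
                   weight_percent = unname(tree_w), stringsAsFactors = FALSE),
        data.frame(learner = "linear", feature = names(coefs),
                   weight_percent = unname(lin_w), stringsAsFactors = FALSE))
}

MODEL_FORMAT <- "missvote-model-1"

#' Persist and restore a fitted model
#'
#' The archive embeds both learners, the standardization parameters, the
#' selected feature lists, the voting weights, the decision threshold and
#' the training metadata under a format-version tag; restoring yields
#' bit-identical scores.
#'
#' @param model a fitted `soft_voting_model`.
#' @param path file path.
#' @return `load_model` returns the restored `soft_voting_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "soft_voting_model"))
  saveRDS(list(format = MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- tryCatch(readRDS(path),
                error = function(e) stop(sprintf("cannot read model file '%s': %s",
                                                 path, conditionMessage(e)),
                                         call. = FALSE))
  if (!is.list(x) || is.null(x$format))
    stop(sprintf("'%s' is not a model file", path), call. = FALSE)
  if (!identical(x$format, MODEL_FORMAT))
    stop(sprintf("model format version mismatch: file has '%s', expected '%s'",
                 x$format, MODEL_FORMAT), call. = FALSE)
  if (!inherits(x$model, "soft_voting_model"))
    stop(sprintf("'%s' is corrupt: payload is not a soft_voting_model", path),
         call. = FALSE)
  x$model
}

#' @export
print.soft_voting_model <- function(x, ...) {
  cat(sprintf("soft_voting_model: %d tree / %d linear features, weights (%.2f, %.2f), threshold %.2f\n",
              length(x$features_tree), length(x$features_linear),
              x$weights["tree"], x$weights["linear"], x$threshold))
  cat(sprintf("  best cross-validated AUC %.4f over %d search iterations\n",
              x$train_metadata$best_cv_auc, x$train_metadata$n_iter))
  invisible(x)
}

#' Write a score table
#'
#' Tab-separated `CHROM, POS, REF, ALT, score, class` layout (scores to 6
#' decimals), matching the layout of a precomputed-score release.
#'
#' @param variants data.frame of variant keys.
#' @param scores numeric scores.
#' @param path output path.
#' @param threshold classification cutoff.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(variants, scores, path, threshold = 0.5) {
  cls <- classify(scores, threshold)
  out <- data.frame(CHROM = variants$chrom, POS = variants$pos,
                    REF = variants$ref, ALT = variants$alt,
                    score = sprintf("%.6f", scores),
                    class = ifelse(cls == 1L, "deleterious", "benign"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
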