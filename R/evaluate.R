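# confusion-matrix metric panel and evaluation scenarios

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: tied scores receive averaged ranks. Returns
#' `NA` when either class is absent.
#'
#' @param scores continuous scores (higher = more deleterious).
#' @param labels 0/1 true labels.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Tabulate a confusion matrix
#'
#' Positive class = deleterious (1).
#'
#' @param labels true 0/1 labels.
#' @param classes predicted 0/1 classes.
#' @return A `confusion_counts` list with fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, classes) {
  if (length(labels) != length(classes))
    stop("labels and classes must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  classes <- as.integer(classes)
  if (length(labels) && (!all(labels %in% 0:1) || !all(classes %in% 0:1)))
    stop("labels and classes must be binary (0/1)", call. = FALSE)
  structure(list(TP = sum(labels == 1L & classes == 1L),
                 FP = sum(labels == 0L & classes == 1L),
                 TN = sum(labels == 0L & classes == 0L),
                 FN = sum(labels == 1L & classes == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Compute the 12-metric performance panel
#'
#' Derives sensitivity, specificity, precision, negative predictive value,
#' accuracy, F1, Matthews correlation, false positive/negative rates and
#' diagnostic odds ratio from the confusion counts, plus rank-statistic AUC
#' and log loss from the continuous scores. A zero denominator yields `NA`
#' (an explicit undefined marker), except the DOR, which is reported as
#' `+Inf` when `FP * FN = 0` with a positive numerator (optionally replaced
#' by the Haldane-Anscombe +0.5-corrected estimate).
#'
#' Log loss modes: `"probability"` (default) evaluates the divergence on the
#' continuous scores; `"hard_label"` evaluates it on the 0/1 predicted
#' classes — under the clipping constant `eps` each misclassified variant
#' then contributes `-log(eps)`, which reproduces the large log-loss
#' magnitudes conventionally reported alongside thresholded calls.
#'
#' @param counts a `confusion_counts` (or `NULL` to derive from
#'   `classify(scores, threshold)`).
#' @param scores continuous scores in `[0, 1]`.
#' @param labels true 0/1 labels.
#' @param log_loss_mode `"probability"` or `"hard_label"`.
#' @param classes predicted classes (required for `"hard_label"` mode when
#'   `counts` alone cannot supply them); defaults to
#'   `classify(scores, threshold)`.
#' @param threshold cutoff used when deriving classes.
#' @param eps clipping constant for log loss (default `1e-15`).
#' @param dor_correction apply the Haldane-Anscombe +0.5 correction to the
#'   DOR instead of reporting `+Inf` on zero cells.
#' @return A `metrics_report` (named list of numerics, plus the mode used).
#' @export
metric_panel <- function(counts = NULL, scores, labels,
                         log_loss_mode = c("probability", "hard_label"),
                         classes = NULL, threshold = 0.5, eps = 1e-15,
                         dor_correction = FALSE) {
  log_loss_mode <- match.arg(log_loss_mode)
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (is.null(classes)) classes <- classify(scores, threshold)
  if (is.null(counts)) counts <- confusion(labels, classes)
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (TP + FP + TN + FN != length(labels))
    stop("confusion counts do not sum to the number of scored variants",
         call. = FALSE)
  sens <- safe_ratio(TP, TP + FN)
  spec <- safe_ratio(TN, TN + FP)
  prec <- safe_ratio(TP, TP + FP)
  npv <- safe_ratio(TN, TN + FN)
  acc <- (TP + TN) / (TP + FP + TN + FN)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
    else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  dor <- if (dor_correction) {
    ((TP + 0.5) * (TN + 0.5)) / ((FP + 0.5) * (FN + 0.5))
  } else if (FP * FN == 0) {
    if (TP * TN > 0) Inf else NA_real_
  } else (TP * TN) / (FP * FN)
  p <- if (log_loss_mode == "probability") scores else as.numeric(classes)
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 npv = npv, accuracy = acc, f1 = f1, mcc = mcc,
                 auc = auc_rank(scores, labels), log_loss = ll, dor = dor,
                 fpr = if (is.na(spec)) NA_real_ else 1 - spec,
                 fnr = if (is.na(sens)) NA_real_ else 1 - sens,
                 log_loss_mode = log_loss_mode),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (m in setdiff(names(x), "log_loss_mode"))
    cat(sprintf("%-12s %s\n", m, formatC(x[[m]], digits = 4, format = "f")))
  cat(sprintf("%-12s %s\n", "log_loss_mode", x$log_loss_mode))
  invisible(x)
}

#' Diagnostic odds ratio from sensitivity and specificity
#'
#' Closed form `(sens / (1 - sens)) * (spec / (1 - spec))`, used to
#' recompute a DOR from reported rates.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return DOR (may be `+Inf`).
#' @export
dor_from_rates <- function(sensitivity, specificity) {
  (sensitivity / (1 - sensitivity)) * (specificity / (1 - specificity))
}

#' Repeated balanced evaluation over frequency bins
#'
#' For each minor-allele-frequency bin, draws `n_rep` random balanced sets
#' of benign variants (matching the deleterious set size), computes the
#' metric panel per draw, and reports the mean and sample standard
#' deviation (n-1) of every metric.
#'
#' @param del_scores scores of the deleterious set.
#' @param benign data.frame with columns `score`, `maf` and (for the
#'   singleton bin) `allele_count`.
#' @param bins passed to [maf_bin_subsets()].
#' @param n_rep number of balanced draws (default 10).
#' @param seed integer seed.
#' @param threshold classification cutoff.
#' @param log_loss_mode passed to [metric_panel()].
#' @return data.frame with columns `bin`, `metric`, `mean`, `sd`, `n_rep`.
#' @export
repeated_balanced_eval <- function(del_scores, benign,
                                   bins = c(0.01, 0.005, 0.001, 0.0001, "singleton"),
                                   n_rep = 10L, seed = 1L, threshold = 0.5,
                                   log_loss_mode = "hard_label") {
  need_cols(benign, c("score", "maf"), "benign set")
  subsets <- maf_bin_subsets(benign, bins)
  n_del <- length(del_scores)
  for (b in names(subsets))
    if (nrow(subsets[[b]]) < n_del)
      stop(sprintf("insufficient benign pool for bin '%s': %d available, %d required",
                   b, nrow(subsets[[b]]), n_del), call. = FALSE)
  metric_names <- c("sensitivity", "specificity", "precision", "npv", "accuracy",
                    "f1", "mcc", "auc", "log_loss", "dor", "fpr", "fnr")
  out <- list()
  with_seed(seed, {
    for (b in names(subsets)) {
      pool <- subsets[[b]]
      draws <- vapply(seq_len(n_rep), function(r) {
        ben <- pool$score[sample.int(nrow(pool), n_del)]
        scores <- c(del_scores, ben)
        labels <- rep(c(1L, 0L), each = n_del)
        rep_ <- metric_panel(NULL, scores, labels, log_loss_mode = log_loss_mode,
                             threshold = threshold)
        vapply(metric_names, function(m) rep_[[m]], numeric(1))
      }, numeric(length(metric_names)))
      draws <- matrix(draws, nrow = length(metric_names))
      sds <- apply(draws, 1, function(v) if (length(v) > 1) sd(v) else 0)
      sds[!is.finite(sds)] <- NA_real_
      if (n_rep == 1L) sds[] <- 0
      out[[b]] <- data.frame(bin = b, metric = metric_names,
                             mean = rowMeans(draws), sd = sds, n_rep = n_rep,
                             stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop variants lacking a score from any compared tool
#'
#' Mirrors the fair-comparison rule: only variants scored by every tool are
#' kept, and per-tool missingness is reported.
#'
#' @param score_table data.frame with one column per tool (plus any key
#'   columns).
#' @param tool_columns names of the score columns to require.
#' @return list with `table` (the filtered rows) and `missingness`
#'   (named percentages per tool).
#' @export
handle_missing_scores <- function(score_table, tool_columns) {
  need_cols(score_table, tool_columns, "score table")
  n <- nrow(score_table)
  missingness <- vapply(tool_columns, function(col)
    if (n == 0) 0 else 100 * sum(is.na(score_table[[col]])) / n, numeric(1))
  keep <- rowSums(is.na(score_table[, tool_columns, drop = FALSE])) == 0
  list(table = score_table[keep, , drop = FALSE], missingness = missingness)
}

#' Concordance between two classifiers
#'
#' Percentage of variants on which two models emit the same class, overall
#' and stratified by the true label.
#'
#' @param classesA,classesB predicted 0/1 classes.
#' @param labels true 0/1 labels.
#' @return named numeric vector `overall`, `on_positives`, `on_negatives`
#'   (percent; `NA` for an empty stratum).
#' @export
model_concordance <- function(classesA, classesB, labels) {
  if (length(classesA) != length(classesB) || length(classesA) != length(labels))
    stop("classesA, classesB and labels must have equal length", call. = FALSE)
  agree <- classesA == classesB
  pct <- function(idx) if (!any(idx)) NA_real_ else 100 * mean(agree[idx])
  c(overall = if (length(agree)) 100 * mean(agree) else NA_real_,
    on_positives = pct(labels == 1L),
    on_negatives = pct(labels == 0L))
}

#' Export a long-format score table for plotting
#'
#' One row per variant: score, true class, predicted class and the constant
#' threshold — the layout consumed by violin/ROC plotting.
#'
#' @param scores numeric scores.
#' @param labels true 0/1 labels.
#' @param threshold classification cutoff.
#' @param path output path (tab-separated).
#' @return the exported data.frame, invisibly.
#' @export
score_distribution_export <- function(scores, labels, threshold, path) {
  out <- data.frame(score = scores,
                    true_class = ifelse(as.integer(labels) == 1L,
                                        "deleterious", "benign"),
                    predicted_class = ifelse(classify(scores, threshold) == 1L,
                                             "deleterious", "benign"),
                    threshold = rep(threshold, length(scores)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
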