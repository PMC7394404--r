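# independent oracles and small fixture builders used across tests

# all-pairs AUC: exhaustive comparison of every (positive, negative) pair
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  if (!length(s1) || !length(s0)) return(NA_real_)
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct closed-form metric evaluation from raw counts
oracle_panel <- function(TP, FP, TN, FN) {
  list(sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
       npv = if (TN + FN == 0) NA_real_ else TN / (TN + FN),
       accuracy = (TP + TN) / (TP + FP + TN + FN),
       f1 = 2 * TP / (2 * TP + FP + FN),
       mcc = (TP * TN - FP * FN) /
         sqrt((TP + FP)) / sqrt((TP + FN)) / sqrt((TN + FP)) / sqrt((TN + FN)),
       dor = if (FP * FN == 0) {
         if (TP * TN > 0) Inf else NA_real_
       } else (TP * TN) / (FP * FN),
       fpr = FP / (FP + TN),
       fnr = FN / (FN + TP))
}

# two-sided Mann-Whitney p by enumerating rank-sum assignments (ties get
# midranks); independent of the package's pairwise-count formulation
mw_oracle_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  sets <- utils::combn(length(pooled), n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  mean(abs(ws - mu) >= obs - 1e-12)
}

# small all-conservation manifest for cheap synthetic runs
small_manifest <- function(p, prefix = "f") {
  feature_manifest(paste0(prefix, seq_len(p)), "conservation")
}

# minimal variant-key table
make_keys <- function(n, chrom = "1") {
  data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 100L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             stringsAsFactors = FALSE)
}
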