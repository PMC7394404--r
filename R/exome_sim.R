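# spike-in disease-exome simulation and causative-variant ranking

#' Apply clinical exome filters
#'
#' Community best-practice shortlist filters: depth strictly above
#' `min_depth` (default 10X) and minor allele frequency strictly below
#' `maf_max` (default 1%) in control populations; a variant with no MAF
#' annotation passes the frequency filter (rare/novel variants lack one).
#' Exclusion-list members are removed afterwards.
#'
#' @param variants data.frame with key columns plus `depth` and `maf`
#'   (`maf` may be `NA`).
#' @param min_depth depth cutoff in reads.
#' @param maf_max frequency cutoff.
#' @param exclusions optional list of exclusion lists (see
#'   [apply_circularity_filter()]).
#' @return the filtered data.frame.
#' @export
apply_exome_filters <- function(variants, min_depth = 10, maf_max = 0.01,
                                exclusions = NULL) {
  need_cols(variants, c("chrom", "pos", "ref", "alt", "depth"), "variants")
  maf <- if ("maf" %in% names(variants)) variants$maf else rep(NA_real_, nrow(variants))
  keep <- variants$depth > min_depth & (is.na(maf) | maf < maf_max)
  out <- variants[keep, , drop = FALSE]
  if (!is.null(exclusions) && length(exclusions))
    out <- apply_circularity_filter(out, exclusions)
  out
}

#' Spike a causative deleterious variant into a background exome
#'
#' Builds a simulated disease exome: the healthy background plus exactly one
#' causative variant. When `causative` contains several candidate variants,
#' one is drawn under `seed`.
#'
#' @param background data.frame of background variants (key columns, plus a
#'   `score` column if already scored).
#' @param causative one-row data.frame, or a pool to draw from.
#' @param seed integer seed governing the draw from a pool.
#' @param exome_id identifier carried into downstream ranking reports.
#' @return A `simulated_exome`: list with `variants` (background plus the
#'   spiked variant), `causative_id`, `exome_id`.
#' @export
spike_causative <- function(background, causative, seed = 1L, exome_id = "exome_1") {
  need_cols(background, c("chrom", "pos", "ref", "alt"), "background")
  need_cols(causative, c("chrom", "pos", "ref", "alt"), "causative")
  pick <- if (nrow(causative) > 1L)
    with_seed(seed, causative[sample.int(nrow(causative), 1L), , drop = FALSE])
  else causative
  cid <- variant_id(pick)
  if (cid %in% variant_id(background))
    stop(sprintf("causative variant %s is already present in the background exome", cid),
         call. = FALSE)
  common <- intersect(names(background), names(pick))
  variants <- rbind(background[, common, drop = FALSE], pick[, common, drop = FALSE])
  rownames(variants) <- NULL
  structure(list(variants = variants, causative_id = cid, exome_id = exome_id,
                 filters_applied = attr(background, "filters_applied")),
            class = "simulated_exome")
}

#' Rank the causative variant within a scored exome
#'
#' Variants are sorted by descending score; the causative rank is 1 plus
#' the number of variants scoring strictly higher (ties share the best
#' rank — optimistic competition ranking; set `ties = "pessimistic"` to
#' count ties against the causative). Also reports the percentage of exome
#' variants classified deleterious at the threshold.
#'
#' @param scored_exome a `simulated_exome` whose `variants` carry a
#'   `score` column, or a data.frame with key and `score` columns plus a
#'   designated causative.
#' @param causative_id key of the causative variant (taken from the
#'   `simulated_exome` when omitted).
#' @param threshold classification cutoff.
#' @param ties `"optimistic"` (default) or `"pessimistic"`.
#' @return A `ranking_result`: list with `exome_id`, `causative_rank`,
#'   `n_variants`, `percent_deleterious`.
#' @export
rank_causative <- function(scored_exome, causative_id = NULL, threshold = 0.5,
                           ties = c("optimistic", "pessimistic")) {
  ties <- match.arg(ties)
  if (inherits(scored_exome, "simulated_exome")) {
    variants <- scored_exome$variants
    causative_id <- causative_id %||% scored_exome$causative_id
    exome_id <- scored_exome$exome_id
  } else {
    variants <- scored_exome
    exome_id <- attr(scored_exome, "exome_id") %||% "exome"
    if (is.null(causative_id)) stop("causative_id is required", call. = FALSE)
  }
  need_cols(variants, c("chrom", "pos", "ref", "alt", "score"), "scored exome")
  if (anyNA(variants$score))
    stop("every exome variant must carry a score", call. = FALSE)
  ids <- variant_id(variants)
  ci <- match(causative_id, ids)
  if (is.na(ci))
    stop(sprintf("causative variant %s not found in the exome", causative_id),
         call. = FALSE)
  cs <- variants$score[ci]
  rank <- if (ties == "optimistic") 1L + sum(variants$score > cs)
    else sum(variants$score >= cs)
  structure(list(exome_id = exome_id, causative_rank = as.integer(rank),
                 n_variants = nrow(variants),
                 percent_deleterious =
                   100 * mean(classify(variants$score, threshold) == 1L)),
            class = "ranking_result")
}

#' Summarize causative-variant rankings over simulated exomes
#'
#' @param results list of `ranking_result` objects (nonempty).
#' @return list with `n_exomes`, `median_rank`, `mean_rank`, `sd_rank`,
#'   `mean_percent_deleterious`, `sd_percent_deleterious` (sample sd; 0 for
#'   a single exome).
#' @export
summarize_rankings <- function(results) {
  if (!length(results)) stop("no ranking results to summarize", call. = FALSE)
  ranks <- vapply(results, function(r) as.numeric(r$causative_rank), numeric(1))
  pdel <- vapply(results, function(r) r$percent_deleterious, numeric(1))
  sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
  list(n_exomes = length(results),
       median_rank = median(ranks), mean_rank = mean(ranks), sd_rank = sd0(ranks),
       mean_percent_deleterious = mean(pdel),
       sd_percent_deleterious = sd0(pdel))
}

# exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments of the combined sample (handles ties; U counts 0.5 per tie)
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- n1 * length(b) / 2
  obs <- abs(u_stat(a, b) - mu)
  sets <- combn(length(pooled), n1)
  us <- apply(sets, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= obs - 1e-12)
}

#' Compare two rank distributions (two-sided Mann-Whitney)
#'
#' Exact enumeration of all group assignments for combined sample sizes up
#' to 12 (valid under ties); the normal approximation with tie correction
#' (no continuity correction) is used for larger samples.
#'
#' @param ranksA,ranksB numeric vectors (e.g. causative ranks per tool),
#'   both nonempty.
#' @return list with `p_value`, `method` (`"exact"` or
#'   `"normal_approximation"`), and the sample sizes.
#' @export
compare_rank_distributions <- function(ranksA, ranksB) {
  if (!length(ranksA) || !length(ranksB))
    stop("both rank samples must be nonempty", call. = FALSE)
  if (length(ranksA) + length(ranksB) <= 12L) {
    p <- mw_exact_p(ranksA, ranksB)
    method <- "exact"
  } else {
    p <- suppressWarnings(wilcox.test(ranksA, ranksB, exact = FALSE,
                                      correct = FALSE)$p.value)
    method <- "normal_approximation"
  }
  list(p_value = min(p, 1), method = method,
       n = c(A = length(ranksA), B = length(ranksB)))
}

#' Order an exome report deterministically
#'
#' Stable descending-score sort with `(chrom, pos)` as tiebreaker, used for
#' reported orderings.
#'
#' @param variants data.frame with `score`, `chrom`, `pos` columns.
#' @return the reordered data.frame.
#' @export
sort_by_score <- function(variants) {
  need_cols(variants, c("score", "chrom", "pos"), "variants")
  ord <- order(-variants$score, as.character(variants$chrom), variants$pos)
  out <- variants[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
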