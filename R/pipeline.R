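# end-to-end helpers tying the modules together

#' Run a spike-in disease-exome ranking study
#'
#' Generates a scored synthetic cohort: a benign-profile variant pool forms
#' the healthy background exomes and a deleterious-profile pool supplies
#' the causative variants. For each simulated exome, `exome_size`
#' background variants are drawn, the clinical depth/frequency filters are
#' applied, one causative variant is spiked in, every variant is scored by
#' the model, and the causative rank and the percentage of variants called
#' deleterious are recorded.
#'
#' @param model a fitted `soft_voting_model`.
#' @param n_exomes number of simulated exomes (default 50).
#' @param exome_size background missense variants per exome before
#'   filtering (default 420).
#' @param effect_size class separation of the generating distributions.
#' @param seed integer seed.
#' @param manifest manifest used for the pool (default [default_manifest()];
#'   must cover the model's features).
#' @param pool_per_class pool size per class (default
#'   `max(1000, 2 * exome_size)`).
#' @param min_depth,maf_max clinical filter cutoffs.
#' @param threshold classification cutoff.
#' @return list with `per_exome` (data.frame of `exome_id`,
#'   `causative_rank`, `n_variants`, `percent_deleterious`), `results`
#'   (the `ranking_result` objects) and `summary`
#'   (see [summarize_rankings()]).
#' @export
simulate_exome_study <- function(model, n_exomes = 50L, exome_size = 420L,
                                 effect_size = 3, seed = 1L,
                                 manifest = default_manifest(),
                                 pool_per_class = NULL,
                                 min_depth = 10, maf_max = 0.01,
                                 threshold = 0.5) {
  pool_per_class <- pool_per_class %||% max(1000L, 2L * exome_size)
  pool <- generate_labeled_features(pool_per_class, manifest = manifest,
                                    effect_size = effect_size, seed = seed)
  scores <- predict_score(model, pool$matrix)
  vars <- pool$matrix$variants
  vars$score <- scores
  ben <- vars[pool$labels == 0L, , drop = FALSE]
  del <- vars[pool$labels == 1L, , drop = FALSE]
  results <- with_seed(seed, lapply(seq_len(n_exomes), function(e) {
    bg <- ben[sample.int(nrow(ben), min(exome_size, nrow(ben))), , drop = FALSE]
    bg <- apply_exome_filters(bg, min_depth = min_depth, maf_max = maf_max)
    caus <- del[sample.int(nrow(del), 1L), , drop = FALSE]
    # the pool keys are unique, but the draw could in principle collide
    while (variant_id(caus) %in% variant_id(bg))
      caus <- del[sample.int(nrow(del), 1L), , drop = FALSE]
    ex <- spike_causative(bg, caus, exome_id = sprintf("exome_%03d", e))
    rank_causative(ex, threshold = threshold)
  }))
  per_exome <- data.frame(
    exome_id = vapply(results, `[[`, "", "exome_id"),
    causative_rank = vapply(results, function(r) r$causative_rank, integer(1)),
    n_variants = vapply(results, function(r) r$n_variants, integer(1)),
    percent_deleterious = vapply(results, function(r) r$percent_deleterious,
                                 numeric(1)),
    stringsAsFactors = FALSE)
  list(per_exome = per_exome, results = results,
       summary = summarize_rankings(results))
}

#' Read a flat key-value run configuration
#'
#' Minimal configuration format for reproducible command-line runs:
#' `key = value` lines grouped under `[section]` headers; `#` starts a
#' comment. Values are returned as strings; command-line flags take
#' precedence over configuration values.
#'
#' @param path configuration file.
#' @param section optional section to extract (otherwise the full nested
#'   list is returned).
#' @return named list (of named lists when `section` is `NULL`).
#' @export
read_run_config <- function(path, section = NULL) {
  lines <- readLines(path)
  out <- list()
  current <- "global"
  out[[current]] <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      current <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[current]])) out[[current]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("malformed config line %d: '%s'", i, lines[i]), call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    out[[current]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  if (is.null(section)) out else out[[section]] %||% list()
}
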