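# training / evaluation dataset construction: the filter cascade

#' Construct a labeled dataset
#'
#' @param matrix a `feature_matrix`.
#' @param labels integer vector of 0 (benign) / 1 (deleterious), one per row.
#' @param provenance per-variant source tag (e.g. `"clinvar"`, `"gnomad"`,
#'   `"synthetic"`); recycled if length 1.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(matrix, labels, provenance = "unknown") {
  stopifnot(inherits(matrix, "feature_matrix"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix$values))
    stop("labels length must equal the number of variants", call. = FALSE)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (benign) or 1 (deleterious)", call. = FALSE)
  provenance <- rep_len(as.character(provenance), length(labels))
  structure(list(matrix = matrix, labels = labels, provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d variants (%d deleterious / %d benign), %d features\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$matrix$values)))
  invisible(x)
}

# subset a labeled_dataset by row index
subset_dataset <- function(data, idx) {
  m <- data$matrix
  labeled_dataset(feature_matrix(m$variants[idx, , drop = FALSE], m$manifest,
                                 m$values[idx, , drop = FALSE],
                                 m$coverage[idx, , drop = FALSE]),
                  data$labels[idx], data$provenance[idx])
}

#' Select high-confidence pathogenic variants from ClinVar-style records
#'
#' Keeps records whose clinical significance is exactly `Pathogenic` (the
#' high-confidence filter deliberately excludes `Likely_pathogenic`) and
#' whose review status indicates criteria provided by multiple submitters,
#' review by an expert panel, or a practice guideline, with no conflicting
#' interpretations.
#'
#' @param records data.frame with key columns `chrom`, `pos`, `ref`, `alt`
#'   plus significance and review-status columns.
#' @param clnsig_col,clnrevstat_col column names carrying the significance
#'   and review-status strings (ClinVar INFO-key defaults).
#' @return data.frame of the unique surviving variant keys.
#' @export
select_clinvar_positives <- function(records, clnsig_col = "CLNSIG",
                                     clnrevstat_col = "CLNREVSTAT") {
  need_cols(records, c("chrom", "pos", "ref", "alt"), "records")
  if (!clnsig_col %in% names(records))
    stop(sprintf("records lack the clinical-significance column '%s'", clnsig_col),
         call. = FALSE)
  if (!clnrevstat_col %in% names(records))
    stop(sprintf("records lack the review-status column '%s'", clnrevstat_col),
         call. = FALSE)
  sig <- as.character(records[[clnsig_col]])
  rev <- as.character(records[[clnrevstat_col]])
  rev[is.na(rev)] <- ""
  high_conf <- (grepl("criteria_provided", rev) & grepl("multiple_submitters", rev)) |
    grepl("reviewed_by_expert_panel", rev) | grepl("practice_guideline", rev)
  keep <- !is.na(sig) & sig == "Pathogenic" & high_conf & !grepl("conflicting", rev)
  unique(records[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE])
}

#' Select disease-mutation positives from HGMD-style records
#'
#' Keeps records whose status tag is exactly `DM` (questioned `DM?` entries
#' are excluded by the high-confidence filter).
#'
#' @param records data.frame with key columns plus a status column.
#' @param status_col column carrying the status tag.
#' @return data.frame of the unique surviving variant keys.
#' @export
select_hgmd_positives <- function(records, status_col = "STATUS") {
  need_cols(records, c("chrom", "pos", "ref", "alt"), "records")
  if (!status_col %in% names(records))
    stop(sprintf("records lack the status column '%s'", status_col), call. = FALSE)
  keep <- !is.na(records[[status_col]]) & records[[status_col]] == "DM"
  unique(records[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE])
}

#' Select rare, well-covered population variants as benign candidates
#'
#' Applies the population-database negative-set filter: global minor allele
#' frequency strictly below `maf_max`, sequencing depth strictly above
#' `min_depth`, and exclusion of any key present in the positive sources.
#' Both inequalities are strict, taken literally from the stated cutoffs
#' (MAF < 1%, depth > 30X).
#'
#' @param records data.frame with key columns plus MAF and depth columns.
#' @param maf_max frequency cutoff (default 0.01).
#' @param min_depth depth cutoff in reads (default 30).
#' @param exclusion optional data.frame of keys to remove (e.g. the merged
#'   positive set).
#' @param maf_col,depth_col column names for frequency and depth.
#' @return data.frame of the unique surviving variant keys.
#' @export
select_population_negatives <- function(records, maf_max = 0.01, min_depth = 30,
                                        exclusion = NULL, maf_col = "MAF",
                                        depth_col = "DP") {
  need_cols(records, c("chrom", "pos", "ref", "alt", maf_col, depth_col), "records")
  maf <- as.numeric(records[[maf_col]])
  dp <- as.numeric(records[[depth_col]])
  keep <- !is.na(maf) & !is.na(dp) & maf < maf_max & dp > min_depth
  out <- records[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  if (!is.null(exclusion) && nrow(exclusion))
    out <- out[!(variant_id(out) %in% variant_id(exclusion)), , drop = FALSE]
  unique(out)
}

#' Remove variants that overlap component-predictor training sets
#'
#' Drops every key present in any exclusion list, preventing type 1
#' circularity errors (evaluating or training on variants a component
#' predictor has already seen). Per-list removal counts are attached as the
#' `removal_counts` attribute.
#'
#' @param keys data.frame of variant keys.
#' @param exclusions list of exclusion lists; each element either a
#'   data.frame of keys or a list with fields `name` and `keys`.
#' @return The filtered key data.frame, with attribute `removal_counts`
#'   (named integer vector, removals attributed per list).
#' @export
apply_circularity_filter <- function(keys, exclusions = list()) {
  need_cols(keys, c("chrom", "pos", "ref", "alt"), "keys")
  ids <- variant_id(keys)
  counts <- integer(0)
  drop <- rep(FALSE, nrow(keys))
  for (i in seq_along(exclusions)) {
    ex <- exclusions[[i]]
    nm <- names(exclusions)[i]
    if (is.list(ex) && !is.data.frame(ex) && !is.null(ex$keys)) {
      nm <- ex$name %||% nm
      ex <- ex$keys
    }
    if (is.null(nm) || is.na(nm) || nm == "") nm <- sprintf("exclusion_%d", i)
    hit <- ids %in% variant_id(ex)
    counts[nm] <- sum(hit)
    drop <- drop | hit
  }
  out <- keys[!drop, , drop = FALSE]
  attr(out, "removal_counts") <- counts
  out
}

#' Balance the negative pool and split into training and test sets
#'
#' Subsamples the benign pool without replacement to the size of the
#' positive set, then splits each class at `train_fraction` (floor
#' rounding), reproducibly under `seed`.
#'
#' @param pos `labeled_dataset` of positives (labels all 1).
#' @param neg_pool `labeled_dataset` pool of negatives (labels all 0), at
#'   least as large as `pos`.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.9).
#' @param seed integer seed.
#' @return list with `labeled_dataset` elements `train` and `test`.
#' @export
balance_and_split <- function(pos, neg_pool, train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(pos, "labeled_dataset"), inherits(neg_pool, "labeled_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  n_pos <- length(pos$labels)
  n_neg <- length(neg_pool$labels)
  if (n_neg < n_pos)
    stop(sprintf("insufficient negatives: %d required, %d available", n_pos, n_neg),
         call. = FALSE)
  with_seed(seed, {
    neg <- subset_dataset(neg_pool, sort(sample.int(n_neg, n_pos)))
    n_train <- floor(train_fraction * n_pos)
    pos_train <- sort(sample.int(n_pos, n_train))
    neg_train <- sort(sample.int(n_pos, n_train))
    train <- bind_datasets(subset_dataset(pos, pos_train),
                           subset_dataset(neg, neg_train))
    test <- bind_datasets(subset_dataset(pos, setdiff(seq_len(n_pos), pos_train)),
                          subset_dataset(neg, setdiff(seq_len(n_pos), neg_train)))
    list(train = train, test = test)
  })
}

#' Concatenate labeled datasets sharing a manifest
#'
#' @param ... `labeled_dataset` objects with identical manifests.
#' @return A single `labeled_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  m1 <- parts[[1]]$matrix$manifest
  for (p in parts)
    if (!identical(p$matrix$manifest$name, m1$name))
      stop("datasets use different manifests", call. = FALSE)
  labeled_dataset(
    feature_matrix(do.call(rbind, lapply(parts, function(p) p$matrix$variants)),
                   m1,
                   do.call(rbind, lapply(parts, function(p) p$matrix$values)),
                   do.call(rbind, lapply(parts, function(p) p$matrix$coverage))),
    unlist(lapply(parts, function(p) p$labels)),
    unlist(lapply(parts, function(p) p$provenance)))
}

#' Partition benign variants into minor-allele-frequency bins
#'
#' The evaluation bins are nested frequency cutoffs (`MAF < 0.01`, `< 0.005`,
#' `< 0.001`, `< 0.0001`) plus a `singleton` bin defined by allele count
#' exactly 1.
#'
#' @param benign data.frame with columns `maf` and (for the singleton bin)
#'   `allele_count`; extra columns are carried through.
#' @param bins numeric frequency cutoffs and/or the string `"singleton"`.
#' @return named list of data.frames, one per bin (names `maf_lt_<cutoff>`
#'   or `singleton`).
#' @export
maf_bin_subsets <- function(benign,
                            bins = c(0.01, 0.005, 0.001, 0.0001, "singleton")) {
  need_cols(benign, "maf", "benign set")
  out <- list()
  for (b in bins) {
    if (identical(b, "singleton")) {
      if (!"allele_count" %in% names(benign))
        stop("singleton bin requested but benign set has no 'allele_count' column",
             call. = FALSE)
      out[["singleton"]] <- benign[!is.na(benign$allele_count) &
                                     benign$allele_count == 1, , drop = FALSE]
    } else {
      cutoff <- as.numeric(b)
      out[[paste0("maf_lt_", format(cutoff, scientific = FALSE))]] <-
        benign[!is.na(benign$maf) & benign$maf < cutoff, , drop = FALSE]
    }
  }
  out
}

#' Read / write exclusion lists as plain-text key files
#'
#' One `chrom:pos:ref:alt` key per line.
#'
#' @param path file path.
#' @param keys data.frame of variant keys (for writing).
#' @return `read_exclusion_list` returns a data.frame of keys.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop(sprintf("malformed exclusion key on line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 3),
             alt = vapply(parts, `[`, "", 4), stringsAsFactors = FALSE)
}

#' @rdname read_exclusion_list
#' @export
write_exclusion_list <- function(keys, path) {
  writeLines(variant_id(keys), path)
  invisible(path)
}
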