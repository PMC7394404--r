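# synthetic variants, feature tables and background exomes
#
# These generators emulate the statistical structure of the curated
# training sources — deleterious variants skewed to absent/very low allele
# frequency and high conservation/predictor scores, benign variants rare
# but observed, population frequency columns correlated through a shared
# latent frequency — so that every pipeline stage is testable without the
# licensed databases.

random_variant_keys <- function(n) {
  bases <- c("A", "C", "G", "T")
  aa <- amino_acids()
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ref_aa <- sample(aa, n, replace = TRUE)
  alt_aa <- vapply(ref_aa, function(r) sample(setdiff(aa, r), 1L), character(1))
  data.frame(chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sample.int(5e7, n),
             ref = unname(ref), alt = unname(alt),
             ref_aa = unname(ref_aa), alt_aa = unname(alt_aa),
             gene = paste0("GENE", sample.int(2000, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

# draw n variant keys with unique (chrom,pos,ref,alt)
unique_variant_keys <- function(n) {
  keys <- random_variant_keys(ceiling(n * 1.2) + 10L)
  keys <- keys[!duplicated(variant_id(keys)), , drop = FALSE]
  while (nrow(keys) < n) {
    keys <- rbind(keys, random_variant_keys(n))
    keys <- keys[!duplicated(variant_id(keys)), , drop = FALSE]
  }
  keys <- keys[seq_len(n), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

# class-conditional MAF draw; the deleterious profile interpolates toward
# the benign profile as effect_size -> 0 so a zero effect size is a true
# null (identical class-conditional distributions everywhere)
draw_maf <- function(n, deleterious, effect_size, an = 100000L) {
  benign_ac <- function(n) pmax(1L, as.integer(round(an * 0.01 * rbeta(n, 0.5, 3))))
  if (!deleterious) {
    ac <- benign_ac(n)
  } else {
    w <- min(effect_size / 3, 1)      # full deleterious profile at >= 3 sd
    del_profile <- runif(n) < w
    ac <- integer(n)
    absent <- del_profile & (runif(n) < 0.85)
    ac[absent] <- 0L
    ac[del_profile & !absent] <- sample(1:3, sum(del_profile & !absent), replace = TRUE)
    ac[!del_profile] <- benign_ac(sum(!del_profile))
  }
  list(ac = ac, an = an, maf = ac / an)
}

#' Generate a synthetic labeled feature dataset
#'
#' Samples class-conditional feature values over a manifest: MAF features
#' from a rare-variant profile (deleterious variants mostly absent from the
#' population, benign variants rare but observed, population columns tied
#' to the global frequency through multiplicative noise), conservation and
#' functional-score features from unit-variance Gaussians whose class means
#' differ by `effect_size`, predictor features as logistic transforms of
#' the same, and substitution features by matrix lookup on each variant's
#' random amino-acid change. A fraction of the conservation / functional /
#' predictor columns is made label-independent. At `effect_size = 0` the
#' two classes have identical distributions in every feature (a true null).
#'
#' @param n_per_class variants per class.
#' @param manifest a `feature_manifest` (default [default_manifest()]).
#' @param effect_size class separation in standard deviations (default 3).
#' @param noise_fraction fraction of non-MAF, non-substitution features made
#'   label-independent (default 0.1).
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and the seed.
#' @param aaindex_set substitution matrices resolving the manifest's matrix
#'   identifiers (default: synthetic set derived from `seed`).
#' @param coverage_gap_fraction fraction of matrix cells marked unannotated
#'   (default 0, i.e. full coverage).
#' @return A `labeled_dataset` whose `matrix$variants` additionally carries
#'   `maf`, `allele_count`, `allele_number` and `depth` columns.
#' @export
generate_labeled_features <- function(n_per_class, manifest = default_manifest(),
                                      effect_size = 3, noise_fraction = 0.1,
                                      seed = 1L, aaindex_set = NULL,
                                      coverage_gap_fraction = 0) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must lie in [0, 1]", call. = FALSE)
  if (coverage_gap_fraction < 0 || coverage_gap_fraction > 1)
    stop("coverage_gap_fraction must lie in [0, 1]", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be nonnegative", call. = FALSE)
  aa_ids <- manifest$source_column[manifest$category == "functional" &
                                     grepl("^aaindex_", manifest$name)]
  if (is.null(aaindex_set) && length(aa_ids))
    aaindex_set <- synthetic_aaindex_set(aa_ids, seed = seed + 1000L)
  with_seed(seed, {
    n <- 2L * n_per_class
    labels <- rep(c(1L, 0L), each = n_per_class)
    variants <- unique_variant_keys(n)
    del <- labels == 1L
    maf_del <- draw_maf(n_per_class, TRUE, effect_size)
    maf_ben <- draw_maf(n_per_class, FALSE, effect_size)
    maf <- numeric(n); ac <- integer(n)
    maf[del] <- maf_del$maf; maf[!del] <- maf_ben$maf
    ac[del] <- maf_del$ac; ac[!del] <- maf_ben$ac
    variants$maf <- maf
    variants$allele_count <- ac
    variants$allele_number <- maf_del$an
    variants$depth <- pmax(0L, as.integer(round(rnorm(n, 50, 15))))

    p <- nrow(manifest)
    values <- matrix(NA_real_, n, p)
    colnames(values) <- manifest$name
    is_aaindex <- manifest$source_column %in% names(aaindex_set)
    shiftable <- which(!is_aaindex & manifest$category != "MAF")
    noise_cols <- sample(shiftable, floor(noise_fraction * length(shiftable)))
    for (j in seq_len(p)) {
      cat_j <- manifest$category[j]
      if (cat_j == "MAF") {
        values[, j] <- if (manifest$population[j] == "global") maf else
          pmin(1, maf * exp(rnorm(n, 0, 0.3)))
      } else if (is_aaindex[j]) {
        m <- aaindex_set[[manifest$source_column[j]]]$values
        values[, j] <- m[cbind(variants$ref_aa, variants$alt_aa)]
      } else {
        shift <- if (j %in% noise_cols) 0 else effect_size
        z <- rnorm(n) + ifelse(del, shift, 0)
        values[, j] <- if (cat_j == "predictor") plogis(z - shift / 2) else z
      }
    }
    coverage <- matrix(TRUE, n, p)
    if (coverage_gap_fraction > 0) {
      gaps <- sample.int(n * p, floor(coverage_gap_fraction * n * p))
      coverage[gaps] <- FALSE
      values[gaps] <- NA_real_
    }
    labeled_dataset(feature_matrix(variants, manifest, values, coverage),
                    labels, provenance = "synthetic")
  })
}

#' Generate a synthetic healthy background exome
#'
#' Emits benign-profile missense variants with depth and frequency
#' annotations tuned so that a configurable fraction survives the clinical
#' depth/frequency filters, together with a keyed annotation table in the
#' layout the joining step reads.
#'
#' @param n_variants number of variants.
#' @param maf_profile list with `absent_fraction` (no MAF annotation),
#'   `shape1`, `shape2`, `max` (scaled-Beta frequency draw).
#' @param depth_profile list with `mean`, `sd` of the read-depth draw.
#' @param seed integer seed.
#' @return list with `variants` (keys plus `maf`, `allele_count`, `depth`)
#'   and `annotation` (the same values keyed by upper-case `CHROM`, `POS`,
#'   `REF`, `ALT` columns).
#' @export
generate_background_exome <- function(n_variants,
                                      maf_profile = list(absent_fraction = 0.25,
                                                         shape1 = 0.5, shape2 = 3,
                                                         max = 0.012),
                                      depth_profile = list(mean = 50, sd = 18),
                                      seed = 1L) {
  if (n_variants < 1) stop("n_variants must be >= 1", call. = FALSE)
  with_seed(seed, {
    variants <- unique_variant_keys(n_variants)
    maf <- maf_profile$max * rbeta(n_variants, maf_profile$shape1, maf_profile$shape2)
    an <- 100000L
    ac <- pmax(1L, as.integer(round(maf * an)))
    maf <- ac / an
    absent <- runif(n_variants) < maf_profile$absent_fraction
    maf[absent] <- NA_real_
    ac[absent] <- NA_integer_
    variants$maf <- maf
    variants$allele_count <- ac
    variants$depth <- pmax(0L, as.integer(round(rnorm(n_variants, depth_profile$mean,
                                                      depth_profile$sd))))
    annotation <- data.frame(CHROM = variants$chrom, POS = variants$pos,
                             REF = variants$ref, ALT = variants$alt,
                             maf = variants$maf, allele_count = variants$allele_count,
                             depth = variants$depth, stringsAsFactors = FALSE)
    list(variants = variants, annotation = annotation)
  })
}

#' Write variants as a well-formed fixture VCF
#'
#' Emits VCF v4.2 with configurable INFO keys so that the ingestion and
#' filter stages can be exercised end-to-end: a consequence key (defaults
#' to `MC=missense_variant`; a per-variant `consequence` column overrides,
#' `NA` omits the key), an amino-acid-change key (`AA=R/Q`), a gene key,
#' and any extra per-variant INFO fields supplied as columns of
#' `info_fields` (clinical-significance, review-status, status, frequency,
#' allele-count or depth style keys; `NA` cells are omitted).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optional `ref_aa`, `alt_aa`, `gene`, `consequence` columns; may have
#'   zero rows (header-only VCF).
#' @param path output path.
#' @param info_fields optional data.frame (same row count) whose columns
#'   become INFO keys.
#' @param consequence_key,aa_key,gene_key INFO key names.
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(variants, path, info_fields = NULL,
                              consequence_key = "MC", aa_key = "AA",
                              gene_key = "GENE") {
  if (!is.null(info_fields) && nrow(variants) &&
      nrow(info_fields) != nrow(variants))
    stop("info_fields must have one row per variant", call. = FALSE)
  keys_used <- c(consequence_key, aa_key, gene_key, names(info_fields))
  header <- c("##fileformat=VCFv4.2",
              sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
                      keys_used, keys_used),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                    collapse = "\t"))
  lines <- character(0)
  for (i in seq_len(nrow(variants))) {
    info <- character(0)
    csq <- if ("consequence" %in% names(variants)) variants$consequence[i]
      else "missense_variant"
    if (!is.na(csq)) info <- c(info, paste0(consequence_key, "=", csq))
    if (all(c("ref_aa", "alt_aa") %in% names(variants)) &&
        !is.na(variants$ref_aa[i]) && !is.na(variants$alt_aa[i]))
      info <- c(info, paste0(aa_key, "=", variants$ref_aa[i], "/", variants$alt_aa[i]))
    if ("gene" %in% names(variants) && !is.na(variants$gene[i]))
      info <- c(info, paste0(gene_key, "=", variants$gene[i]))
    for (k in names(info_fields)) {
      v <- info_fields[[k]][i]
      if (!is.na(v)) info <- c(info, paste0(k, "=", v))
    }
    lines <- c(lines, paste(variants$chrom[i], variants$pos[i], ".",
                            variants$ref[i], variants$alt[i], ".", "PASS",
                            if (length(info)) paste(info, collapse = ";") else ".",
                            sep = "\t"))
  }
  ok <- tryCatch({ writeLines(c(header, lines), path); TRUE },
                 error = function(e) stop(sprintf("cannot write VCF to '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  invisible(path)
}
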