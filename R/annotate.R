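# VCF ingestion and feature-table joining

#' Construct a feature matrix
#'
#' Couples per-variant keys with a numeric value matrix laid out by a
#' manifest, plus a coverage mask recording which cells were actually
#' annotated. Values are only meaningful where coverage is `TRUE`.
#'
#' @param variants data.frame of variant keys (`chrom`, `pos`, `ref`, `alt`,
#'   optionally `ref_aa`, `alt_aa`, `gene`).
#' @param manifest a `feature_manifest`.
#' @param values numeric matrix, rows = variants, columns = manifest order.
#' @param coverage logical matrix of the same shape (`TRUE` = annotated).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(variants, manifest, values, coverage) {
  values <- as.matrix(values)
  coverage <- as.matrix(coverage)
  stopifnot(nrow(values) == nrow(variants),
            ncol(values) == nrow(manifest),
            all(dim(values) == dim(coverage)))
  if (any(!is.finite(values[coverage])))
    stop("feature values must be finite wherever coverage is TRUE", call. = FALSE)
  colnames(values) <- manifest$name
  colnames(coverage) <- manifest$name
  structure(list(variants = variants, manifest = manifest,
                 values = values, coverage = coverage),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d variants x %d features (%.1f%% cells covered)\n",
              nrow(x$values), ncol(x$values),
              if (length(x$coverage)) 100 * mean(x$coverage) else 100))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# light structural validation of variant lines, so parse failures carry a
# line number; the heavy lifting is done by vcfR afterwards
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L)
      stop(sprintf("malformed VCF line %d: expected >= 8 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    if (is.na(suppressWarnings(as.integer(fields[2]))))
      stop(sprintf("malformed VCF line %d: POS '%s' is not an integer", i, fields[2]),
           call. = FALSE)
    if (fields[4] == "" || fields[5] == "")
      stop(sprintf("malformed VCF line %d: empty REF or ALT", i), call. = FALSE)
  }
  invisible(TRUE)
}

# INFO key extraction from raw INFO strings (per record)
info_value <- function(info, key) {
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0("^(.*;)?", key, "=([^;]*).*$"), "\\2", info[hit])
  out
}

#' Read missense variants from a VCF file
#'
#' Parses a VCF v4.x file, splits multi-allelic records into one variant per
#' alternate allele, and keeps the records whose configurable consequence
#' INFO key marks them as missense. Amino-acid change and gene symbol are
#' populated when the corresponding INFO keys are present. Transcript
#' collapsing is not attempted: when a consequence key carries several
#' comma-separated terms, the record is kept if any term (aligned to its
#' allele for multi-allelic records) is the missense value.
#'
#' @param path VCF file (plain or gzipped).
#' @param consequence_key INFO key carrying the consequence term
#'   (default `"MC"`).
#' @param missense_value consequence term identifying missense records.
#' @param aa_key INFO key carrying the amino-acid change as `REF/ALT`
#'   single letters (default `"AA"`), optional.
#' @param gene_key INFO key carrying the gene symbol, optional.
#' @param permissive if `TRUE`, records lacking the consequence key are kept
#'   (treated as missense); if `FALSE` (default) such records raise an error
#'   naming the key.
#' @param validate pre-scan variant lines for structural problems so errors
#'   carry a line number (cheap for fixture-scale files; disable for large
#'   inputs).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `ref_aa`,
#'   `alt_aa`, `gene` (amino acids/gene `NA` when unannotated).
#' @export
read_missense_vcf <- function(path, consequence_key = "MC",
                              missense_value = "missense_variant",
                              aa_key = "AA", gene_key = "GENE",
                              permissive = FALSE, validate = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such VCF file: %s", path), call. = FALSE)
  if (validate && !grepl("\\.gz$", path)) validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), ref_aa = character(),
                      alt_aa = character(), gene = character(),
                      stringsAsFactors = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(as.matrix(fix)) == 0) return(empty)
  fix <- as.data.frame(rbind(fix), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- fix$INFO[i] %||% ""
    if (is.na(info)) info <- ""
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    csq <- info_value(info, consequence_key)
    if (is.na(csq)) {
      if (!permissive)
        stop(sprintf("record %s:%s lacks consequence INFO key '%s' (use permissive = TRUE to keep such records)",
                     fix$CHROM[i], fix$POS[i], consequence_key), call. = FALSE)
      csq_terms <- rep(missense_value, length(alts))
    } else {
      csq_terms <- strsplit(csq, ",", fixed = TRUE)[[1]]
      if (length(csq_terms) == 1L) csq_terms <- rep(csq_terms, length(alts))
    }
    aa <- info_value(info, aa_key)
    aa_terms <- if (is.na(aa)) rep(NA_character_, length(alts)) else {
      t <- strsplit(aa, ",", fixed = TRUE)[[1]]
      if (length(t) == 1L) rep(t, length(alts)) else t
    }
    gene <- info_value(info, gene_key)
    for (a in seq_along(alts)) {
      if (!identical(csq_terms[min(a, length(csq_terms))], missense_value)) next
      ref_aa <- alt_aa <- NA_character_
      if (!is.na(aa_terms[min(a, length(aa_terms))])) {
        parts <- strsplit(aa_terms[min(a, length(aa_terms))], "/", fixed = TRUE)[[1]]
        if (length(parts) == 2L) { ref_aa <- parts[1]; alt_aa <- parts[2] }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        ref_aa = ref_aa, alt_aa = alt_aa,
        gene = if (is.na(gene)) NA_character_ else gene,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read selected INFO keys from a VCF into a per-variant table
#'
#' Generic reader for ClinVar-style / HGMD-style / population-database-style
#' INFO annotations (key names configurable). Multi-allelic records are
#' split; scalar INFO values are repeated across alternate alleles.
#'
#' @param path VCF file.
#' @param info_keys character vector of INFO keys to extract.
#' @param numeric_keys subset of `info_keys` to convert to numeric.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` plus one column per
#'   requested key (`NA` where absent).
#' @export
read_vcf_info_table <- function(path, info_keys, numeric_keys = character()) {
  if (!file.exists(path)) stop(sprintf("no such VCF file: %s", path), call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  base_cols <- c("chrom", "pos", "ref", "alt", info_keys)
  if (is.null(fix) || nrow(as.matrix(fix)) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), length(base_cols)), base_cols))
    out$pos <- integer()
    return(out)
  }
  fix <- as.data.frame(rbind(fix), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- fix$INFO[i]
    if (is.na(info)) info <- ""
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    vals <- vapply(info_keys, function(k) info_value(info, k), character(1))
    for (a in seq_along(alts)) {
      row <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
      per_alt <- vapply(seq_along(info_keys), function(j) {
        v <- vals[j]
        if (is.na(v)) return(NA_character_)
        parts <- strsplit(v, ",", fixed = TRUE)[[1]]
        if (length(parts) == length(alts)) parts[a] else v
      }, character(1))
      row[info_keys] <- as.list(per_alt)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  for (k in intersect(numeric_keys, names(out)))
    out[[k]] <- suppressWarnings(as.numeric(out[[k]]))
  rownames(out) <- NULL
  out
}

#' Join annotation tables and substitution features into a feature matrix
#'
#' For each manifest feature, values are looked up by `(chrom, pos, ref,
#' alt)` in the first annotation table carrying the feature's source column;
#' substitution (AAindex) features are computed from the variant's amino-acid
#' change via the supplied matrix set. Cells with no value are marked
#' uncovered; no rows are dropped here (see [filter_full_coverage()]).
#'
#' @param variants data.frame of variant keys as returned by
#'   [read_missense_vcf()].
#' @param tables list of annotation data.frames keyed by columns
#'   `CHROM`, `POS`, `REF`, `ALT` (case-insensitive) plus feature columns.
#' @param manifest a `feature_manifest`.
#' @param aaindex_set named list of `aaindex_matrix` objects resolving the
#'   manifest's matrix identifiers.
#' @param impute `"none"` (default; unannotated cells stay uncovered) or
#'   `"median"` (fill uncovered cells with the per-feature median of covered
#'   values; the returned object is flagged via its `imputed` attribute).
#' @return A `feature_matrix` with one row per input variant.
#' @export
join_features <- function(variants, tables, manifest, aaindex_set = list(),
                          impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (inherits(tables, "data.frame")) tables <- list(tables)
  tables <- lapply(tables, function(t) {
    names(t) <- sub("^(chrom|pos|ref|alt)$", "\\U\\1", names(t), perl = TRUE)
    need_cols(t, c("CHROM", "POS", "REF", "ALT"), "annotation table")
    t
  })
  n <- nrow(variants)
  p <- nrow(manifest)
  values <- matrix(NA_real_, n, p)
  coverage <- matrix(FALSE, n, p)
  vkeys <- variant_id(variants)
  tkeys <- lapply(tables, function(t)
    variant_id(data.frame(chrom = t$CHROM, pos = t$POS, ref = t$REF, alt = t$ALT)))
  unresolved <- character()
  for (j in seq_len(p)) {
    src <- manifest$source_column[j]
    if (src %in% names(aaindex_set)) {
      ok <- !is.na(variants$ref_aa) & !is.na(variants$alt_aa) &
        variants$ref_aa %in% amino_acids() & variants$alt_aa %in% amino_acids() &
        variants$ref_aa != variants$alt_aa
      if (any(ok)) {
        m <- aaindex_set[[src]]$values
        values[ok, j] <- m[cbind(variants$ref_aa[ok], variants$alt_aa[ok])]
        coverage[ok, j] <- TRUE
      }
      next
    }
    hit <- which(vapply(tables, function(t) src %in% names(t), logical(1)))
    if (!length(hit)) { unresolved <- c(unresolved, manifest$name[j]); next }
    t <- tables[[hit[1]]]
    idx <- match(vkeys, tkeys[[hit[1]]])
    v <- suppressWarnings(as.numeric(t[[src]][idx]))
    got <- !is.na(v)
    values[got, j] <- v[got]
    coverage[got, j] <- TRUE
  }
  if (length(unresolved))
    stop(sprintf("manifest feature(s) unresolvable in any annotation table or matrix set: %s",
                 paste(unresolved, collapse = ", ")), call. = FALSE)
  imputed_cells <- 0L
  if (impute == "median") {
    for (j in seq_len(p)) {
      miss <- !coverage[, j]
      if (!any(miss) || all(miss)) next
      values[miss, j] <- median(values[coverage[, j], j])
      coverage[miss, j] <- TRUE
      imputed_cells <- imputed_cells + sum(miss)
    }
  }
  fm <- feature_matrix(variants, manifest, values, coverage)
  attr(fm, "imputed") <- impute == "median"
  attr(fm, "imputed_cells") <- imputed_cells
  fm
}

#' Keep only fully annotated variants
#'
#' Retains exactly the rows whose coverage mask is all-`TRUE`, preserving
#' row order — the default missing-data policy for training-set
#' construction.
#'
#' @param matrix a `feature_matrix`.
#' @return A `feature_matrix` containing the fully covered rows.
#' @export
filter_full_coverage <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  keep <- if (nrow(matrix$values)) rowSums(!matrix$coverage) == 0 else logical(0)
  feature_matrix(matrix$variants[keep, , drop = FALSE], matrix$manifest,
                 matrix$values[keep, , drop = FALSE],
                 matrix$coverage[keep, , drop = FALSE])
}
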