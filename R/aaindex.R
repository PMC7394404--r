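# amino-acid substitution matrices (AAindex-style)

#' Construct an amino-acid substitution matrix
#'
#' @param id matrix identifier (AAindex-style accession).
#' @param values 20x20 numeric matrix with rows and columns named by the
#'   standard amino acids in the order of [amino_acids()]; all entries must
#'   be finite.
#' @return An `aaindex_matrix` object.
#' @export
aaindex_matrix <- function(id, values) {
  aa <- amino_acids()
  values <- as.matrix(values)
  if (!all(dim(values) == c(20L, 20L)))
    stop("substitution matrix must be 20x20", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- aa
  if (is.null(colnames(values))) colnames(values) <- aa
  if (!identical(sort(rownames(values)), aa) || !identical(sort(colnames(values)), aa))
    stop("substitution matrix must be indexed by the 20 standard amino acids",
         call. = FALSE)
  values <- values[aa, aa]
  if (!all(is.finite(values)))
    stop(sprintf("substitution matrix '%s' contains non-finite values", id),
         call. = FALSE)
  structure(list(id = as.character(id), values = values), class = "aaindex_matrix")
}

check_aa <- function(aa, arg) {
  if (length(aa) != 1L || !is.character(aa) || !(aa %in% amino_acids()))
    stop(sprintf("'%s' is not a standard amino-acid letter (%s = %s)",
                 as.character(aa)[1], arg, as.character(aa)[1]), call. = FALSE)
  aa
}

#' Look up a substitution value
#'
#' Pure lookup of the property change for the substitution `ref_aa` ->
#' `alt_aa` in a 20x20 matrix. Non-standard residues (e.g. selenocysteine)
#' are rejected rather than imputed, and identical residues are rejected
#' because the substitution is then not a missense change.
#'
#' @param matrix an `aaindex_matrix`.
#' @param ref_aa,alt_aa single-letter standard amino acids, `ref_aa != alt_aa`.
#' @return scalar numeric value.
#' @export
aaindex_substitution_value <- function(matrix, ref_aa, alt_aa) {
  stopifnot(inherits(matrix, "aaindex_matrix"))
  check_aa(ref_aa, "ref_aa")
  check_aa(alt_aa, "alt_aa")
  if (ref_aa == alt_aa)
    stop("ref_aa equals alt_aa: not a missense substitution", call. = FALSE)
  unname(matrix$values[ref_aa, alt_aa])
}

#' Read substitution matrices from an AAindex-format flat file
#'
#' Parses matrix blocks of the AAindex matrix format: an `H <accession>`
#' line, an `M rows = ..., cols = ...` line declaring the amino-acid order,
#' value rows (full square or lower triangle; lower-triangle blocks are
#' mirrored into full symmetric matrices), terminated by `//`. Lines with
#' other one-letter prefixes (D, R, A, T, J, *) are ignored as annotation.
#'
#' @param path flat file path.
#' @return named list of `aaindex_matrix` objects.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!startsWith(line, "H ")) { i <- i + 1L; next }
    id <- trimws(sub("^H ", "", line))
    # advance to the M line
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], "M ")) j <- j + 1L
    if (j > length(lines))
      stop(sprintf("matrix block '%s' has no M line", id), call. = FALSE)
    mline <- sub("^M ", "", lines[j])
    rows <- sub(".*rows\\s*=\\s*([A-Z]+).*", "\\1", mline)
    cols <- sub(".*cols\\s*=\\s*([A-Z]+).*", "\\1", mline)
    row_aa <- strsplit(rows, "")[[1]]
    col_aa <- strsplit(cols, "")[[1]]
    if (length(row_aa) != 20L || length(col_aa) != 20L)
      stop(sprintf("matrix block '%s' does not declare 20 amino acids", id),
           call. = FALSE)
    vals <- matrix(NA_real_, 20L, 20L, dimnames = list(row_aa, col_aa))
    k <- j + 1L
    r <- 1L
    while (k <= length(lines) && !startsWith(lines[k], "//")) {
      fields <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      if (length(fields)) {
        num <- suppressWarnings(as.numeric(gsub("^NA$", "NA", fields)))
        if (r > 20L)
          stop(sprintf("matrix block '%s' has more than 20 value rows", id),
               call. = FALSE)
        if (!(length(num) %in% c(r, 20L)))
          stop(sprintf("matrix block '%s', value row %d: expected %d or 20 values, got %d",
                       id, r, r, length(num)), call. = FALSE)
        vals[r, seq_along(num)] <- num
        r <- r + 1L
      }
      k <- k + 1L
    }
    if (r != 21L)
      stop(sprintf("matrix block '%s' has %d value rows, expected 20", id, r - 1L),
           call. = FALSE)
    # mirror a lower-triangle block into a full symmetric matrix
    upper <- upper.tri(vals)
    if (anyNA(vals[upper])) {
      tv <- t(vals)
      vals[upper] <- tv[upper]
    }
    out[[id]] <- aaindex_matrix(id, vals)
    i <- k + 1L
  }
  if (!length(out)) stop("no matrix blocks found in AAindex file", call. = FALSE)
  out
}

#' Write substitution matrices in AAindex flat-file format
#'
#' @param set named list of `aaindex_matrix` objects.
#' @param path output path.
#' @param lower_triangle write the lower triangle only (valid for symmetric
#'   matrices, the common AAindex convention).
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(set, path, lower_triangle = FALSE) {
  aa <- paste(amino_acids(), collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in set) {
    writeLines(sprintf("H %s", m$id), con)
    writeLines(sprintf("M rows = %s, cols = %s", aa, aa), con)
    for (r in 1:20) {
      n <- if (lower_triangle) r else 20L
      writeLines(paste(formatC(m$values[r, seq_len(n)], format = "g", digits = 7),
                       collapse = " "), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Generate a synthetic set of substitution matrices
#'
#' Produces symmetric 20x20 matrices with standard-normal entries, a
#' deterministic function of `(ids, seed)`. These stand in for the (not
#' redistributable) AAindex property matrices in tests and simulations and
#' are labelled synthetic by their identifiers.
#'
#' @param ids matrix identifiers (default the packaged 90 slots).
#' @param seed integer seed.
#' @return named list of `aaindex_matrix` objects.
#' @export
synthetic_aaindex_set <- function(ids = default_aaindex_ids(), seed = 1L) {
  with_seed(seed, {
    out <- lapply(ids, function(id) {
      v <- matrix(rnorm(400), 20, 20)
      v[lower.tri(v)] <- t(v)[lower.tri(v)]
      aaindex_matrix(id, v)
    })
    names(out) <- ids
    out
  })
}
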