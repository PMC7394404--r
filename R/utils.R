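# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Canonical variant identifier
#'
#' Builds `chrom:pos:ref:alt` keys with any `chr` prefix stripped, so that
#' b37-style and hg19-style files compare equal.
#'
#' @param x data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variant_id <- function(x) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  chrom <- sub("^chr", "", as.character(x$chrom), ignore.case = TRUE)
  paste(chrom, x$pos, x$ref, x$alt, sep = ":")
}

# required-column check with a uniform error message
need_cols <- function(x, cols, what = "input") {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
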