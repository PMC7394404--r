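#' @importFrom stats median predict quantile rbeta rbinom rnorm runif sd setNames wilcox.test plogis
#' @importFrom utils read.table write.table combn head tail
NULL

#' Standard amino acids in canonical order
#'
#' Fixed alphabetical single-letter ordering used for serializing 20x20
#' substitution matrices.
#' @return character vector of the 20 standard one-letter codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

FEATURE_CATEGORIES <- c("MAF", "conservation", "functional", "predictor")
MAF_POPULATIONS <- c("global", "AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS")

#' Construct a feature manifest
#'
#' A manifest is an ordered table of feature definitions; its row order
#' defines the column order of every feature matrix built from it.
#'
#' @param name unique feature identifiers.
#' @param category one of `"MAF"`, `"conservation"`, `"functional"`,
#'   `"predictor"` per feature.
#' @param population population code for MAF features (empty otherwise).
#' @param source_column column name in annotation tables, or an AAindex
#'   matrix identifier for substitution-derived features.
#' @param version free-text manifest tag.
#' @return A `feature_manifest` data.frame.
#' @export
feature_manifest <- function(name, category, population = "", source_column = name,
                             version = "custom") {
  m <- data.frame(name = as.character(name),
                  category = as.character(category),
                  population = rep_len(as.character(population), length(name)),
                  source_column = rep_len(as.character(source_column), length(name)),
                  stringsAsFactors = FALSE)
  attr(m, "version") <- version
  class(m) <- c("feature_manifest", "data.frame")
  m
}

#' Default identifiers for the AAindex substitution-matrix slots
#'
#' The production model uses 90 amino-acid substitution matrices drawn from
#' the AAindex collection; their values are user-supplied (or synthetic, see
#' [synthetic_aaindex_set()]), so the default manifest ships 90 configurable
#' placeholder slots with AAindex-style accessions.
#'
#' @param n number of identifiers (default 90).
#' @return character vector of matrix identifiers.
#' @export
default_aaindex_ids <- function(n = 90) sprintf("SYNM%03d001", seq_len(n))

#' The default 113-feature manifest
#'
#' Builds the packaged feature panel: 6 minor-allele-frequency features
#' (global plus AFR, AMR, EAS, NFE, SAS populations; ASJ and FIN are
#' excluded by feature selection), 8 conservation features (PhastCons and
#' PhyloP over primate/mammal/vertebrate alignments, SiPhy, GERP++), 92
#' functional features (constrained-coding-region score, regional missense
#' constraint score, and 90 amino-acid substitution matrices), and 7
#' component predictor scores (SIFT, PolyPhen-2, VEST4, Condel, CADD PHRED,
#' MetaLR, MetaSVM) consumed as annotation columns.
#'
#' @param aaindex_ids identifiers of the 90 substitution matrices.
#' @return A `feature_manifest` with 113 rows.
#' @export
default_manifest <- function(aaindex_ids = default_aaindex_ids()) {
  maf_pops <- c("global", "AFR", "AMR", "EAS", "NFE", "SAS")
  maf <- feature_manifest(name = paste0("maf_", tolower(maf_pops)),
                          category = "MAF", population = maf_pops)
  cons_names <- c("phastcons_primates", "phastcons_mammals", "phastcons_vertebrates",
                  "phylop_primates", "phylop_mammals", "phylop_vertebrates",
                  "siphy_29way_logodds", "gerp_rs")
  cons <- feature_manifest(cons_names, "conservation")
  func <- feature_manifest(name = c("ccrs", "mpc", paste0("aaindex_", aaindex_ids)),
                           category = "functional",
                           source_column = c("ccrs", "mpc", aaindex_ids))
  pred <- feature_manifest(c("sift", "polyphen2", "vest4", "condel",
                             "cadd_phred", "metalr", "metasvm"),
                           "predictor")
  m <- rbind(maf, cons, func, pred)
  attr(m, "version") <- "default-113"
  class(m) <- c("feature_manifest", "data.frame")
  rownames(m) <- NULL
  m
}

#' Validate a feature manifest
#'
#' Structural checks only; problems are returned as records, never raised.
#'
#' @param manifest a `feature_manifest`.
#' @return data.frame with columns `type`, `feature`, `message`; zero rows
#'   when the manifest is valid.
#' @export
validate_manifest <- function(manifest) {
  v <- data.frame(type = character(), feature = character(),
                  message = character(), stringsAsFactors = FALSE)
  add <- function(type, feature, message)
    rbind(v, data.frame(type = type, feature = feature, message = message,
                        stringsAsFactors = FALSE))
  dup <- unique(manifest$name[duplicated(manifest$name)])
  for (d in dup)
    v <- add("duplicate name", d, sprintf("feature name '%s' appears more than once", d))
  bad <- !(manifest$category %in% FEATURE_CATEGORIES)
  for (i in which(bad))
    v <- add("unknown category", manifest$name[i],
             sprintf("category '%s' is not one of %s", manifest$category[i],
                     paste(FEATURE_CATEGORIES, collapse = "/")))
  pop_bad <- (manifest$category == "MAF" & manifest$population == "") |
    (manifest$category != "MAF" & manifest$population != "")
  for (i in which(pop_bad & !bad))
    v <- add("population rule", manifest$name[i],
             "population must be nonempty exactly for MAF features")
  maf_pop_bad <- manifest$category == "MAF" & manifest$population != "" &
    !(manifest$population %in% MAF_POPULATIONS)
  for (i in which(maf_pop_bad))
    v <- add("unknown population", manifest$name[i],
             sprintf("population '%s' is not a known code", manifest$population[i]))
  v
}

#' Serialize / read a manifest as a tab-separated table
#'
#' @param manifest a `feature_manifest`.
#' @param path file path.
#' @return `read_manifest` returns a `feature_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                  na.strings = character())
  feature_manifest(x$name, x$category, x$population, x$source_column,
                   version = basename(path))
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat(sprintf("Feature manifest '%s': %d features\n",
              attr(x, "version") %||% "unversioned", nrow(x)))
  print(table(factor(x$category, levels = FEATURE_CATEGORIES)))
  invisible(x)
}
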