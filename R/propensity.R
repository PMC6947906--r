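# Per-residue prion propensity lookup used by all window scoring.

.canonical_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.pkg_cache <- new.env(parent = emptyenv())

#' Construct a prion propensity table
#'
#' A propensity table maps each of the 20 canonical amino acids to a
#' dimensionless prion propensity. Window scores are arithmetic means of
#' these values, so the table fully determines the compositional part of
#' the aggregation propensity score.
#'
#' @param values Named numeric vector with exactly the 20 canonical
#'   one-letter residue codes as names; all values must be finite.
#' @param source_tag Free-text provenance string recorded with the table.
#' @return An object of class `propensity_table`: a named numeric vector
#'   (ordered A..Y) with a `source_tag` attribute.
#' @export
#' @examples
#' tab <- default_propensity_table()
#' tab["Q"]
propensity_table <- function(values, source_tag = "user-supplied") {
  if (is.null(names(values))) {
    stop("propensity values must be named by one-letter residue code")
  }
  nm <- toupper(names(values))
  missing <- setdiff(.canonical_aa, nm)
  extra <- setdiff(nm, .canonical_aa)
  if (length(missing) || length(extra)) {
    stop("propensity table must cover exactly the 20 canonical residues; ",
         if (length(missing)) paste0("missing: ", paste(missing, collapse = ","), "; "),
         if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ",")))
  }
  v <- as.numeric(values)[match(.canonical_aa, nm)]
  if (any(!is.finite(v))) stop("all propensity values must be finite")
  structure(stats::setNames(v, .canonical_aa),
            source_tag = as.character(source_tag)[1],
            class = "propensity_table")
}

#' Read a propensity table from a two-column TSV file
#'
#' @param path Path to a tab-separated file with columns `residue` and
#'   `propensity` (header required).
#' @param source_tag Provenance string; defaults to the file path.
#' @return A [propensity_table()].
#' @export
read_propensity_table <- function(path, source_tag = path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "propensity") %in% names(df))) {
    stop("propensity TSV must have columns 'residue' and 'propensity': ", path)
  }
  propensity_table(stats::setNames(df$propensity, df$residue), source_tag)
}

#' The packaged prion propensity table
#'
#' Per-residue prion propensities estimated from random mutagenesis of a
#' canonical Q/N-rich yeast prion domain, as distributed with the PAPA
#' scanner. Shipped in `inst/extdata/prion_propensity.tsv`.
#'
#' @return A [propensity_table()] (cached after first load).
#' @export
default_propensity_table <- function() {
  if (is.null(.pkg_cache$propensity)) {
    path <- system.file("extdata", "prion_propensity.tsv", package = "prionscan",
                        mustWork = TRUE)
    .pkg_cache$propensity <- read_propensity_table(
      path, source_tag = "PAPA distribution (Sup35 mutagenesis-derived)")
  }
  .pkg_cache$propensity
}

#' @export
print.propensity_table <- function(x, ...) {
  cat("Prion propensity table (", attr(x, "source_tag"), ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Checksum identifying a propensity table
#'
#' MD5 of the canonical `residue<TAB>propensity` rendering of the table,
#' printed in output manifests so that results can be traced to the exact
#' table in force.
#'
#' @param table A [propensity_table()].
#' @return Character MD5 digest.
#' @export
propensity_checksum <- function(table = default_propensity_table()) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(names(table), sprintf("%.9f", as.numeric(table)), sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}
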