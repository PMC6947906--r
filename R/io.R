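# Shared readers/writers: FASTA, strict TSV, output manifests.

#' Read protein sequences from FASTA
#'
#' Multi-record FASTA (wrapped or unwrapped). The accession is the first
#' whitespace-delimited token of the description line; an optional
#' `gene=<symbol>` token supplies the gene.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `accession`, `gene`, `sequence`,
#'   `length`. Duplicate accessions are an error.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  desc <- names(aa)
  accession <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(accession[duplicated(accession)]), collapse = ","))
  }
  gene <- rep(NA_character_, length(desc))
  hit <- regmatches(desc, regexpr("gene=[^\\s]+", desc, perl = TRUE))
  has <- grepl("gene=", desc, fixed = TRUE)
  gene[has] <- sub("^gene=", "", hit)
  seqs <- as.character(aa)
  data.frame(accession = accession, gene = gene, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records as FASTA
#'
#' @param proteins Data frame with `accession`, `sequence`, optional
#'   `gene` (emitted as a `gene=` token).
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(proteins))) {
    hdr <- proteins$accession[k]
    if ("gene" %in% names(proteins) && !is.na(proteins$gene[k])) {
      hdr <- paste0(hdr, " gene=", proteins$gene[k])
    }
    writeLines(paste0(">", hdr), con)
    s <- proteins$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a tab-separated table with a mandatory header
#'
#' Rejects ragged rows, reporting their line numbers. Lines beginning
#' with `#` (e.g. output manifests) are skipped; CRLF is tolerated.
#'
#' @param path Path to the TSV file.
#' @param required_columns Character vector of column names that must be
#'   present.
#' @return Data frame.
#' @export
read_tsv_strict <- function(path, required_columns = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep & nzchar(lines))
  lines <- lines[keep & nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  # trailing empty fields are preserved by counting separators instead
  nfield <- pmax(nfield, nchar(gsub("[^\t]", "", lines)) + 1L)
  if (any(nfield != nfield[1])) {
    bad <- lineno[which(nfield != nfield[1])]
    stop(sprintf("ragged row(s) in %s at line(s) %s (expected %d fields)",
                 path, paste(utils::head(bad, 5), collapse = ","), nfield[1]))
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required_columns)) {
    miss <- setdiff(required_columns, names(df))
    if (length(miss)) {
      stop("missing required column(s) in ", path, ": ",
           paste(miss, collapse = ","))
    }
  }
  df
}

#' Write a table as TSV with an optional run manifest header
#'
#' Numeric columns are rounded to 6 decimals; output is UTF-8, LF
#' line endings, '.' decimal separator, with a mandatory header row.
#' Manifest lines are written first as `# key: value` comments.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param manifest Named character/list of manifest entries, or `NULL`.
#' @export
write_tsv <- function(df, path, manifest = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(manifest)) {
    hdr <- paste0("# ", names(manifest), ": ", unlist(manifest))
    writeLines(hdr, con, sep = "\n")
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "")
  invisible(path)
}

#' Standard manifest entries for an output file
#'
#' @param subcommand Character label of the producing operation.
#' @param config A [scoring_config()].
#' @param table A [propensity_table()].
#' @param extra Named list of additional entries.
#' @return Named list of manifest entries.
#' @export
run_manifest <- function(subcommand, config = scoring_config(),
                         table = default_propensity_table(), extra = NULL) {
  m <- list(
    tool = paste0("prionscan ", as.character(utils::packageVersion("prionscan"))),
    subcommand = subcommand,
    window_size = config$window_size,
    relaxed_threshold = config$relaxed_threshold,
    classical_threshold = config$classical_threshold,
    sentinel = config$sentinel,
    gate_mode = config$gate_mode,
    propensity_md5 = propensity_checksum(table),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  c(m, extra)
}
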