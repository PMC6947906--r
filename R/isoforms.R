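# Isoform-level comparison: group isoforms by gene, compute deltas to
# the gene's maximum score, classify threshold-crossing patterns.

#' Group protein records by gene
#'
#' @param proteins Data frame with `accession` (unique) and `sequence`.
#' @param gene_map Data frame with columns `accession`, `gene`.
#' @return Named list (by gene) of data frames; unmapped accessions are
#'   collected in the `orphans` attribute (character vector) rather than
#'   any group.
#' @export
group_isoforms <- function(proteins, gene_map) {
  stopifnot(all(c("accession", "gene") %in% names(gene_map)))
  if (anyDuplicated(proteins$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]),
               collapse = ","))
  }
  gene <- gene_map$gene[match(proteins$accession, gene_map$accession)]
  orphans <- proteins$accession[is.na(gene)]
  mapped <- proteins[!is.na(gene), , drop = FALSE]
  mapped$gene <- gene[!is.na(gene)]
  groups <- split(mapped, mapped$gene)
  attr(groups, "orphans") <- orphans
  groups
}

#' Classify one isoform against its gene maximum
#'
#' Category rules (classical threshold `t`): `max_isoform` when the
#' isoform attains the gene maximum (ties share the category);
#' `high_with_higher` when the isoform exceeds `t` but a higher-scoring
#' isoform exists; `crossing` when the isoform is at or below `t` while
#' the gene maximum exceeds `t`; `below_both` otherwise.
#'
#' @param isoform_score,gene_max_score Numeric scalars.
#' @param classical_threshold Numeric (default 0.05).
#' @return Character category.
#' @export
classify_isoform <- function(isoform_score, gene_max_score,
                             classical_threshold = 0.05) {
  stopifnot(gene_max_score >= isoform_score)
  if (isoform_score == gene_max_score) return("max_isoform")
  if (isoform_score > classical_threshold) return("high_with_higher")
  if (gene_max_score > classical_threshold) return("crossing")
  "below_both"
}

#' Compare isoforms within one gene group
#'
#' Scores each isoform, computes the gene maximum and per-isoform delta
#' to it, and assigns categories via [classify_isoform()].
#'
#' @param group Data frame with `accession`, `sequence` and `gene`
#'   (one gene).
#' @param table,config As for [position_scores()].
#' @param affected_only If `TRUE`, drop isoforms whose score equals the
#'   gene maximum (only isoforms for which splicing changed the score).
#' @return Data frame: `gene`, `accession`, `isoform_score`,
#'   `gene_max_score`, `delta_to_max`, `category`.
#' @export
compare_isoforms <- function(group, table = default_propensity_table(),
                             config = scoring_config(), affected_only = FALSE) {
  stopifnot(nrow(group) >= 1)
  scores <- vapply(seq_len(nrow(group)), function(k) {
    protein_score(group$sequence[k], table = table, config = config,
                  accession = group$accession[k])
  }, numeric(1))
  gmax <- max(scores)
  out <- data.frame(
    gene = group$gene,
    accession = group$accession,
    isoform_score = scores,
    gene_max_score = gmax,
    delta_to_max = gmax - scores,
    category = vapply(scores, classify_isoform, character(1),
                      gene_max_score = gmax,
                      classical_threshold = config$classical_threshold),
    stringsAsFactors = FALSE)
  if (affected_only) out <- out[out$delta_to_max > 0, , drop = FALSE]
  out
}

#' Isoform comparison across a proteome
#'
#' @param proteins Data frame with `accession`, `sequence`.
#' @param gene_map Data frame with `accession`, `gene`.
#' @param table,config,affected_only As for [compare_isoforms()].
#' @param crossing_only If `TRUE`, keep only genes with at least one
#'   isoform at or below the classical threshold and at least one above
#'   it (the threshold-crossing report); genes entirely at or below the
#'   threshold are retained in the full output otherwise.
#' @return Data frame of per-isoform rows; orphan accessions (no gene
#'   mapping) are reported in the `orphans` attribute.
#' @export
isoform_analysis <- function(proteins, gene_map,
                             table = default_propensity_table(),
                             config = scoring_config(),
                             affected_only = FALSE, crossing_only = FALSE) {
  groups <- group_isoforms(proteins, gene_map)
  res <- lapply(groups, compare_isoforms, table = table, config = config,
                affected_only = affected_only)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (crossing_only && nrow(out)) {
    t0 <- config$classical_threshold
    keep_gene <- vapply(split(out, out$gene), function(g) {
      any(g$isoform_score <= t0) && any(g$gene_max_score > t0)
    }, logical(1))
    out <- out[out$gene %in% names(keep_gene)[keep_gene], , drop = FALSE]
  }
  attr(out, "orphans") <- attr(groups, "orphans")
  out
}
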