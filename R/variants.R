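# Variant-combination analysis: enumerate single and pairwise variant
# combinations within PrLDs and summarise the score distribution.

.validate_variants <- function(sequence, variants, accession = "protein") {
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)))
  n <- nchar(sequence)
  if (any(variants$position < 1 | variants$position > n)) {
    bad <- variants$position[variants$position < 1 | variants$position > n]
    stop(sprintf("variant position(s) out of range for %s (length %d): %s",
                 accession, n, paste(bad, collapse = ",")))
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt residues must differ (", accession, ")")
  }
  actual <- substring(sequence, variants$position, variants$position)
  ok <- actual == variants$ref
  if (!all(ok)) {
    stop(sprintf("reference residue mismatch for %s at position(s) %s (sequence has %s)",
                 accession,
                 paste(variants$position[!ok], collapse = ","),
                 paste(actual[!ok], collapse = ",")))
  }
  invisible(TRUE)
}

#' Apply single amino acid substitutions to a sequence
#'
#' @param sequence Protein sequence (character scalar).
#' @param variants Data frame with columns `position`, `ref`, `alt`
#'   (1-based). At most one variant per position; every `ref` must match
#'   the sequence, else the call is rejected with the offending
#'   positions named. The empty set returns the sequence unchanged.
#' @param accession Identifier used in error messages.
#' @return The substituted sequence (same length).
#' @export
#' @examples
#' apply_variants("AAAAAAA", data.frame(position = 5, ref = "A", alt = "V"))
apply_variants <- function(sequence, variants, accession = "protein") {
  if (is.null(variants) || nrow(variants) == 0) return(sequence)
  if (anyDuplicated(variants$position)) {
    stop("multiple variants at one position for ", accession, ": ",
         paste(unique(variants$position[duplicated(variants$position)]),
               collapse = ","))
  }
  .validate_variants(sequence, variants, accession)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[variants$position] <- variants$alt
  paste(chars, collapse = "")
}

#' Enumerate variant combinations up to pairs
#'
#' Yields the reference (empty set), every singleton, and every
#' unordered pair of variants at distinct positions; pairs sharing a
#' position are never yielded. With `k` variants at distinct positions
#' this is `1 + k + choose(k, 2)` sets.
#'
#' @param variants Data frame of variants (one row each) with a
#'   `position` column.
#' @param pairs_only If `TRUE`, omit the reference and singleton sets.
#' @param max_sets Optional cap; exceeding it is an error (guards
#'   pathological variant counts).
#' @return List of integer vectors indexing rows of `variants`; the
#'   empty integer vector denotes the reference sequence.
#' @export
#' @examples
#' length(enumerate_combinations(data.frame(position = c(2, 5, 9))))  # 7
enumerate_combinations <- function(variants, pairs_only = FALSE,
                                   max_sets = Inf) {
  k <- if (is.null(variants)) 0L else nrow(variants)
  sets <- list()
  if (!pairs_only) {
    sets <- c(list(integer(0)), lapply(seq_len(k), identity))
  }
  if (k >= 2) {
    pairs <- utils::combn(k, 2, simplify = FALSE)
    ok <- vapply(pairs, function(p) {
      variants$position[p[1]] != variants$position[p[2]]
    }, logical(1))
    sets <- c(sets, pairs[ok])
  }
  if (length(sets) > max_sets) {
    stop("combination count ", length(sets), " exceeds max_sets = ", max_sets)
  }
  sets
}

#' Summarise aggregation propensity over enumerated variant combinations
#'
#' Filters the supplied variants to those lying inside PrLDs called at
#' the relaxed threshold on the *reference* sequence (domain boundaries
#' are fixed by the reference; only scores are recomputed per variant),
#' enumerates combinations up to pairs, scores every resulting sequence,
#' and reports the minimum, maximum, range and unique-score count.
#' Summaries whose minimum equals the sentinel (a variant combination
#' abolishing all predicted disorder) are flagged for exclusion from
#' aggregate outputs.
#'
#' @param sequence Reference protein sequence.
#' @param variants Data frame with `position`, `ref`, `alt`. Rows whose
#'   `ref` mismatches the sequence are skipped with a warning (public
#'   variant tables mix isoform coordinate frames).
#' @param accession Identifier.
#' @param table,config As for [position_scores()].
#' @param pairs_only,max_sets Passed to [enumerate_combinations()].
#' @return One-row data frame: `accession`, `reference_score`,
#'   `min_score`, `max_score`, `score_range`, `n_unique_scores`,
#'   `n_sequences_scored`, `n_variants_in_prld`, `excluded` (logical).
#' @export
summarize_variant_scores <- function(sequence, variants, accession = "protein",
                                     table = default_propensity_table(),
                                     config = scoring_config(),
                                     pairs_only = FALSE, max_sets = Inf) {
  ref_prof <- position_scores(sequence, table = table, config = config,
                              accession = accession)
  ref_score <- ref_prof$protein_score
  doms <- find_prlds(ref_prof, threshold = config$relaxed_threshold)

  if (is.null(variants) || nrow(variants) == 0) {
    variants <- data.frame(position = integer(0), ref = character(0),
                           alt = character(0), stringsAsFactors = FALSE)
  }
  mismatch <- logical(nrow(variants))
  if (nrow(variants) > 0) {
    actual <- substring(sequence, variants$position, variants$position)
    mismatch <- actual != variants$ref
  }
  if (any(mismatch)) {
    warning(sprintf("%s: skipped %d variant(s) with reference mismatch at position(s) %s",
                    accession, sum(mismatch),
                    paste(variants$position[mismatch], collapse = ",")),
            call. = FALSE)
    variants <- variants[!mismatch, , drop = FALSE]
  }
  in_prld <- rep(FALSE, nrow(variants))
  if (nrow(doms) && nrow(variants)) {
    for (d in seq_len(nrow(doms))) {
      in_prld <- in_prld | (variants$position >= doms$start[d] &
                            variants$position <= doms$end[d])
    }
  }
  vs <- variants[in_prld, , drop = FALSE]
  sets <- enumerate_combinations(vs, pairs_only = pairs_only, max_sets = max_sets)
  scores <- vapply(sets, function(ix) {
    s <- apply_variants(sequence, vs[ix, , drop = FALSE], accession)
    protein_score(s, table = table, config = config, accession = accession)
  }, numeric(1))
  if (!length(scores)) scores <- ref_score
  data.frame(accession = accession,
             reference_score = ref_score,
             min_score = min(scores),
             max_score = max(scores),
             score_range = max(scores) - min(scores),
             n_unique_scores = length(unique(scores)),
             n_sequences_scored = length(scores),
             n_variants_in_prld = nrow(vs),
             excluded = min(scores) == config$sentinel,
             stringsAsFactors = FALSE)
}

#' Variant score-range analysis over a proteome
#'
#' Runs [summarize_variant_scores()] for every protein whose baseline
#' score strictly exceeds the relaxed threshold (moderately high-scoring
#' PrLD candidates); lower-scoring proteins are not summarised.
#'
#' @param proteins Data frame with `accession`, `sequence`.
#' @param variant_table Data frame with `accession`, `position`, `ref`,
#'   `alt`.
#' @param table,config,pairs_only,max_sets As above.
#' @return Data frame of per-protein summaries (possibly zero rows).
#' @export
variant_analysis <- function(proteins, variant_table,
                             table = default_propensity_table(),
                             config = scoring_config(),
                             pairs_only = FALSE, max_sets = Inf) {
  stopifnot(all(c("accession", "position", "ref", "alt") %in% names(variant_table)))
  out <- list()
  for (k in seq_len(nrow(proteins))) {
    acc <- proteins$accession[k]
    base <- protein_score(proteins$sequence[k], table = table, config = config,
                          accession = acc, strict = FALSE)
    if (is.na(base) || base <= config$relaxed_threshold) next
    vs <- variant_table[variant_table$accession == acc, , drop = FALSE]
    out[[length(out) + 1L]] <- summarize_variant_scores(
      proteins$sequence[k], vs, accession = acc, table = table,
      config = config, pairs_only = pairs_only, max_sets = max_sets)
  }
  if (!length(out)) {
    return(data.frame(accession = character(0), reference_score = numeric(0),
                      min_score = numeric(0), max_score = numeric(0),
                      score_range = numeric(0), n_unique_scores = integer(0),
                      n_sequences_scored = integer(0),
                      n_variants_in_prld = integer(0), excluded = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
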