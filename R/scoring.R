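# Core scanner: windowed propensity, FoldIndex gating, per-position
# profiles, whole-protein score, merged PrLD boundary calling.

.encode_residues <- function(sequence, strict = TRUE, accession = "protein") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, .canonical_aa)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    msg <- sprintf("non-canonical residue(s) in %s at position(s) %s: %s",
                   accession,
                   paste(utils::head(bad, 5), collapse = ","),
                   paste(unique(chars[bad]), collapse = ","))
    if (strict) stop(msg, call. = FALSE) else return(structure(NA, msg = msg))
  }
  idx
}

#' Mean prion propensity of one window
#'
#' The score of a window is the arithmetic mean of per-residue prion
#' propensities; it depends on composition only, not residue order.
#'
#' @param window_sequence Non-empty residue string (canonical residues).
#' @param table A [propensity_table()].
#' @return Mean propensity (numeric scalar).
#' @export
#' @examples
#' window_propensity(strrep("Q", 41))
window_propensity <- function(window_sequence, table = default_propensity_table()) {
  if (!nzchar(window_sequence)) stop("window must be non-empty")
  idx <- .encode_residues(window_sequence, strict = TRUE, accession = "window")
  mean(as.numeric(table)[idx])
}

#' FoldIndex of one window
#'
#' FoldIndex is `slope * <H> - |<R>| + intercept`, where `<H>` is the mean
#' Kyte-Doolittle hydropathy rescaled to 0-1 and `<R>` the mean net
#' charge. Negative values predict intrinsic disorder.
#'
#' @param window_sequence Non-empty residue string.
#' @param config A [scoring_config()] holding the FoldIndex constants.
#' @return FoldIndex value (numeric scalar).
#' @export
#' @examples
#' window_foldindex(strrep("K", 41))  # strongly disordered
window_foldindex <- function(window_sequence, config = scoring_config()) {
  if (!nzchar(window_sequence)) stop("window must be non-empty")
  idx <- .encode_residues(window_sequence, strict = TRUE, accession = "window")
  h <- mean(config$hydrophobicity_scaled[idx])
  q <- mean(config$charge[idx])
  config$fold_slope * h - abs(q) + config$fold_intercept
}

#' Per-position aggregation propensity profile
#'
#' Scans one protein. The raw score of the window run starting at residue
#' `i` is the mean of the window propensities of up to `window_size`
#' consecutive windows (runs near the C-terminus average over however
#' many windows exist, at least one); the run score is anchored at the
#' last residue of its first window (`i + window_size - 1`). A position
#' is *gated* (reported as scored) only when the FoldIndex over the
#' governing span is negative.
#'
#' @param sequence Protein sequence (character scalar).
#' @param table A [propensity_table()].
#' @param config A [scoring_config()].
#' @param accession Identifier carried into the profile.
#' @param strict If `TRUE` (default) non-canonical residues are an error
#'   naming the offending positions; if `FALSE` the function warns and
#'   returns `NULL` (the protein is skipped).
#' @return Object of class `papa_profile`: a list with `accession`,
#'   `sequence`, `length`, `protein_score` and a data frame `profile`
#'   with columns `position` (1-based anchored position), `score`,
#'   `foldindex`, `gated`, `span_start`, `span_end`. Proteins shorter
#'   than `window_size` yield an empty profile and the sentinel score.
#' @export
#' @examples
#' p <- position_scores(strrep("Q", 60))
#' p$protein_score
position_scores <- function(sequence,
                            table = default_propensity_table(),
                            config = scoring_config(),
                            accession = "protein",
                            strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  idx <- .encode_residues(sequence, strict = strict, accession = accession)
  if (length(idx) == 1L && is.na(idx[1]) && !is.null(attr(idx, "msg"))) {
    warning(attr(idx, "msg"), call. = FALSE)
    return(NULL)
  }
  n <- length(idx)
  W <- config$window_size
  S <- config$effective_span
  empty <- data.frame(position = integer(0), score = numeric(0),
                      foldindex = numeric(0), gated = logical(0),
                      span_start = integer(0), span_end = integer(0))
  if (n < W) {
    return(structure(list(accession = accession, sequence = toupper(sequence),
                          length = n, profile = empty,
                          protein_score = config$sentinel, config = config),
                     class = "papa_profile"))
  }
  pv <- as.numeric(table)[idx]
  nw <- n - W + 1L
  cs <- c(0, cumsum(pv))
  wp <- (cs[(W + 1L):(n + 1L)] - cs[1:nw]) / W          # window propensities
  cw <- c(0, cumsum(wp))
  i <- seq_len(nw)                                       # run starts
  last <- pmin(i + W - 1L, nw)                           # last governing window
  run_score <- (cw[last + 1L] - cw[i]) / (last - i + 1L)
  span_end <- pmin(i + S - 1L, n)
  if (config$gate_mode == "span") {
    g_end <- span_end
  } else {
    g_end <- i + W - 1L
  }
  hs <- c(0, cumsum(config$hydrophobicity_scaled[idx]))
  qs <- c(0, cumsum(config$charge[idx]))
  g_len <- g_end - i + 1L
  fi <- config$fold_slope * (hs[g_end + 1L] - hs[i]) / g_len -
    abs((qs[g_end + 1L] - qs[i]) / g_len) + config$fold_intercept
  gated <- fi < 0
  prof <- data.frame(position = i + W - 1L, score = run_score,
                     foldindex = fi, gated = gated,
                     span_start = i, span_end = span_end)
  score <- if (any(gated)) max(run_score[gated]) else config$sentinel
  structure(list(accession = accession, sequence = toupper(sequence),
                 length = n, profile = prof, protein_score = score,
                 config = config),
            class = "papa_profile")
}

#' @export
print.papa_profile <- function(x, ...) {
  cat(sprintf("<papa_profile> %s (%d aa)\n", x$accession, x$length))
  cat(sprintf("  protein score: %.6f%s\n", x$protein_score,
              if (x$protein_score == x$config$sentinel) " (sentinel: no predicted disorder)" else ""))
  cat(sprintf("  %d anchored positions, %d gated (FoldIndex < 0)\n",
              nrow(x$profile), sum(x$profile$gated)))
  invisible(x)
}

#' Plot a per-protein aggregation propensity profile
#'
#' Draws the anchored position scores along the sequence: gated
#' (disordered, scored) stretches as thick coloured segments, ungated
#' stretches as thin grey segments, the classical threshold as a dashed
#' line, and optional PTM site positions as vertical marks.
#'
#' @param x A `papa_profile`.
#' @param ptm_positions Optional integer vector of PTM site positions.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.papa_profile <- function(x, ptm_positions = NULL, ...) {
  p <- x$profile
  if (!nrow(p)) {
    graphics::plot(NA, xlim = c(1, max(2, x$length)), ylim = c(-1, 1),
                   xlab = "position", ylab = "aggregation propensity",
                   main = x$accession, ...)
    return(invisible(x))
  }
  graphics::plot(p$position, p$score, type = "n",
                 xlab = "position", ylab = "aggregation propensity",
                 main = x$accession, ...)
  graphics::abline(h = x$config$classical_threshold, lty = 2, col = "grey50")
  r <- rle(p$gated)
  stops <- cumsum(r$lengths); starts <- c(1, utils::head(stops, -1) + 1)
  for (k in seq_along(r$values)) {
    sel <- starts[k]:stops[k]
    graphics::lines(p$position[sel], p$score[sel],
                    lwd = if (r$values[k]) 3 else 1,
                    col = if (r$values[k]) "steelblue" else "grey70")
  }
  if (!is.null(ptm_positions)) {
    graphics::abline(v = ptm_positions, col = "red", lwd = 0.5)
  }
  invisible(x)
}

#' Whole-protein aggregation propensity score
#'
#' The maximum gated position score, or the sentinel (default -1.0) when
#' no position passes the disorder gate.
#'
#' @param x A sequence string or a `papa_profile`.
#' @param table,config,accession,strict As for [position_scores()]
#'   (ignored when `x` is already a profile).
#' @return Numeric scalar.
#' @export
#' @examples
#' protein_score(strrep("I", 100))  # -1.0
protein_score <- function(x, table = default_propensity_table(),
                          config = scoring_config(),
                          accession = "protein", strict = TRUE) {
  if (inherits(x, "papa_profile")) return(x$protein_score)
  prof <- position_scores(x, table = table, config = config,
                          accession = accession, strict = strict)
  if (is.null(prof)) return(NA_real_)
  prof$protein_score
}

.merge_intervals <- function(start, end, peak) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]; peak <- peak[o]
  ms <- me <- integer(0); mp <- numeric(0)
  for (k in seq_along(start)) {
    if (length(ms) && start[k] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[k])
      mp[length(mp)] <- max(mp[length(mp)], peak[k])
    } else {
      ms <- c(ms, start[k]); me <- c(me, end[k]); mp <- c(mp, peak[k])
    }
  }
  data.frame(start = ms, end = me, peak_score = mp)
}

#' Call merged prion-like domains
#'
#' Candidate PrLDs are the window extents (governing spans) of all gated
#' positions whose score strictly exceeds `threshold`; overlapping
#' extents are merged into maximal intervals, yielding the predicted PrLD
#' boundaries. Multiple PrLDs per protein are returned as separate,
#' non-overlapping, sorted intervals.
#'
#' @param x A sequence string or a `papa_profile`.
#' @param threshold Score threshold (strict comparison); defaults to the
#'   config's relaxed threshold (0.0).
#' @param table,config,accession,strict As for [position_scores()].
#' @return Data frame with columns `accession`, `start`, `end`
#'   (1-based inclusive), `peak_score`, `domain_sequence`; zero rows when
#'   nothing exceeds the threshold.
#' @export
#' @examples
#' find_prlds(strrep("I", 100))  # empty
find_prlds <- function(x, threshold = NULL,
                       table = default_propensity_table(),
                       config = scoring_config(),
                       accession = "protein", strict = TRUE) {
  prof <- if (inherits(x, "papa_profile")) x else
    position_scores(x, table = table, config = config,
                    accession = accession, strict = strict)
  empty <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), peak_score = numeric(0),
                      domain_sequence = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(prof)) return(empty)
  cfg <- prof$config
  if (is.null(threshold)) threshold <- cfg$relaxed_threshold
  stopifnot(is.finite(threshold))
  p <- prof$profile
  sel <- p$gated & p$score > threshold
  if (!any(sel)) return(empty)
  m <- .merge_intervals(p$span_start[sel], p$span_end[sel], p$score[sel])
  data.frame(accession = prof$accession, start = as.integer(m$start),
             end = as.integer(m$end), peak_score = m$peak_score,
             domain_sequence = substring(prof$sequence, m$start, m$end),
             stringsAsFactors = FALSE)
}

#' Scan a set of proteins
#'
#' Batch interface over [position_scores()] and [find_prlds()]. In
#' lenient mode (default) proteins containing non-canonical residues
#' (U/B/Z/X/* etc.) are skipped with a warning, since the propensity
#' table is defined only on canonical residues.
#'
#' @param proteins Data frame with columns `accession`, `sequence` and
#'   optionally `gene` (as returned by [read_fasta()]).
#' @param table,config As for [position_scores()].
#' @param threshold PrLD-calling threshold (default: relaxed, 0.0).
#' @param strict If `TRUE` any non-canonical residue is an error.
#' @return A list with `scores` (accession, gene, protein_score,
#'   n_prlds), `prlds` (row-bound [find_prlds()] output) and `skipped`
#'   (accessions skipped under the lenient policy).
#' @export
scan_proteome <- function(proteins, table = default_propensity_table(),
                          config = scoring_config(), threshold = NULL,
                          strict = FALSE) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]), collapse = ","))
  }
  if (is.null(threshold)) threshold <- config$relaxed_threshold
  gene <- if ("gene" %in% names(proteins)) proteins$gene else
    rep(NA_character_, nrow(proteins))
  rows <- vector("list", nrow(proteins))
  doms <- vector("list", nrow(proteins))
  skipped <- character(0)
  for (k in seq_len(nrow(proteins))) {
    acc <- proteins$accession[k]
    prof <- position_scores(proteins$sequence[k], table = table, config = config,
                            accession = acc, strict = strict)
    if (is.null(prof)) { skipped <- c(skipped, acc); next }
    d <- find_prlds(prof, threshold = threshold)
    rows[[k]] <- data.frame(accession = acc, gene = gene[k],
                            protein_score = prof$protein_score,
                            n_prlds = nrow(d), stringsAsFactors = FALSE)
    doms[[k]] <- d
  }
  list(scores = do.call(rbind, rows),
       prlds = do.call(rbind, doms),
       skipped = skipped)
}
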