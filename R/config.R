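# Scoring configuration: window geometry, thresholds, FoldIndex constants.

# Kyte-Doolittle hydropathy, raw scale (-4.5 .. 4.5); FoldIndex rescales to 0-1.
.kyte_doolittle <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

.residue_charge <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)

#' Scanner configuration
#'
#' Bundles the window geometry, score thresholds, the sentinel score for
#' proteins without predicted disorder, and the FoldIndex constants.
#' Aggregation propensity is assigned per position from `window_size`
#' consecutive `window_size`-residue windows, i.e. an effective span of
#' `2 * window_size - 1` residues; a position receives a score only when
#' the FoldIndex over its governing span is negative (predicted
#' intrinsically disordered).
#'
#' @param window_size Sliding window length in residues; odd, >= 3.
#' @param relaxed_threshold Score above which candidate PrLDs are called
#'   for variant/PTM analyses (default 0.0).
#' @param classical_threshold Score above which a PrLD is considered
#'   aggregation-prone (default 0.05).
#' @param sentinel Score assigned to proteins lacking any predicted
#'   disordered region (default -1.0); must lie below any attainable
#'   windowed score.
#' @param gate_mode `"span"` (default) evaluates FoldIndex over the full
#'   union span of the governing windows (up to `2*window_size - 1`
#'   residues, truncated at termini); `"window"` gates on the single
#'   `window_size`-mer ending at the anchored position, for comparison.
#' @param fold_slope,fold_intercept FoldIndex linear coefficients
#'   (defaults 2.785 and -1.151).
#' @param hydrophobicity Named numeric, per-residue hydropathy on the raw
#'   Kyte-Doolittle scale; rescaled internally to 0-1 via `(x + 4.5) / 9`.
#' @param charge Named numeric/integer in \{-1, 0, +1\} per residue.
#' @return An object of class `scoring_config` (a list).
#' @export
#' @examples
#' cfg <- scoring_config()
#' cfg$effective_span  # 81
scoring_config <- function(window_size = 41L,
                           relaxed_threshold = 0.0,
                           classical_threshold = 0.05,
                           sentinel = -1.0,
                           gate_mode = c("span", "window"),
                           fold_slope = 2.785,
                           fold_intercept = -1.151,
                           hydrophobicity = .kyte_doolittle,
                           charge = .residue_charge) {
  gate_mode <- match.arg(gate_mode)
  window_size <- as.integer(window_size)
  if (window_size < 3L || window_size %% 2L == 0L) {
    stop("window_size must be odd and >= 3")
  }
  if (!(relaxed_threshold < classical_threshold)) {
    stop("relaxed_threshold must be strictly below classical_threshold")
  }
  hn <- toupper(names(hydrophobicity))
  if (!all(.canonical_aa %in% hn)) stop("hydrophobicity must cover all canonical residues")
  cn <- toupper(names(charge))
  if (!all(.canonical_aa %in% cn)) stop("charge must cover all canonical residues")
  hyd_scaled <- (as.numeric(hydrophobicity)[match(.canonical_aa, hn)] + 4.5) / 9
  chg <- as.numeric(charge)[match(.canonical_aa, cn)]
  if (!all(chg %in% c(-1, 0, 1))) stop("charges must be -1, 0 or +1")
  # sentinel must undercut any attainable window mean; window means are
  # bounded by the propensity extrema, which for the packaged table lie in
  # (-1.6, 0.9) -- enforced loosely here against the bound implied by use
  structure(list(
    window_size = window_size,
    effective_span = 2L * window_size - 1L,
    relaxed_threshold = relaxed_threshold,
    classical_threshold = classical_threshold,
    sentinel = sentinel,
    gate_mode = gate_mode,
    fold_slope = fold_slope,
    fold_intercept = fold_intercept,
    hydrophobicity_scaled = stats::setNames(hyd_scaled, .canonical_aa),
    charge = stats::setNames(chg, .canonical_aa)
  ), class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Scanner configuration\n")
  cat(sprintf("  window_size: %d (effective span %d)\n", x$window_size, x$effective_span))
  cat(sprintf("  thresholds: relaxed %g, classical %g; sentinel %g\n",
              x$relaxed_threshold, x$classical_threshold, x$sentinel))
  cat(sprintf("  FoldIndex: %g * <H> - |<R>| + %g, gate over %s\n",
              x$fold_slope, x$fold_intercept,
              if (x$gate_mode == "span") "full governing span" else "single window"))
  invisible(x)
}

#' Read key=value overrides for the scanner configuration
#'
#' Lines of the form `key=value` (`#` comments and blank lines ignored)
#' override [scoring_config()] defaults. Recognised keys: window_size,
#' relaxed_threshold, classical_threshold, sentinel, gate_mode,
#' fold_slope, fold_intercept.
#'
#' @param path Path to the config file.
#' @return A `scoring_config`.
#' @export
read_scoring_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  numeric_keys <- c("relaxed_threshold", "classical_threshold", "sentinel",
                    "fold_slope", "fold_intercept")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    args[[key]] <- switch(key,
      window_size = as.integer(val),
      gate_mode = val,
      if (key %in% numeric_keys) as.numeric(val) else
        stop("unknown config key: ", key))
  }
  do.call(scoring_config, args)
}
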