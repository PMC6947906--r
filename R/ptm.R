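# PTM enrichment/depletion within PrLDs, controlled for amino acid
# composition: only residues modifiable by the PTM type are counted.

#' Packaged PTM type to target-residue mapping
#'
#' Which residues each modification type can occur on (e.g. serine
#' phosphorylation targets S; arginine methylation targets R). Shipped
#' as `inst/extdata/ptm_residues.tsv` and user-overridable via
#' `read_tsv_strict()` plus this format: columns `ptm_type`, `residues`
#' (string of one-letter codes).
#'
#' @return Named character vector: ptm_type -> target residue string.
#' @export
default_ptm_targets <- function() {
  if (is.null(.pkg_cache$ptm_targets)) {
    path <- system.file("extdata", "ptm_residues.tsv", package = "prionscan",
                        mustWork = TRUE)
    df <- read_tsv_strict(path, required_columns = c("ptm_type", "residues"))
    .pkg_cache$ptm_targets <- stats::setNames(df$residues, df$ptm_type)
  }
  .pkg_cache$ptm_targets
}

.positions_in_intervals <- function(positions, starts, ends) {
  if (!length(starts)) return(rep(FALSE, length(positions)))
  out <- rep(FALSE, length(positions))
  for (d in seq_along(starts)) {
    out <- out | (positions >= starts[d] & positions <= ends[d])
  }
  out
}

#' Map PTM sites to PrLD intervals
#'
#' Labels every site as inside or outside a PrLD (1-based inclusive
#' interval membership) and tallies per-PrLD modification counts per
#' type. Sites beyond the protein length are rejected with a log entry.
#'
#' @param sites Data frame with `accession`, `position`, `residue`,
#'   `ptm_type`.
#' @param prlds Data frame of PrLDs (as from [find_prlds()], called at
#'   the relaxed threshold) with `accession`, `start`, `end`.
#' @param proteins Optional data frame with `accession`, `sequence` used
#'   to validate positions and residues.
#' @return List with `sites` (input plus logical `in_prld`),
#'   `per_prld_counts` (accession, start, end, ptm_type, n_sites) and
#'   `rejects`.
#' @export
map_ptms_to_prlds <- function(sites, prlds, proteins = NULL) {
  stopifnot(all(c("accession", "position", "ptm_type") %in% names(sites)))
  rejects <- sites[0, , drop = FALSE]
  if (!is.null(proteins)) {
    len <- nchar(proteins$sequence)[match(sites$accession, proteins$accession)]
    bad <- is.na(len) | sites$position < 1 | sites$position > len
    if (any(bad)) {
      rejects <- sites[bad, , drop = FALSE]
      rejects$reason <- ifelse(is.na(len[bad]), "unknown_accession",
                               "position_out_of_range")
      sites <- sites[!bad, , drop = FALSE]
    }
  }
  in_prld <- rep(FALSE, nrow(sites))
  counts <- list()
  for (acc in unique(sites$accession)) {
    si <- which(sites$accession == acc)
    d <- prlds[prlds$accession == acc, , drop = FALSE]
    in_prld[si] <- .positions_in_intervals(sites$position[si], d$start, d$end)
    if (nrow(d)) {
      for (r in seq_len(nrow(d))) {
        inside <- sites$position[si] >= d$start[r] & sites$position[si] <= d$end[r]
        if (any(inside)) {
          tab <- table(sites$ptm_type[si][inside])
          counts[[length(counts) + 1L]] <- data.frame(
            accession = acc, start = d$start[r], end = d$end[r],
            ptm_type = names(tab), n_sites = as.integer(tab),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sites$in_prld <- in_prld
  per_prld <- if (length(counts)) do.call(rbind, counts) else
    data.frame(accession = character(0), start = integer(0), end = integer(0),
               ptm_type = character(0), n_sites = integer(0),
               stringsAsFactors = FALSE)
  list(sites = sites, per_prld_counts = per_prld, rejects = rejects)
}

#' Build the 2x2 modifiable-residue contingency table for one PTM type
#'
#' Counts residues modifiable under the given type inside and outside
#' PrLDs, split by whether they carry empirical modification evidence.
#' Non-modified residues are modifiable residues with no site recorded;
#' a residue modified by another type still counts as unmodified here.
#'
#' @param sites Data frame of PTM sites (all types; filtered internally).
#' @param proteins Data frame with `accession`, `sequence`.
#' @param prlds PrLD data frame (relaxed-threshold calls).
#' @param ptm_type Type label to analyse.
#' @param targets Named target-residue mapping
#'   (default [default_ptm_targets()]).
#' @return List of class `ptm_contingency`: `ptm_type`, `mod_in_prld`,
#'   `unmod_in_prld`, `mod_outside`, `unmod_outside`,
#'   `n_sites_proteome`.
#' @export
build_contingency <- function(sites, proteins, prlds, ptm_type,
                              targets = default_ptm_targets()) {
  res_str <- targets[[ptm_type]]
  if (is.null(res_str)) stop("no target residues defined for PTM type: ", ptm_type)
  target_res <- strsplit(res_str, "", fixed = TRUE)[[1]]
  s <- sites[sites$ptm_type == ptm_type, , drop = FALSE]
  mod_in <- unmod_in <- mod_out <- unmod_out <- 0L
  for (k in seq_len(nrow(proteins))) {
    acc <- proteins$accession[k]
    chars <- strsplit(proteins$sequence[k], "", fixed = TRUE)[[1]]
    modifiable <- which(chars %in% target_res)
    if (!length(modifiable)) next
    d <- prlds[prlds$accession == acc, , drop = FALSE]
    inside <- .positions_in_intervals(modifiable, d$start, d$end)
    mpos <- unique(s$position[s$accession == acc])
    is_mod <- modifiable %in% mpos
    mod_in <- mod_in + sum(inside & is_mod)
    unmod_in <- unmod_in + sum(inside & !is_mod)
    mod_out <- mod_out + sum(!inside & is_mod)
    unmod_out <- unmod_out + sum(!inside & !is_mod)
  }
  structure(list(ptm_type = ptm_type,
                 mod_in_prld = mod_in, unmod_in_prld = unmod_in,
                 mod_outside = mod_out, unmod_outside = unmod_out,
                 n_sites_proteome = mod_in + mod_out),
            class = "ptm_contingency")
}

#' Enrichment statistics from a 2x2 contingency table
#'
#' The enrichment of a PTM type within PrLDs is `E = ln(OR)` with
#' `OR = (f_in / (1 - f_in)) / (f_out / (1 - f_out))`, where `f_in` and
#' `f_out` are the modified fractions of modifiable residues inside and
#' outside PrLDs. The p-value is a two-sided Fisher exact test on the
#' 2x2 table; the standard error of `ln(OR)` is the square root of the
#' summed reciprocal cell counts. A zero cell leaves OR/SE undefined and
#' flags the result (no continuity correction is applied by default;
#' `haldane = TRUE` adds 0.5 to every cell instead).
#'
#' @param counts A `ptm_contingency` (or list with the same fields).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables (default `FALSE`).
#' @return One-row data frame: `ptm_type`, cell counts,
#'   `f_mod_prld`, `f_mod_nonprld`, `odds_ratio`, `log_enrichment`,
#'   `se_log_enrichment`, `fisher_p`, `n_sites_proteome`,
#'   `zero_cell` (logical).
#' @export
#' @examples
#' ptm_enrichment(list(ptm_type = "x", mod_in_prld = 10, unmod_in_prld = 90,
#'                     mod_outside = 50, unmod_outside = 950,
#'                     n_sites_proteome = 60))
ptm_enrichment <- function(counts, haldane = FALSE) {
  a <- counts$mod_in_prld; b <- counts$unmod_in_prld
  c0 <- counts$mod_outside; d0 <- counts$unmod_outside
  stopifnot(a >= 0, b >= 0, c0 >= 0, d0 >= 0)
  n_in <- a + b; n_out <- c0 + d0
  if (n_in == 0 || n_out == 0) {
    return(data.frame(ptm_type = counts$ptm_type, mod_in_prld = a,
                      unmod_in_prld = b, mod_outside = c0, unmod_outside = d0,
                      f_mod_prld = NA_real_, f_mod_nonprld = NA_real_,
                      odds_ratio = NA_real_, log_enrichment = NA_real_,
                      se_log_enrichment = NA_real_, fisher_p = NA_real_,
                      n_sites_proteome = counts$n_sites_proteome,
                      zero_cell = TRUE, stringsAsFactors = FALSE))
  }
  zero <- any(c(a, b, c0, d0) == 0)
  aa <- a; bb <- b; cc <- c0; dd <- d0
  if (zero && haldane) { aa <- a + 0.5; bb <- b + 0.5; cc <- c0 + 0.5; dd <- d0 + 0.5 }
  f_in <- aa / (aa + bb); f_out <- cc / (cc + dd)
  or <- (f_in / (1 - f_in)) / (f_out / (1 - f_out))
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  if (zero && !haldane) { or <- NA_real_; se <- NA_real_ }
  p <- stats::fisher.test(matrix(c(a, b, c0, d0), nrow = 2, byrow = TRUE),
                          alternative = "two.sided")$p.value
  data.frame(ptm_type = counts$ptm_type, mod_in_prld = a, unmod_in_prld = b,
             mod_outside = c0, unmod_outside = d0,
             f_mod_prld = a / n_in, f_mod_nonprld = c0 / n_out,
             odds_ratio = or, log_enrichment = log(or),
             se_log_enrichment = se, fisher_p = p,
             n_sites_proteome = counts$n_sites_proteome,
             zero_cell = zero && !haldane, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment over PTM enrichment results
#'
#' Low-count-excluded types (`excluded_lowcount`) must be removed before
#' adjustment; the q-values are computed over the remaining tests only.
#'
#' @param results Data frame of [ptm_enrichment()] rows with no
#'   low-count exclusions.
#' @param fdr False discovery rate threshold for the significance flag
#'   (default 0.05).
#' @return `results` with `bh_q` and logical `significant` appended.
#' @export
bh_adjust <- function(results, fdr = 0.05) {
  if (!nrow(results)) {
    results$bh_q <- numeric(0); results$significant <- logical(0)
    return(results)
  }
  results$bh_q <- stats::p.adjust(results$fisher_p, method = "BH")
  results$significant <- !is.na(results$bh_q) & results$bh_q < fdr
  results
}

#' PTM enrichment/depletion analysis within PrLDs
#'
#' Full pipeline: call PrLDs at the relaxed threshold, build one
#' composition-controlled contingency table per PTM type present in the
#' site table, compute enrichment statistics, exclude types with fewer
#' than `min_sites` modification sites proteome-wide, and apply
#' Benjamini-Hochberg correction across the remaining types.
#'
#' @param proteins Data frame with `accession`, `sequence`.
#' @param sites PTM site data frame (`accession`, `position`, `residue`,
#'   `ptm_type`).
#' @param table,config As for [position_scores()].
#' @param targets Target-residue mapping.
#' @param min_sites Proteome-wide site-count filter (default 100).
#' @param fdr BH false discovery rate threshold (default 0.05).
#' @param prlds Optional precomputed PrLD table (skips the scan).
#' @return Data frame: one row per PTM type with contingency counts,
#'   fractions, odds ratio, log enrichment, SE, Fisher p, BH q,
#'   `excluded_lowcount` and `significant` (`NA` for excluded types).
#' @export
ptm_analysis <- function(proteins, sites,
                         table = default_propensity_table(),
                         config = scoring_config(),
                         targets = default_ptm_targets(),
                         min_sites = 100L, fdr = 0.05, prlds = NULL) {
  if (is.null(prlds)) {
    prlds <- scan_proteome(proteins, table = table, config = config,
                           threshold = config$relaxed_threshold)$prlds
  }
  types <- intersect(names(targets), unique(sites$ptm_type))
  res <- do.call(rbind, lapply(types, function(tp) {
    ptm_enrichment(build_contingency(sites, proteins, prlds, tp, targets))
  }))
  if (is.null(res)) return(res)
  res$excluded_lowcount <- res$n_sites_proteome < min_sites
  kept <- bh_adjust(res[!res$excluded_lowcount, , drop = FALSE], fdr = fdr)
  res$bh_q <- NA_real_; res$significant <- NA
  res$bh_q[!res$excluded_lowcount] <- kept$bh_q
  res$significant[!res$excluded_lowcount] <- kept$significant
  rownames(res) <- NULL
  res
}
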