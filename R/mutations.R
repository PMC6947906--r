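# Clinical missense variant analysis: parse p. notation, score
# wild-type vs mutant, classify aggregation-propensity effects.

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Parse a protein-change string in p. notation
#'
#' Accepts one-letter (`p.P275S`) and three-letter (`p.Gly12Asp`)
#' substitution notation, with or without the `p.` prefix or enclosing
#' parentheses. Records that are not single-residue missense
#' substitutions are returned as exclusions with a reason: `stop` (e.g.
#' `p.Arg100Ter`, `p.Q50*`), `frameshift` (`fs`), `indel`
#' (del/dup/ins/delins), `synonymous` (`p.Leu54=`), `noncanonical`
#' (e.g. selenocysteine), or `unparseable`. Never errors on bad input.
#'
#' @param text Character scalar.
#' @return List with `status` (`"ok"` or `"excluded"`), and either
#'   `position`, `ref`, `alt` (one-letter) or `reason`.
#' @export
#' @examples
#' parse_protein_change("p.P275S")
#' parse_protein_change("p.Arg100Ter")$reason  # "stop"
parse_protein_change <- function(text) {
  excl <- function(reason) list(status = "excluded", reason = reason)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    return(excl("unparseable"))
  }
  s <- trimws(text)
  s <- sub("^p\\.", "", s)
  s <- gsub("^\\(|\\)$", "", s)
  if (grepl("fs", s)) return(excl("frameshift"))
  if (grepl("del|dup|ins", s, ignore.case = TRUE)) return(excl("indel"))
  if (grepl("=$", s)) return(excl("synonymous"))
  # three-letter form
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|Ter|\\*)$", s))[[1]]
  if (length(m) == 4) {
    if (m[4] %in% c("Ter", "*")) return(excl("stop"))
    ref <- .aa3to1[m[2]]; alt <- .aa3to1[m[4]]
    if (is.na(ref) || is.na(alt)) return(excl("noncanonical"))
    return(list(status = "ok", position = as.integer(m[3]),
                ref = unname(ref), alt = unname(alt)))
  }
  # one-letter form
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1]]
  if (length(m) == 4) {
    if (m[4] %in% c("*", "X")) return(excl("stop"))
    if (!(m[2] %in% .canonical_aa) || !(m[4] %in% .canonical_aa)) {
      return(excl("noncanonical"))
    }
    return(list(status = "ok", position = as.integer(m[3]),
                ref = m[2], alt = m[4]))
  }
  excl("unparseable")
}

#' Classify the effect of a mutation on aggregation propensity
#'
#' A total function of the wild-type score, mutant score and classical
#' threshold `t`: `high_increasing` (wt > t and score increased),
#' `threshold_crossing` (wt < t < mutant), `decreasing` (score
#' decreased), `subthreshold_other` (everything else).
#'
#' @param wt_score,mut_score Numeric scalars.
#' @param classical_threshold Numeric (default 0.05).
#' @return Character category.
#' @export
classify_mutation_effect <- function(wt_score, mut_score,
                                     classical_threshold = 0.05) {
  t0 <- classical_threshold
  if (wt_score > t0 && mut_score > wt_score) return("high_increasing")
  if (wt_score < t0 && mut_score > t0) return("threshold_crossing")
  if (mut_score < wt_score) return("decreasing")
  "subthreshold_other"
}

#' Score a single mutation against its wild-type sequence
#'
#' @param sequence Wild-type protein sequence.
#' @param position,ref,alt Substitution (1-based; `ref` must match).
#' @param accession Identifier.
#' @param table,config As for [position_scores()].
#' @return One-row data frame: `accession`, `protein_change`,
#'   `wt_score`, `mut_score`, `delta` (mut - wt), `category`.
#' @export
score_mutation <- function(sequence, position, ref, alt,
                           accession = "protein",
                           table = default_propensity_table(),
                           config = scoring_config()) {
  v <- data.frame(position = position, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  mut_seq <- apply_variants(sequence, v, accession)  # validates ref match
  wt <- protein_score(sequence, table = table, config = config,
                      accession = accession)
  mt <- protein_score(mut_seq, table = table, config = config,
                      accession = accession)
  data.frame(accession = accession,
             protein_change = sprintf("p.%s%d%s", ref, position, alt),
             wt_score = wt, mut_score = mt, delta = mt - wt,
             category = classify_mutation_effect(
               wt, mt, config$classical_threshold),
             stringsAsFactors = FALSE)
}

#' Clinical variant effect analysis over a table of protein changes
#'
#' Parses each record's `protein_change`, resolves the coordinate frame
#' (an optional `isoform_accession` column selects the scored isoform;
#' otherwise `accession` is used), scores wild-type and mutant, and
#' classifies the effect. Non-missense records, unknown accessions,
#' out-of-range positions and reference mismatches are diverted to a
#' rejects table with reasons, never fatal.
#'
#' @param proteins Data frame with `accession`, `sequence`.
#' @param clinvar Data frame with `accession`, `protein_change`, and
#'   optionally `isoform_accession` and `phenotype`.
#' @param table,config As for [position_scores()].
#' @return List with `effects` (accession, protein_change, wt_score,
#'   mut_score, delta, category, phenotype) and `rejects` (accession,
#'   protein_change, reason).
#' @export
mutation_analysis <- function(proteins, clinvar,
                              table = default_propensity_table(),
                              config = scoring_config()) {
  stopifnot(all(c("accession", "protein_change") %in% names(clinvar)))
  phen <- if ("phenotype" %in% names(clinvar)) clinvar$phenotype else
    rep(NA_character_, nrow(clinvar))
  frame_acc <- if ("isoform_accession" %in% names(clinvar)) {
    ifelse(is.na(clinvar$isoform_accession) | !nzchar(clinvar$isoform_accession),
           clinvar$accession, clinvar$isoform_accession)
  } else clinvar$accession
  eff <- list(); rej <- list()
  reject <- function(k, reason) {
    rej[[length(rej) + 1L]] <<- data.frame(
      accession = clinvar$accession[k],
      protein_change = clinvar$protein_change[k],
      reason = reason, stringsAsFactors = FALSE)
  }
  # cache wild-type scores per frame accession
  wt_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(clinvar))) {
    p <- parse_protein_change(clinvar$protein_change[k])
    if (p$status != "ok") { reject(k, p$reason); next }
    row <- match(frame_acc[k], proteins$accession)
    if (is.na(row)) { reject(k, "unknown_accession"); next }
    seqk <- proteins$sequence[row]
    if (p$position > nchar(seqk)) { reject(k, "position_out_of_range"); next }
    if (substring(seqk, p$position, p$position) != p$ref) {
      reject(k, "ref_mismatch"); next
    }
    acc <- frame_acc[k]
    if (is.null(wt_cache[[acc]])) {
      wt_cache[[acc]] <- protein_score(seqk, table = table, config = config,
                                       accession = acc)
    }
    mt <- protein_score(apply_variants(
      seqk, data.frame(position = p$position, ref = p$ref, alt = p$alt),
      acc), table = table, config = config, accession = acc)
    wt <- wt_cache[[acc]]
    eff[[length(eff) + 1L]] <- data.frame(
      accession = clinvar$accession[k],
      protein_change = clinvar$protein_change[k],
      wt_score = wt, mut_score = mt, delta = mt - wt,
      category = classify_mutation_effect(wt, mt, config$classical_threshold),
      phenotype = phen[k], stringsAsFactors = FALSE)
  }
  empty_eff <- data.frame(accession = character(0), protein_change = character(0),
                          wt_score = numeric(0), mut_score = numeric(0),
                          delta = numeric(0), category = character(0),
                          phenotype = character(0), stringsAsFactors = FALSE)
  empty_rej <- data.frame(accession = character(0), protein_change = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  list(effects = if (length(eff)) do.call(rbind, eff) else empty_eff,
       rejects = if (length(rej)) do.call(rbind, rej) else empty_rej)
}
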