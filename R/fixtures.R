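# Deterministic synthetic proteomes and annotation tables with known
# planted structure, so every analysis is testable without downloads.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Residue alphabets for synthetic sequence blocks
#'
#' Three block kinds with analytically predictable behaviour under the
#' packaged propensity table and FoldIndex constants: `qn_prionlike`
#' (Q/N/S/Y-rich, positive mean propensity, FoldIndex negative),
#' `charged_disordered` (charge-rich, strongly negative mean propensity,
#' FoldIndex negative), `hydrophobic_ordered` (aliphatic/aromatic,
#' FoldIndex positive so never scored).
#'
#' @return Named list of lists with `residues` and `weights`.
#' @export
block_alphabets <- function() {
  list(
    qn_prionlike = list(
      residues = c("Q", "N", "S", "T", "G", "Y", "K", "R"),
      weights  = c(0.24, 0.24, 0.14, 0.06, 0.08, 0.14, 0.05, 0.05)),
    charged_disordered = list(
      residues = c("E", "D", "K", "R", "S", "T", "G", "P", "Y"),
      weights  = c(0.18, 0.12, 0.18, 0.14, 0.12, 0.08, 0.08, 0.06, 0.04)),
    hydrophobic_ordered = list(
      residues = c("I", "V", "L", "F", "A", "M"),
      weights  = c(0.22, 0.22, 0.20, 0.14, 0.14, 0.08)))
}

#' Specification for a synthetic fixture bundle
#'
#' The generator emulates proteomes mixing Q/N-rich disorder-prone
#' blocks, charged disordered blocks, and hydrophobic ordered blocks,
#' with sparse variant tables, clinical-style mutation tables, and PTM
#' tables with planted per-type enrichment. Identical specs produce
#' byte-identical outputs.
#'
#' @param seed Integer seed; the single pseudo-random source.
#' @param n_proteins Number of reference proteins.
#' @param p_qn Probability a (non-all-ordered) protein carries a planted
#'   Q/N-rich block.
#' @param p_all_ordered Probability a protein is entirely hydrophobic
#'   ordered (sentinel-scoring).
#' @param qn_len,charged_len,ordered_len,all_ordered_len Length ranges
#'   `c(min, max)` per block kind.
#' @param variants_per_prld Variants planted per called PrLD.
#' @param ptm_plan Named list: ptm_type -> `list(n_sites, or)` (target
#'   proteome-wide site count and planted in/out odds ratio).
#' @param isoform_fraction Fraction of Q/N-carrying genes that receive a
#'   second isoform with the Q/N block spliced out.
#' @return Object of class `fixture_spec` (a list).
#' @export
fixture_spec <- function(seed = 1L,
                         n_proteins = 60L,
                         p_qn = 0.7,
                         p_all_ordered = 0.15,
                         qn_len = c(60L, 120L),
                         charged_len = c(50L, 100L),
                         ordered_len = c(30L, 60L),
                         all_ordered_len = c(120L, 240L),
                         variants_per_prld = 3L,
                         ptm_plan = default_ptm_plan(),
                         isoform_fraction = 0.3) {
  stopifnot(n_proteins >= 1, p_qn >= 0, p_qn <= 1,
            p_all_ordered >= 0, p_all_ordered <= 1,
            variants_per_prld >= 0, isoform_fraction >= 0,
            all(qn_len >= 1), all(charged_len >= 1), all(ordered_len >= 1))
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 p_qn = p_qn, p_all_ordered = p_all_ordered,
                 qn_len = qn_len, charged_len = charged_len,
                 ordered_len = ordered_len, all_ordered_len = all_ordered_len,
                 variants_per_prld = as.integer(variants_per_prld),
                 ptm_plan = ptm_plan, isoform_fraction = isoform_fraction),
            class = "fixture_spec")
}

#' Default planted PTM plan
#'
#' Serine phosphorylation planted at odds ratio 3 with 500 sites; five
#' further types planted at odds ratio 1 (no enrichment) with 200 sites
#' each, all above the 100-site inclusion filter.
#'
#' @return Named list of `list(n_sites, or)`.
#' @export
default_ptm_plan <- function() {
  list(
    `serine-phosphorylation`   = list(n_sites = 500L, or = 3),
    `threonine-phosphorylation` = list(n_sites = 200L, or = 1),
    `tyrosine-phosphorylation` = list(n_sites = 200L, or = 1),
    `lysine-acetylation`       = list(n_sites = 200L, or = 1),
    `lysine-ubiquitination`    = list(n_sites = 200L, or = 1),
    `arginine-methylation`     = list(n_sites = 200L, or = 1))
}

.sample_block <- function(kind, len_range, alphabets) {
  len <- sample(len_range[1]:len_range[2], 1)
  a <- alphabets[[kind]]
  paste(sample(a$residues, len, replace = TRUE, prob = a$weights),
        collapse = "")
}

#' Generate a synthetic proteome with planted PrLD structure
#'
#' Each protein is either entirely hydrophobic ordered, or an ordered
#' flank + optional Q/N-rich prion-like block + charged disordered block
#' + ordered flank. The emitted truth table records the planted Q/N
#' block intervals. A fraction of Q/N-carrying genes receives a second
#' isoform with the block spliced out (same gene, `-2` accession
#' suffix).
#'
#' @param spec A [fixture_spec()].
#' @return List with `proteins` (accession, gene, sequence, length),
#'   `gene_map` (accession, gene) and `truth`: `planted` (accession,
#'   start, end, kind) and `spliced` (accession of spliced isoforms and
#'   their source accession).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  alphabets <- block_alphabets()
  .with_seed(spec$seed, {
    prot <- list(); planted <- list(); spliced <- list(); gene_map <- list()
    for (k in seq_len(spec$n_proteins)) {
      acc <- sprintf("SYN%04d", k)
      gene <- sprintf("GENE%04d", k)
      u <- stats::runif(1)
      if (u < spec$p_all_ordered) {
        seqk <- .sample_block("hydrophobic_ordered", spec$all_ordered_len, alphabets)
        has_qn <- FALSE; qn_start <- qn_end <- NA_integer_
      } else {
        left <- .sample_block("hydrophobic_ordered", spec$ordered_len, alphabets)
        has_qn <- stats::runif(1) < spec$p_qn
        qn <- if (has_qn) .sample_block("qn_prionlike", spec$qn_len, alphabets) else ""
        charged <- .sample_block("charged_disordered", spec$charged_len, alphabets)
        right <- .sample_block("hydrophobic_ordered", spec$ordered_len, alphabets)
        seqk <- paste0(left, qn, charged, right)
        qn_start <- nchar(left) + 1L
        qn_end <- nchar(left) + nchar(qn)
      }
      if (!nchar(seqk)) stop("impossible block grammar: zero-length protein")
      prot[[length(prot) + 1L]] <- data.frame(
        accession = acc, gene = gene, sequence = seqk,
        length = nchar(seqk), stringsAsFactors = FALSE)
      gene_map[[length(gene_map) + 1L]] <- data.frame(
        accession = acc, gene = gene, stringsAsFactors = FALSE)
      if (has_qn) {
        planted[[length(planted) + 1L]] <- data.frame(
          accession = acc, start = qn_start, end = qn_end,
          kind = "qn_prionlike", stringsAsFactors = FALSE)
        if (stats::runif(1) < spec$isoform_fraction) {
          iso_acc <- paste0(acc, "-2")
          iso_seq <- paste0(substring(seqk, 1, qn_start - 1L),
                            substring(seqk, qn_end + 1L, nchar(seqk)))
          prot[[length(prot) + 1L]] <- data.frame(
            accession = iso_acc, gene = gene, sequence = iso_seq,
            length = nchar(iso_seq), stringsAsFactors = FALSE)
          gene_map[[length(gene_map) + 1L]] <- data.frame(
            accession = iso_acc, gene = gene, stringsAsFactors = FALSE)
          spliced[[length(spliced) + 1L]] <- data.frame(
            accession = iso_acc, source_accession = acc,
            stringsAsFactors = FALSE)
        }
      }
    }
    empty_planted <- data.frame(accession = character(0), start = integer(0),
                                end = integer(0), kind = character(0),
                                stringsAsFactors = FALSE)
    empty_spliced <- data.frame(accession = character(0),
                                source_accession = character(0),
                                stringsAsFactors = FALSE)
    list(proteins = do.call(rbind, prot),
         gene_map = do.call(rbind, gene_map),
         truth = list(
           planted = if (length(planted)) do.call(rbind, planted) else empty_planted,
           spliced = if (length(spliced)) do.call(rbind, spliced) else empty_spliced))
  })
}

#' Generate a variant table with known score-direction labels
#'
#' Places `variants_per_prld` single amino acid variants inside each
#' PrLD called (at the relaxed threshold) on the reference proteins,
#' alternating propensity-raising (alt F or Y) and propensity-lowering
#' (alt K or D) substitutions. The realised direction of each variant is
#' derived by rescoring the singleton mutant and stored as truth.
#'
#' @param spec A [fixture_spec()].
#' @param proteome Output of [generate_proteome()].
#' @param table,config As for [position_scores()].
#' @return Data frame: `accession`, `position`, `ref`, `alt`,
#'   `planted_direction` (`raise`/`lower`), `realized_direction`
#'   (`raised`/`lowered`/`neutral` from rescoring).
#' @export
generate_variant_table <- function(spec, proteome,
                                   table = default_propensity_table(),
                                   config = scoring_config()) {
  ref <- proteome$proteins[!grepl("-2$", proteome$proteins$accession), ,
                           drop = FALSE]
  .with_seed(spec$seed + 104729L, {
    rows <- list()
    for (k in seq_len(nrow(ref))) {
      acc <- ref$accession[k]; seqk <- ref$sequence[k]
      doms <- find_prlds(seqk, threshold = config$relaxed_threshold,
                         table = table, config = config, accession = acc,
                         strict = FALSE)
      if (!nrow(doms)) next
      base <- protein_score(seqk, table = table, config = config, accession = acc)
      for (d in seq_len(nrow(doms))) {
        width <- doms$end[d] - doms$start[d] + 1L
        npick <- min(spec$variants_per_prld, width)
        if (npick < 1) next
        pos <- sort(sample(doms$start[d]:doms$end[d], npick))
        for (j in seq_along(pos)) {
          refres <- substring(seqk, pos[j], pos[j])
          raise <- j %% 2L == 1L
          alt <- if (raise) {
            if (refres == "F") "Y" else "F"
          } else {
            if (refres == "K") "D" else "K"
          }
          mut <- protein_score(apply_variants(
            seqk, data.frame(position = pos[j], ref = refres, alt = alt), acc),
            table = table, config = config, accession = acc)
          rows[[length(rows) + 1L]] <- data.frame(
            accession = acc, position = pos[j], ref = refres, alt = alt,
            planted_direction = if (raise) "raise" else "lower",
            realized_direction = if (mut > base) "raised"
                                 else if (mut < base) "lowered" else "neutral",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows)) {
      return(data.frame(accession = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        planted_direction = character(0),
                        realized_direction = character(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  })
}

#' Generate a clinical-style mutation table from a variant table
#'
#' Reformats planted variants into `p.<ref><pos><alt>` notation with a
#' synthetic phenotype string, and appends a few records that must be
#' excluded by the parser (stop gain, frameshift, indel, synonymous).
#'
#' @param variant_table Output of [generate_variant_table()].
#' @return Data frame: `accession`, `protein_change`, `phenotype`.
#' @export
generate_clinvar_table <- function(variant_table) {
  main <- data.frame(
    accession = variant_table$accession,
    protein_change = sprintf("p.%s%d%s", variant_table$ref,
                             variant_table$position, variant_table$alt),
    phenotype = "synthetic aggregation phenotype", stringsAsFactors = FALSE)
  if (nrow(variant_table)) {
    acc1 <- variant_table$accession[1]
    extra <- data.frame(
      accession = acc1,
      protein_change = c("p.Arg100Ter", "p.Gly5fs", "p.Leu10del", "p.Ser7="),
      phenotype = "synthetic excluded record", stringsAsFactors = FALSE)
    main <- rbind(main, extra)
  }
  main
}

.solve_site_fractions <- function(n_sites, or, m_in_total, m_out_total) {
  # find f_out such that expected total sites matches n_sites, with
  # odds_in = or * odds_out
  total <- function(f_out) {
    f_in <- or * f_out / (1 - f_out + or * f_out)
    f_in * m_in_total + f_out * m_out_total
  }
  cap <- total(0.95)
  if (n_sites >= cap) {
    stop(sprintf("insufficient modifiable residues: requested %d sites, capacity ~%.0f",
                 n_sites, cap))
  }
  f_out <- stats::uniroot(function(f) total(f) - n_sites,
                          lower = 1e-6, upper = 0.95)$root
  f_in <- or * f_out / (1 - f_out + or * f_out)
  c(f_in = f_in, f_out = f_out)
}

#' Generate a PTM site table with planted per-type odds ratios
#'
#' For each type in the spec's PTM plan, modifiable residues inside and
#' outside the supplied PrLD intervals are modified independently with
#' probabilities chosen so the expected in/out odds ratio equals the
#' planted value and the expected total site count matches the plan.
#' Sampling is rejected and redrawn (deterministic sub-seeds) until the
#' realised odds ratio lies within 5% of the planted value; the realised
#' values are recorded as truth in the `realized` attribute.
#'
#' @param spec A [fixture_spec()].
#' @param proteome Output of [generate_proteome()].
#' @param prlds PrLD intervals defining "inside" (typically
#'   relaxed-threshold calls on the proteome).
#' @param targets PTM target-residue mapping.
#' @param max_attempts Rejection-sampling cap per type (default 200).
#' @return Data frame `accession`, `position`, `residue`, `ptm_type`
#'   with attribute `realized`: per-type planted vs realised odds
#'   ratios and cell counts.
#' @export
generate_ptm_table <- function(spec, proteome, prlds,
                               targets = default_ptm_targets(),
                               max_attempts = 200L) {
  proteins <- proteome$proteins
  # index modifiable residues once per target residue set
  chars_by_prot <- lapply(proteins$sequence, function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  rows <- list(); realized <- list()
  for (tp in names(spec$ptm_plan)) {
    plan <- spec$ptm_plan[[tp]]
    res_str <- targets[[tp]]
    if (is.null(res_str)) stop("no target residues defined for PTM type: ", tp)
    target_res <- strsplit(res_str, "", fixed = TRUE)[[1]]
    pos_in <- list(); pos_out <- list()
    for (k in seq_len(nrow(proteins))) {
      modifiable <- which(chars_by_prot[[k]] %in% target_res)
      if (!length(modifiable)) next
      d <- prlds[prlds$accession == proteins$accession[k], , drop = FALSE]
      inside <- .positions_in_intervals(modifiable, d$start, d$end)
      if (any(inside)) pos_in[[length(pos_in) + 1L]] <- data.frame(
        accession = proteins$accession[k], position = modifiable[inside],
        stringsAsFactors = FALSE)
      if (any(!inside)) pos_out[[length(pos_out) + 1L]] <- data.frame(
        accession = proteins$accession[k], position = modifiable[!inside],
        stringsAsFactors = FALSE)
    }
    p_in <- do.call(rbind, pos_in); p_out <- do.call(rbind, pos_out)
    m_in <- if (is.null(p_in)) 0L else nrow(p_in)
    m_out <- if (is.null(p_out)) 0L else nrow(p_out)
    if (m_in < 2L || m_out < 2L) {
      stop("insufficient modifiable residues for PTM type ", tp)
    }
    fr <- .solve_site_fractions(plan$n_sites, plan$or, m_in, m_out)
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      sub <- spec$seed + 15485863L + attempt * 1009L +
        match(tp, names(spec$ptm_plan)) * 97L
      draw <- .with_seed(sub, {
        list(mod_in = stats::runif(m_in) < fr["f_in"],
             mod_out = stats::runif(m_out) < fr["f_out"])
      })
      a <- sum(draw$mod_in); c0 <- sum(draw$mod_out)
      if (a == 0 || c0 == 0 || a == m_in || c0 == m_out) next
      realized_or <- (a / (m_in - a)) / (c0 / (m_out - c0))
      if (abs(realized_or / plan$or - 1) <= 0.05) { ok <- TRUE; break }
    }
    if (!ok) stop("could not realise planted odds ratio for ", tp,
                  " within 5% in ", max_attempts, " attempts")
    sel_in <- p_in[draw$mod_in, , drop = FALSE]
    sel_out <- p_out[draw$mod_out, , drop = FALSE]
    sel <- rbind(sel_in, sel_out)
    sel$residue <- vapply(seq_len(nrow(sel)), function(r) {
      kk <- match(sel$accession[r], proteins$accession)
      chars_by_prot[[kk]][sel$position[r]]
    }, character(1))
    sel$ptm_type <- tp
    rows[[tp]] <- sel
    realized[[tp]] <- data.frame(
      ptm_type = tp, planted_or = plan$or, realized_or = realized_or,
      mod_in = a, m_in = m_in, mod_out = c0, m_out = m_out,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "realized") <- do.call(rbind, realized)
  out
}

#' Generate and optionally write a complete fixture bundle
#'
#' Proteome FASTA, gene map, variant, clinical-style, and PTM tables,
#' plus the truth metadata. With `dir` set, writes `proteome.fasta`,
#' `gene_map.tsv`, `variants.tsv`, `clinvar.tsv`, `ptms.tsv` and
#' `truth.json` into it.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory (created if missing).
#' @param table,config As for [position_scores()].
#' @return (Invisibly, when writing) list with all components:
#'   `proteome`, `prlds`, `variants`, `clinvar`, `ptms`.
#' @export
generate_fixture_bundle <- function(spec, dir = NULL,
                                    table = default_propensity_table(),
                                    config = scoring_config()) {
  proteome <- generate_proteome(spec)
  scan <- scan_proteome(proteome$proteins, table = table, config = config,
                        threshold = config$relaxed_threshold)
  variants <- generate_variant_table(spec, proteome, table = table,
                                     config = config)
  clinvar <- generate_clinvar_table(variants)
  ptms <- generate_ptm_table(spec, proteome, scan$prlds)
  bundle <- list(proteome = proteome, prlds = scan$prlds, scores = scan$scores,
                 variants = variants, clinvar = clinvar, ptms = ptms)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(proteome$proteins, file.path(dir, "proteome.fasta"))
    write_tsv(proteome$gene_map, file.path(dir, "gene_map.tsv"))
    write_tsv(variants[, c("accession", "position", "ref", "alt")],
              file.path(dir, "variants.tsv"))
    write_tsv(clinvar, file.path(dir, "clinvar.tsv"))
    write_tsv(ptms[, c("accession", "position", "residue", "ptm_type")],
              file.path(dir, "ptms.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      truth <- list(seed = spec$seed,
                    planted = proteome$truth$planted,
                    spliced = proteome$truth$spliced,
                    variant_labels = variants[, c("accession", "position",
                                                  "planted_direction",
                                                  "realized_direction")],
                    ptm_realized = attr(ptms, "realized"))
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(bundle)
}
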