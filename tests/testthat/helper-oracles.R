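# Independent oracles and fixture builders shared across tests.
# Oracles deliberately use naive, explicit algorithms (nested loops,
# enumeration) so they share no code path with the package internals.

# Naive per-position scan: explicit nested windows, no cumulative sums.
oracle_position_scores <- function(sequence, table = default_propensity_table(),
                                   config = scoring_config()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  W <- config$window_size
  if (n < W) {
    return(data.frame(position = integer(0), score = numeric(0),
                      gated = logical(0)))
  }
  pv <- as.numeric(table)[match(chars, names(table))]
  hy <- config$hydrophobicity_scaled[match(chars, names(config$hydrophobicity_scaled))]
  ch <- config$charge[match(chars, names(config$charge))]
  nw <- n - W + 1L
  wins <- numeric(nw)
  for (i in seq_len(nw)) {
    s <- 0
    for (j in i:(i + W - 1L)) s <- s + pv[j]
    wins[i] <- s / W
  }
  pos <- integer(nw); sc <- numeric(nw); gated <- logical(nw)
  for (i in seq_len(nw)) {
    last <- min(i + W - 1L, nw)
    s <- 0
    for (j in i:last) s <- s + wins[j]
    sc[i] <- s / (last - i + 1L)
    pos[i] <- i + W - 1L
    gend <- if (config$gate_mode == "span") min(i + config$effective_span - 1L, n)
            else i + W - 1L
    hsum <- 0; qsum <- 0
    for (j in i:gend) { hsum <- hsum + hy[j]; qsum <- qsum + ch[j] }
    len <- gend - i + 1L
    fi <- config$fold_slope * hsum / len - abs(qsum / len) + config$fold_intercept
    gated[i] <- fi < 0
  }
  data.frame(position = pos, score = sc, gated = gated)
}

oracle_protein_score <- function(sequence, table = default_propensity_table(),
                                 config = scoring_config()) {
  o <- oracle_position_scores(sequence, table, config)
  if (!any(o$gated)) config$sentinel else max(o$score[o$gated])
}

# Two-sided Fisher exact p by exhaustive hypergeometric tail summation:
# sum the probabilities of all tables (same margins) no more probable
# than the observed one.
oracle_fisher_two_sided <- function(a, b, c0, d0) {
  m <- a + b        # row 1 total
  n2 <- c0 + d0     # row 2 total
  k <- a + c0       # column 1 total
  lo <- max(0L, k - n2); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out explicitly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

# Random fixture protein built from the generator's block alphabets,
# but assembled here by hand.
random_fixture_protein <- function(len) {
  alph <- block_alphabets()
  kinds <- names(alph)
  out <- character(0)
  while (length(out) < len) {
    a <- alph[[sample(kinds, 1)]]
    blk_len <- sample(20:60, 1)
    out <- c(out, sample(a$residues, blk_len, replace = TRUE, prob = a$weights))
  }
  paste(out[seq_len(len)], collapse = "")
}

# A compact config (window 5) so constructed fixtures stay hand-checkable.
small_config <- function(...) scoring_config(window_size = 5L, ...)

hnrnpa1_fasta <- function() {
  system.file("extdata", "hnRNPA1_isoforms.fasta", package = "prionscan",
              mustWork = TRUE)
}
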