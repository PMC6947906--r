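test_that("window propensity is the composition-only mean of residue propensities", {
  tab <- default_propensity_table()
  # homopolymer: mean of identical values is the value itself
  expect_equal(window_propensity(strrep("Q", 41)), unname(tab["Q"]))
  # permutation invariance
  set.seed(11)
  w <- paste(sample(strsplit("QNQNYSSGGYQNQNYSSGGYQNQNYSSGGYQNQNYSSGGYQ", "")[[1]]),
             collapse = "")
  expect_equal(window_propensity(w),
               window_propensity("QNQNYSSGGYQNQNYSSGGYQNQNYSSGGYQNQNYSSGGYQ"))
  # independent sum-then-divide oracle on a fixed 41-mer
  fix <- "QNQNYGGSYSQQNNPAGSRKQNYGGSSYQNAGYDQSSNYGQ"
  chars <- strsplit(fix, "")[[1]]
  expect_length(chars, 41)
  acc <- 0
  for (ch in chars) acc <- acc + as.numeric(tab[ch])
  expect_equal(window_propensity(fix), acc / 41, tolerance = 1e-12)
})

test_that("window propensity rejects non-canonical residues with a position report", {
  expect_error(window_propensity(paste0(strrep("Q", 20), "X", strrep("Q", 20))),
               "position\\(s\\) 21")
  expect_error(window_propensity(""), "non-empty")
})

test_that("window FoldIndex matches the closed-form arithmetic of its constants", {
  # lysine homopolymer: 2.785 * ((-3.9 + 4.5) / 9) - |1| - 1.151
  expect_equal(window_foldindex(strrep("K", 41)),
               2.785 * ((-3.9 + 4.5) / 9) - 1 - 1.151, tolerance = 1e-12)
  expect_lt(window_foldindex(strrep("K", 41)), 0)  # disordered
  # isoleucine homopolymer: 2.785 * 1.0 - 0 - 1.151
  expect_equal(window_foldindex(strrep("I", 41)), 2.785 * 1.0 - 1.151,
               tolerance = 1e-12)
  expect_gt(window_foldindex(strrep("I", 41)), 0)  # ordered
  # equal-count K/E: net charge cancels, hydrophobicity term alone
  w <- strrep("KE", 20)
  h <- mean((c(-3.9, -3.5)[rep(1:2, 20)] + 4.5) / 9)
  expect_equal(window_foldindex(w), 2.785 * h - 1.151, tolerance = 1e-12)
})

test_that("profiles anchor run scores at the last residue of the first window", {
  cfg <- small_config()  # window 5, span 9
  seqx <- paste0(strrep("I", 10), strrep("Q", 10), strrep("I", 10))
  prof <- position_scores(seqx, config = cfg)$profile
  # hand-enumerated: spans i..i+8 hold >= 6 Q exactly for runs 8..15,
  # anchored at positions 12..19
  expect_identical(prof$position[prof$gated], 12:19)
  expect_identical(prof$position, 5:30)
  expect_identical(prof$span_start, 1:26)
  expect_identical(prof$span_end, as.integer(pmin(1:26 + 8, 30)))
})

test_that("per-41-mer gate mode gates on the single window ending at the position", {
  cfg <- small_config(gate_mode = "window")
  seqx <- paste0(strrep("I", 10), strrep("Q", 10), strrep("I", 10))
  prof <- position_scores(seqx, config = cfg)$profile
  # 5-mers i..i+4 hold >= 4 Q exactly for i = 10..17 -> positions 14..21
  expect_identical(prof$position[prof$gated], 14:21)
})

test_that("profiles match a naive nested-loop oracle on random fixture proteins", {
  set.seed(101)
  cfg <- scoring_config()
  for (rep in 1:20) {
    seqx <- random_fixture_protein(sample(41:500, 1))
    got <- position_scores(seqx, config = cfg)
    want <- oracle_position_scores(seqx, config = cfg)
    expect_equal(got$profile$position, want$position)
    expect_equal(got$profile$score, want$score, tolerance = 1e-9)
    expect_identical(got$profile$gated, want$gated)
    expect_equal(got$protein_score, oracle_protein_score(seqx, config = cfg),
                 tolerance = 1e-9)
  }
})

test_that("profiles are deterministic and protein_score is the max gated score", {
  set.seed(5)
  seqx <- random_fixture_protein(300)
  a <- position_scores(seqx)
  b <- position_scores(seqx)
  expect_identical(a$profile, b$profile)
  expect_identical(a$protein_score, b$protein_score)
  expect_equal(a$protein_score, max(a$profile$score[a$profile$gated]))
})

test_that("ordered proteins and short proteins take the sentinel score", {
  expect_identical(protein_score(strrep("I", 100)), -1.0)
  expect_identical(position_scores(strrep("I", 100))$protein_score, -1.0)
  expect_false(any(position_scores(strrep("I", 100))$profile$gated))
  # shorter than the window: zero scored positions, sentinel
  p <- position_scores(strrep("Q", 30))
  expect_identical(nrow(p$profile), 0L)
  expect_identical(p$protein_score, -1.0)
})

test_that("the disorder gate is composition-only and the score is reversal-symmetric", {
  # The gate (FoldIndex over the span) is a plain mean, so any permutation
  # of the span leaves it unchanged. The run score weights span residues by
  # window coverage (triangular), so it is not permutation-invariant, but
  # the weights are symmetric: reversing a full interior span preserves it.
  set.seed(42)
  cfg <- scoring_config()
  for (rep in 1:10) {
    seqx <- random_fixture_protein(250)
    prof <- position_scores(seqx, config = cfg)$profile
    nw <- 250 - cfg$window_size + 1L
    full <- which(prof$span_start <= nw - cfg$window_size + 1L)
    k <- sample(full, 1)
    i <- prof$span_start[k]; j <- prof$span_end[k]
    chars <- strsplit(seqx, "")[[1]]
    perm <- chars; perm[i:j] <- sample(perm[i:j])
    prof_perm <- position_scores(paste(perm, collapse = ""), config = cfg)$profile
    expect_identical(prof_perm$gated[k], prof$gated[k])
    rev_ <- chars; rev_[i:j] <- rev(rev_[i:j])
    prof_rev <- position_scores(paste(rev_, collapse = ""), config = cfg)$profile
    expect_equal(prof_rev$score[k], prof$score[k], tolerance = 1e-12)
    expect_identical(prof_rev$gated[k], prof$gated[k])
  }
})

test_that("raising a residue's propensity never lowers the score while the gate holds", {
  tab <- default_propensity_table()
  set.seed(77)
  checked <- 0
  for (rep in 1:30) {
    # uncharged prion-like fixture so substitutions rarely perturb the gate
    chars <- sample(c("Q", "N", "S", "G", "Y"), 150, replace = TRUE,
                    prob = c(.3, .3, .2, .1, .1))
    seqx <- paste(chars, collapse = "")
    pos <- sample(150, 1)
    higher <- names(tab)[as.numeric(tab) > as.numeric(tab[chars[pos]])]
    higher <- intersect(higher, c("Q", "N", "S", "G", "Y", "F", "M", "W", "C"))
    if (!length(higher)) next
    chars2 <- chars; chars2[pos] <- sample(higher, 1)
    seq2 <- paste(chars2, collapse = "")
    g1 <- position_scores(seqx)$profile$gated
    g2 <- position_scores(seq2)$profile$gated
    if (!identical(g1, g2) || !any(g1)) next  # gate must hold throughout
    expect_gte(protein_score(seq2), protein_score(seqx))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("PrLD calling merges overlapping window extents and separates distant blocks", {
  cfg <- small_config()
  # all-ordered protein: nothing exceeds any threshold
  expect_identical(nrow(find_prlds(strrep("I", 60), threshold = 0, config = cfg)), 0L)
  # two Q/N blocks separated by a long ordered spacer: two disjoint domains
  two <- paste0(strrep("I", 12), strrep("Q", 10), strrep("I", 30),
                strrep("Q", 10), strrep("I", 12))
  d2 <- find_prlds(two, threshold = 0, config = cfg, accession = "two")
  expect_identical(nrow(d2), 2L)
  expect_true(all(d2$end[1] < d2$start[2]))
  expect_true(all(d2$peak_score > 0))
  expect_identical(d2$domain_sequence,
                   substring(two, d2$start, d2$end))
  # adjacent overlapping above-threshold runs merge into one domain
  one <- paste0(strrep("I", 12), strrep("Q", 20), strrep("I", 12))
  d1 <- find_prlds(one, threshold = 0, config = cfg)
  expect_identical(nrow(d1), 1L)
})

test_that("sentinel score, absent gated positions and empty domain calls coincide", {
  set.seed(300)
  for (rep in 1:20) {
    seqx <- random_fixture_protein(sample(41:300, 1))
    prof <- position_scores(seqx)
    gated_any <- any(prof$profile$gated)
    is_sentinel <- prof$protein_score == -1.0
    doms_low <- find_prlds(prof, threshold = -100)
    expect_identical(is_sentinel, !gated_any)
    expect_identical(nrow(doms_low) == 0L, !gated_any)
    if (nrow(doms_low)) {
      expect_true(all(doms_low$peak_score > -100))
      expect_true(!is.unsorted(doms_low$start))
      expect_true(all(doms_low$start[-1] > doms_low$end[-nrow(doms_low)]))
    }
  }
})

test_that("lenient scans skip proteins with non-canonical residues, strict scans fail", {
  prot <- data.frame(accession = c("A1", "B1"),
                     sequence = c(strrep("Q", 60),
                                  paste0(strrep("Q", 30), "U", strrep("Q", 30))),
                     stringsAsFactors = FALSE)
  expect_warning(res <- scan_proteome(prot, strict = FALSE), "non-canonical")
  expect_identical(res$skipped, "B1")
  expect_identical(res$scores$accession, "A1")
  expect_error(scan_proteome(prot, strict = TRUE), "B1")
  expect_error(scan_proteome(rbind(prot[1, ], prot[1, ])), "duplicate")
})
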