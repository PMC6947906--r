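test_that("PrLD membership of PTM sites is inclusive at both boundaries", {
  prlds <- data.frame(accession = "P1", start = 10L, end = 20L)
  sites <- data.frame(accession = "P1", position = c(9L, 10L, 20L, 21L),
                      residue = "S", ptm_type = "serine-phosphorylation",
                      stringsAsFactors = FALSE)
  m <- map_ptms_to_prlds(sites, prlds)
  expect_identical(m$sites$in_prld, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(m$per_prld_counts$n_sites, 2L)
  # out-of-range sites are rejected with a log entry when sequences are known
  prot <- data.frame(accession = "P1", sequence = strrep("S", 25),
                     stringsAsFactors = FALSE)
  sites2 <- rbind(sites, data.frame(accession = "P1", position = 99L,
                                    residue = "S",
                                    ptm_type = "serine-phosphorylation"))
  m2 <- map_ptms_to_prlds(sites2, prlds, prot)
  expect_identical(m2$rejects$reason, "position_out_of_range")
  expect_identical(nrow(m2$sites), 4L)
})

test_that("site-to-PrLD mapping matches an independent interval recount", {
  spec <- fixture_spec(seed = 3, n_proteins = 20,
                       ptm_plan = list(
                         `serine-phosphorylation` = list(n_sites = 150L, or = 3),
                         `lysine-acetylation` = list(n_sites = 100L, or = 1)))
  b <- generate_fixture_bundle(spec)
  m <- map_ptms_to_prlds(b$ptms, b$prlds, b$proteome$proteins)
  for (k in sample(nrow(m$sites), 50)) {
    acc <- m$sites$accession[k]; pos <- m$sites$position[k]
    d <- b$prlds[b$prlds$accession == acc, , drop = FALSE]
    inside <- FALSE
    for (r in seq_len(nrow(d))) {
      if (pos >= d$start[r] && pos <= d$end[r]) inside <- TRUE
    }
    expect_identical(m$sites$in_prld[k], inside)
  }
})

test_that("contingency tables count modifiable residues exactly", {
  # planted micro-proteome: modifiable = S; one PrLD per protein
  prot <- data.frame(accession = c("P1", "P2"),
                     sequence = c(paste0(strrep("S", 10), strrep("A", 20)),
                                  paste0(strrep("G", 5), strrep("S", 10))),
                     stringsAsFactors = FALSE)
  prlds <- data.frame(accession = c("P1", "P2"), start = c(1L, 6L),
                      end = c(5L, 10L))
  sites <- data.frame(accession = c("P1", "P1", "P2"),
                      position = c(2L, 8L, 7L), residue = "S",
                      ptm_type = "serine-phosphorylation",
                      stringsAsFactors = FALSE)
  ct <- build_contingency(sites, prot, prlds, "serine-phosphorylation")
  # P1: S at 1..10, PrLD 1..5 -> in: 5 (1 mod), out: 5 (1 mod)
  # P2: S at 6..15, PrLD 6..10 -> in: 5 (1 mod), out: 5 (0 mod)
  expect_identical(ct$mod_in_prld, 2L)
  expect_identical(ct$unmod_in_prld, 8L)
  expect_identical(ct$mod_outside, 1L)
  expect_identical(ct$unmod_outside, 9L)
  expect_identical(ct$n_sites_proteome, 3L)
  # doubling every protein duplicates all counts
  prot2 <- rbind(prot, transform(prot, accession = paste0(accession, "b")))
  prlds2 <- rbind(prlds, transform(prlds, accession = paste0(accession, "b")))
  sites2 <- rbind(sites, transform(sites, accession = paste0(accession, "b")))
  ct2 <- build_contingency(sites2, prot2, prlds2, "serine-phosphorylation")
  expect_identical(ct2$mod_in_prld, 2L * ct$mod_in_prld)
  expect_identical(ct2$unmod_outside, 2L * ct$unmod_outside)
  # a proteome without the target residue gives an all-zero, undefined result
  prot0 <- data.frame(accession = "P9", sequence = strrep("A", 30))
  ct0 <- build_contingency(sites[0, ], prot0, prlds[0, ], "serine-phosphorylation")
  e0 <- ptm_enrichment(ct0)
  expect_true(e0$zero_cell)
  expect_true(is.na(e0$odds_ratio))
})

test_that("a residue modified by one type still counts unmodified for another", {
  prot <- data.frame(accession = "P1", sequence = strrep("K", 20),
                     stringsAsFactors = FALSE)
  prlds <- data.frame(accession = "P1", start = 1L, end = 10L)
  sites <- data.frame(accession = "P1", position = 3L, residue = "K",
                      ptm_type = "lysine-acetylation", stringsAsFactors = FALSE)
  ub <- build_contingency(sites, prot, prlds, "lysine-ubiquitination")
  expect_identical(ub$mod_in_prld, 0L)
  expect_identical(ub$unmod_in_prld, 10L)
  ac <- build_contingency(sites, prot, prlds, "lysine-acetylation")
  expect_identical(ac$mod_in_prld, 1L)
})

test_that("enrichment arithmetic follows the fraction-odds definition", {
  ct <- list(ptm_type = "x", mod_in_prld = 10, unmod_in_prld = 90,
             mod_outside = 50, unmod_outside = 950, n_sites_proteome = 60)
  e <- ptm_enrichment(ct)
  expect_equal(e$odds_ratio, (10 / 90) / (50 / 950), tolerance = 1e-12)
  expect_equal(e$odds_ratio, 2.1111, tolerance = 1e-4)
  expect_equal(e$log_enrichment, log((10 / 90) / (50 / 950)), tolerance = 1e-12)
  expect_equal(e$log_enrichment, 0.7472, tolerance = 1e-3)
  expect_equal(e$se_log_enrichment,
               sqrt(1 / 10 + 1 / 90 + 1 / 50 + 1 / 950), tolerance = 1e-12)
  expect_equal(e$f_mod_prld, 0.1)
  # equal fractions: OR = 1, E = 0
  eq <- ptm_enrichment(list(ptm_type = "x", mod_in_prld = 10, unmod_in_prld = 90,
                            mod_outside = 30, unmod_outside = 270,
                            n_sites_proteome = 40))
  expect_equal(eq$odds_ratio, 1)
  expect_equal(eq$log_enrichment, 0)
  # swapping in/out negates E and preserves the Fisher p
  sw <- ptm_enrichment(list(ptm_type = "x", mod_in_prld = 50, unmod_in_prld = 950,
                            mod_outside = 10, unmod_outside = 90,
                            n_sites_proteome = 60))
  expect_equal(sw$log_enrichment, -e$log_enrichment, tolerance = 1e-12)
  expect_equal(sw$fisher_p, e$fisher_p, tolerance = 1e-12)
  # zero cell: flagged undefined by default, finite with Haldane correction
  z <- ptm_enrichment(list(ptm_type = "x", mod_in_prld = 0, unmod_in_prld = 50,
                           mod_outside = 5, unmod_outside = 45,
                           n_sites_proteome = 5))
  expect_true(z$zero_cell)
  expect_true(is.na(z$odds_ratio))
  zh <- ptm_enrichment(list(ptm_type = "x", mod_in_prld = 0, unmod_in_prld = 50,
                            mod_outside = 5, unmod_outside = 45,
                            n_sites_proteome = 5), haldane = TRUE)
  expect_true(is.finite(zh$odds_ratio))
})

test_that("Fisher p agrees with exhaustive hypergeometric tail summation", {
  set.seed(55)
  # tables with all margins <= 50
  for (rep in 1:40) {
    a <- sample(0:20, 1); b <- sample(0:25, 1)
    c0 <- sample(0:20, 1); d0 <- sample(0:25, 1)
    if (a + b == 0 || c0 + d0 == 0 || a + c0 == 0 || b + d0 == 0) next
    e <- ptm_enrichment(list(ptm_type = "x", mod_in_prld = a, unmod_in_prld = b,
                             mod_outside = c0, unmod_outside = d0,
                             n_sites_proteome = a + c0))
    expect_equal(e$fisher_p, oracle_fisher_two_sided(a, b, c0, d0),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches an explicit step-up and flags at the stated FDR", {
  one <- data.frame(ptm_type = "a", fisher_p = 0.031)
  expect_equal(bh_adjust(one)$bh_q, 0.031)
  allsame <- data.frame(ptm_type = letters[1:4], fisher_p = rep(0.02, 4))
  expect_equal(bh_adjust(allsame)$bh_q, rep(0.02, 4))
  set.seed(8)
  mixed <- data.frame(ptm_type = letters[1:9],
                      fisher_p = c(1e-6, 0.004, 0.011, 0.02, 0.04, 0.2,
                                   0.5, 0.8, 0.95))
  adj <- bh_adjust(mixed, fdr = 0.05)
  expect_equal(adj$bh_q, oracle_bh(mixed$fisher_p), tolerance = 1e-12)
  expect_identical(adj$significant, adj$bh_q < 0.05)
  empty <- bh_adjust(data.frame(ptm_type = character(0), fisher_p = numeric(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("the low-count filter excludes types before adjustment", {
  spec <- fixture_spec(seed = 3, n_proteins = 20,
                       ptm_plan = list(
                         `serine-phosphorylation` = list(n_sites = 300L, or = 3),
                         `arginine-methylation` = list(n_sites = 50L, or = 1)))
  b <- generate_fixture_bundle(spec)
  res <- ptm_analysis(b$proteome$proteins, b$ptms, prlds = b$prlds)
  r <- res[res$ptm_type == "arginine-methylation", ]
  expect_true(r$excluded_lowcount)
  expect_true(is.na(r$bh_q))
  s <- res[res$ptm_type == "serine-phosphorylation", ]
  expect_false(s$excluded_lowcount)
  expect_true(s$significant)
  # conservation: modified cells sum to the proteome-wide site count
  expect_identical(s$mod_in_prld + s$mod_outside, s$n_sites_proteome)
  expect_identical(s$n_sites_proteome,
                   length(unique(paste(
                     b$ptms$accession, b$ptms$position
                   )[b$ptms$ptm_type == "serine-phosphorylation"])))
})
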