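---
title: "Methods: scanning for prion-like domains and analysing sequence variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for prion-like domains and analysing sequence variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionscan)
```

## The scoring model

Prion-like domains (PrLDs) are protein regions compositionally similar to
yeast prion domains: rich in glutamine/asparagine (Q/N), poor in charged
and strongly hydrophobic residues. Because composition rather than exact
sequence drives prion-like behaviour, the scanner scores windows by
composition alone.

Three ingredients define the score of a protein:

1. **Per-residue prion propensities.** Each canonical amino acid carries a
   dimensionless propensity (packaged in
   `inst/extdata/prion_propensity.tsv`, provenance recorded in the
   table's `source_tag`). These values derive from random mutagenesis of
   a canonical Q/N-rich yeast prion domain, in which the frequency of
   prion formation was assayed directly, so they estimate how much each
   residue promotes or inhibits prion aggregation. The score of a
   `window_size`-residue window is the arithmetic mean of its residues'
   propensities.

2. **Position scores from runs of windows.** With the default window size
   $w = 41$, the run starting at residue $i$ comprises up to $w$
   consecutive windows (fewer near the C-terminus, at least one), and its
   score is the mean of their window scores — effectively an
   $2w - 1 = 81$-residue span. The run score is anchored at the last
   residue of the run's *first* window ($i + w - 1$), which keeps scores
   attached to real residue coordinates and so lets variants and PTM
   sites be mapped onto scored positions, including near protein
   termini. Note the arithmetic consequence of averaging overlapping
   windows: residues of the span are weighted triangularly (the span
   centre sits in every governing window, the edges in one). The
   anchored score is therefore *not* invariant to arbitrary permutations
   within the span — only within a single window — though it is
   invariant to reversal of a full span, since the weights are
   symmetric. The per-position profile tests assert exactly these
   properties.

3. **A disorder gate.** Prion-like behaviour requires the region to be
   intrinsically disordered. FoldIndex,
   $\mathrm{FI} = 2.785\,\langle H\rangle - |\langle R\rangle| - 1.151$,
   combines mean Kyte–Doolittle hydropathy rescaled to $[0,1]$
   ($\langle H\rangle$) and mean net charge ($\langle R\rangle$);
   negative values predict disorder. A position's score is reported only
   when the FoldIndex computed over the *full governing span* (up to 81
   residues, truncated at termini) is negative. We chose the union span
   of the governing windows as the most literal reading of gating "over
   each full window"; `scoring_config(gate_mode = "window")` switches to
   gating on the single 41-mer ending at the anchored position for
   comparison.

The **protein score** is the maximum gated position score. A protein with
no gated position — no predicted disordered region at all — takes the
sentinel score $-1.0$, which lies below every attainable window mean and
is treated as "not scoreable" downstream rather than as a small score.

**PrLD boundaries** are called by collecting the governing spans of all
gated positions whose score strictly exceeds a threshold and merging
overlapping spans into maximal intervals; each merged interval keeps its
peak contributing score and its 1-based inclusive coordinates. Strict
(`>`) comparisons are used at both thresholds. Two thresholds matter:

* the **classical threshold 0.05**, above which a PrLD is considered
  aggregation-prone, and
* the **relaxed threshold 0.0**, which defines candidate PrLDs for the
  variant and PTM analyses — sequence variation or modification may push
  a near-threshold domain across 0.05, so candidates are collected more
  inclusively.

Because the positions qualifying at 0.05 are a subset of those
qualifying at 0.0, every 0.05-domain is an interval-subset of a
0.0-domain (tested as the nestedness property).

As a check of the whole arithmetic, the packaged two-isoform hnRNPA1
FASTA reproduces the isoform scores reported for this scanner
(0.093 for the 372-residue isoform, 0.042 for the 320-residue isoform):

```{r hnrnpa1}
fa <- read_fasta(system.file("extdata", "hnRNPA1_isoforms.fasta",
                             package = "prionscan"))
round(vapply(fa$sequence, protein_score, numeric(1), USE.NAMES = FALSE), 3)
```

## Residue policy and numerical choices

The propensity table is defined only on the 20 canonical residues.
Strict mode rejects any other letter with a position report; lenient
mode (the default for proteome scans) skips the whole protein with a
warning, since imputing a propensity for U/B/Z/X/* would silently bias
window means. Scores are computed in double precision; file outputs are
rounded to 6 decimals, and test comparisons use 1e-9. Profiles are
deterministic: identical inputs give bit-identical output. Ties for the
maximum (protein score, peak score) need no tie-breaking because only
the value is reported.

## Variant-combination analysis

For proteins whose baseline score exceeds the relaxed threshold, the
analysis enumerates the reference sequence, every singleton variant, and
every unordered pair of variants at distinct positions ("up to
pairwise"; singletons are included by default because the
reference-vs-variant comparisons require them, and `pairs_only = TRUE`
restricts to pairs). Variants qualify when they fall inside a PrLD
called at the relaxed threshold on the *reference* sequence; domain
boundaries are fixed by the reference while scores are recomputed per
variant sequence. Each enumerated sequence is rescored in full, and the
summary records the minimum, maximum, range, and unique-score count. A
combination that abolishes all predicted disorder drives the minimum to
the sentinel $-1.0$; such summaries are flagged and excluded from
aggregate outputs, since $-1.0$ is a category, not a magnitude.
Reference-residue mismatches (common when public variant tables mix
isoform coordinate frames) are logged and skipped, never fatal.

## Isoform comparison

Isoforms are grouped by gene via an explicit accession-to-gene map (a
`gene=` FASTA-header fallback exists). Within a group each isoform is
scored and compared to the gene maximum; all isoforms tied at the
maximum are `max_isoform` and deltas use the shared maximum. An isoform
at or below 0.05 in a gene whose maximum exceeds 0.05 is `crossing`; one
above 0.05 with a higher-scoring sibling is `high_with_higher`; genes
entirely at or below the classical threshold are retained in full output
but dropped from the crossing-only report, matching its selection rule.

## Clinical missense variants

Protein changes arrive in `p.` notation, one- or three-letter. Stop
gains, frameshifts, indels, synonymous records and non-canonical
residues are excluded with reasons rather than errors. Positions are
interpreted on the supplied isoform's sequence; an optional
`isoform_accession` column selects the coordinate frame explicitly,
because silent remapping between isoform frames is exactly the failure
mode that produces reference mismatches. Wild-type and mutant sequences
are scored with identical configuration; the effect categories
(`high_increasing`, `threshold_crossing`, `decreasing`,
`subthreshold_other`) are a total function of the two scores and the
classical threshold. Score-decreasing variants are retained in output —
they may matter for proteins whose function depends on a tuned
aggregation propensity.

## PTM enrichment within PrLDs

PrLDs have strongly biased composition, so raw PTM counts inside PrLDs
mostly reflect residue availability. The analysis therefore conditions
on modifiability: for each PTM type, only residues that *could* carry
that modification are counted (packaged mapping in
`inst/extdata/ptm_residues.tsv`, user-overridable; a residue modified by
type A still counts as unmodified for type B). The 2×2 table of
modified/unmodified × inside/outside PrLDs (called at the relaxed
threshold) gives

$$ OR = \frac{f_{in}/(1-f_{in})}{f_{out}/(1-f_{out})}, \qquad
   E = \ln OR, $$

with the standard error of $E$ the conventional square root of summed
reciprocal cell counts (undefined and flagged on zero cells; an optional
Haldane–Anscombe correction is available but off by default).
Significance is a two-sided Fisher exact test with Benjamini–Hochberg
correction at FDR 0.05; types with fewer than 100 modification sites
proteome-wide are excluded *before* adjustment so they neither dilute
nor borrow strength from the tested types.

## The synthetic fixture generator

The generator builds proteomes from three block kinds whose behaviour
under the packaged propensity table and FoldIndex constants is
analytically predictable: Q/N-rich prion-like blocks (positive mean
propensity, FoldIndex negative), charged disordered blocks (disordered
but strongly negative propensity), and hydrophobic ordered blocks
(FoldIndex positive, hence never scored). Planted Q/N intervals are
emitted as truth; with the default geometry (60 proteins; Q/N blocks of
60–120 residues; flanks of 30–60; 15% of proteins entirely ordered;
70% of the rest carrying a Q/N block) at least 95% of planted blocks
intersect a called PrLD at the relaxed threshold, across seeds. Block
lengths and rates were chosen once to resemble the scale of natural
low-complexity domains while keeping the whole suite fast; the sizes
are stated here as the package's own defaults.

Variant tables place alternating propensity-raising (to F/Y) and
propensity-lowering (to K/D) substitutions inside called PrLDs; the
realised direction of each variant is determined by rescoring and stored
as truth (a variant far from the score peak can be neutral for the
protein maximum, which is why realised labels, not intent, are the
truth). PTM tables plant a per-type in/out odds ratio by independent
Bernoulli placement over modifiable residues, with deterministic
rejection-resampling until the realised odds ratio is within 5% of the
planted one; the default plan plants serine phosphorylation at OR 3 with
500 sites and five further types at OR 1 with 200 sites each.

What the fixtures do **not** emulate: natural proteome composition,
realistic gene structures, linkage between variants, position-specific
PTM sequence motifs, or isoform diversity beyond whole-block splicing.
Passing the fixture suites therefore demonstrates the correctness of the
arithmetic and bookkeeping, not predictive validity on real proteomes —
the hnRNPA1 anchor values are the only real-sequence check shipped with
the package.

All generator randomness flows from the single integer seed of the
`fixture_spec` (sub-seeded deterministically per table; the caller's RNG
state is saved and restored), so identical specs give byte-identical
bundles.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures plus the two packaged hnRNPA1 sequences: 200 random proteins of
length 41–500 for the nested-loop oracle comparison, the default
60-protein proteome for the variant/isoform/PTM pipelines, and 100
seeded replicates of the planted-odds-ratio recovery experiment. These
sizes were chosen so the entire suite completes in about a minute on a
single CPU while leaving each statistical check enough resolution to
fail visibly if the arithmetic drifts.

## Known limitations

* The scanner is composition-based by design; primary-sequence motifs
  (e.g. steric zippers) are invisible to it.
* FoldIndex is the only disorder predictor implemented; proteins whose
  disorder is missed by a linear charge/hydropathy rule are not scored.
* Variant combinations stop at pairs; triple and higher combinations are
  out of scope.
* PTM analysis treats sites as independent and ignores the sequence
  context of modification motifs; it tests global enrichment, not
  per-protein regulation.
* N-terminal modifications have no residue-level target set and are not
  analysed.
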