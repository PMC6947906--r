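# prionscan

Sliding-window prediction of prion-like domains (PrLDs) in protein
sequences, and analysis of how sequence variation — genetic variants,
alternative splicing, clinical missense mutations, and post-translational
modifications (PTMs) — relates to predicted aggregation propensity.

PrLDs are low-complexity regions compositionally similar to yeast prion
domains (Q/N-rich, few charged and hydrophobic residues). Aggregation of
PrLD-containing proteins such as hnRNPA1, FUS and TDP-43 is central to
several neurodegenerative disorders, and reference-proteome scans miss
the sequence diversity *within* a species. This package is for
computational biologists who want to scan proteomes for PrLDs and ask
how natural or pathogenic variation moves proteins across the
aggregation-propensity threshold.

## The model

Each canonical amino acid carries a prion propensity estimated from
random mutagenesis of a canonical Q/N-rich yeast prion domain. The score
of a 41-residue window is the mean propensity of its residues; the score
anchored at position *i* + 40 is the mean over up to 41 consecutive
windows starting at *i* (an effective 81-residue span, truncated at
termini). A position is scored only where the region is predicted
intrinsically disordered by FoldIndex,

    FI = 2.785 <H> − |<R>| − 1.151,

(<H> mean scaled Kyte–Doolittle hydropathy, <R> mean net charge)
computed over the full governing span; negative FI predicts disorder.
The protein score is the maximum gated position score, or the sentinel
−1.0 for proteins with no predicted disorder. Governing spans of gated
positions scoring above a threshold are merged into PrLD intervals
(classical threshold 0.05 for aggregation-prone calls; relaxed threshold
0.0 for candidate domains in variant/PTM analyses).

Downstream analyses: exhaustive enumeration of single and pairwise
variant combinations within PrLDs with min/max/range score summaries;
per-gene isoform comparison with threshold-crossing categories; clinical
`p.` notation parsing and wild-type vs mutant effect classification; and
composition-controlled PTM enrichment within PrLDs (odds ratio over
modifiable residues, `E = ln OR`, two-sided Fisher exact test,
Benjamini–Hochberg correction at FDR 0.05, ≥100-site inclusion filter).
A deterministic synthetic-proteome generator with planted structure
backs the test suite. See `vignette("prionscan-methods")` for details.

## Worked example

Score the packaged two-isoform hnRNPA1 FASTA and call its PrLDs:

```r
library(prionscan)
fa <- read_fasta(system.file("extdata", "hnRNPA1_isoforms.fasta",
                             package = "prionscan"))
scan <- scan_proteome(fa)
scan$scores
#>   accession    gene protein_score n_prlds
#> 1  P09651-1 HNRNPA1    0.09316181       1
#> 2  P09651-2 HNRNPA1    0.04150690       1
scan$prlds[, c("accession", "start", "end", "peak_score")]
#>   accession start end peak_score
#> 1  P09651-1   175 372 0.09316181
#> 2  P09651-2   175 320 0.04150690
```

The long isoform (hnRNPA1-B, 372 aa) scores 0.093 — above the classical
0.05 threshold, i.e. predicted aggregation-prone — while the short
isoform (hnRNPA1-A, 320 aa), which lacks 52 residues of the C-terminal
low-complexity region, scores 0.042, just below it: alternative splicing
alone moves this protein across the aggregation threshold. The called
domain (residues 175 onward) is the glycine-rich C-terminal PrLD. A
per-position profile with the disordered (scored) segments is available
via `position_scores()` and `plot()`:

```r
prof <- position_scores(fa$sequence[1], accession = "P09651-1")
prof
#> <papa_profile> P09651-1 (372 aa)
#>   protein score: 0.093162
#>   332 anchored positions, 280 gated (FoldIndex < 0)
plot(prof)
```

## Command line

A thin Rscript CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","prionscan.R",package="prionscan"))')" \
  score --fasta proteome.fasta --out-dir results/
```

Subcommands: `score`, `prlds`, `variants`, `isoforms`, `mutations`,
`ptm`, `fixtures`. Every output TSV begins with a `#`-commented manifest
recording the thresholds, window size and propensity-table checksum in
force.

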