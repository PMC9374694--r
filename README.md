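# bepiscan

Sequence-similarity prediction of **linear B cell epitopes**: the antigen
fragments (typically 8–25 residues) that antibodies recognize as contiguous
peptides, and that can replace the whole protein for antibody production and
serodiagnostics.

Instead of training a model on epitope features, `bepiscan` leans on the
size of curated epitope collections: a query peptide is called a B cell
epitope when an exhaustive **ungapped alignment search** against a database
of experimentally verified epitope peptides yields a hit with

- length ≥ 8 residues, and
- identity ≥ 80%,

where identity is computed over the hit length. For protein queries, all
qualifying hits are tallied per residue into a coverage count *B* (residues
in no hit have *B* = 0), standardized into z-scores

```
Z_B = (B − μ_B) / σ_B
```

(μ_B, σ_B: mean and population standard deviation of *B* over all residues
of the protein), and reported as non-overlapping **epitope cores** of ≥ 8
residues whose Z_B is at least that of the flanking residues. Cores carry
BLOSUM62 bit scores (Karlin–Altschul conversion, ungapped constants
λ = 0.3176, K = 0.134), support from neutralizing-antibody epitopes, and
averaged per-residue accessibility/flexibility when external tracks are
supplied.

The package also ships everything needed to *evaluate* the approach: dataset
curation (8–25 length filter, greedy 90%-identity redundancy reduction,
composition and length statistics), a synthetic benchmark generator
(Swiss-Prot background composition, epitope-like length profile), k-fold
cross-validation and independent-test evaluation with SE/SP/ACC/MCC, plus a
command-line front end (`inst/scripts/bepiscan.R`).

## Worked example

```r
library(bepiscan)

db <- EpitopeSet(
  c(flu_HA_1 = "WLPKKYIVWQACD",
    flu_HA_2 = "MKTAYIAKQRQIS",
    rsv_F_1  = "NSELLSLINDMPITNDQKKLMSNN"),
  neutralizing = c(TRUE, FALSE, FALSE), label = "positive")

## peptide mode: 13-mer variant of flu_HA_2 with 2 substitutions
classifyPeptide("WKTAYIAKQRQIW", db)
#> Prediction for 'query': epitope (1 qualifying hit(s))
#>   query_start query_end subject_id ... length identity_pct raw_score bit_score
#> 1           1        13   flu_HA_2 ...     13     84.61538        49  25.35149
```

The variant still qualifies: 11/13 identical positions = 84.6% ≥ 80% over a
13-residue ungapped hit. A 7-mer can never qualify, whatever the database.

```r
## protein mode: scan an antigen carrying the flu_HA_1 epitope
prot <- paste0(strrep("G", 12), "WLPKKYIVWQACD", strrep("S", 12))
sc <- scanProtein(c(myAntigen = prot), db)
sc$cores
#>   start end       peptide bit_score accessibility flexibility neutralizing_support n_hits
#> 1    13  25 WLPKKYIVWQACD  40.47209            NA          NA                 TRUE      1
```

The planted epitope is recovered as one core at its exact coordinates
(1-based inclusive), flagged as supported by a neutralizing-antibody epitope.

```r
## evaluation on a synthetic benchmark: database of 20 random peptides,
## 200 exact-copy positives, 200 composition/length-matched random negatives
sim <- simulateBenchmark(nPos = 200, nNeg = 200, mismatchFrac = 0,
                         seed = 1, nParents = 20)
cv <- tenfoldCV(sim$positives, sim$negatives, k = 10, seed = 1)
cv
#> 10-fold cross-validation (seed 1)
#>   %SE  100.00 ± 0.00
#>   %SP  100.00 ± 0.00
#>   %ACC  100.00 ± 0.00
#>   MCC  1.00 ± 0.00
```

Exact-copy positives are always re-found in the database built from the
other nine folds (perfect sensitivity); unrelated random peptides almost
never share an ≥ 8-residue window at ≥ 80% identity with a short-peptide
database (specificity ≥ 99%). Real epitope collections are much harder —
held-out epitopes are not near-duplicates of database entries — which is the
regime the evaluation harness is built to measure; see the methods vignette
(`vignettes/bepiscan-methods.Rmd`) for what the synthetic benchmark does and
does not demonstrate.

## Command-line use

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "bepiscan.R", package = "bepiscan"))')
Rscript "$CLI" makedb   --fasta epitopes.fasta --out bundle --reduce-redundancy 90
Rscript "$CLI" scan     --db bundle/db.fasta --query antigen.fasta --out scanout
Rscript "$CLI" evaluate --positives pos.fasta --negatives neg.fasta \
                        --folds 10 --seed 42 --out evalout
```

Subcommands: `makedb`, `stats`, `classify`, `scan`, `evaluate`, `holdout`,
`simulate`, `similarity`. Every run writes a machine-readable copy of its
resolved configuration next to its outputs.
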