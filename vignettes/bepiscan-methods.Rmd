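---
title: "Predicting linear B cell epitopes by sequence similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting linear B cell epitopes by sequence similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepiscan)
```

## The method

Linear (continuous) B cell epitopes are short antigen fragments — typically
8–25 residues — that antibodies can recognize outside the context of the
folded protein, which makes them directly useful as synthetic peptides for
antibody production and serological assays. Rather than training a model on
features of known epitopes, `bepiscan` exploits the sheer size of curated
epitope collections directly: a query is called a B cell epitope when it is
*sequence-similar to a known epitope*, operationalized as an **ungapped
alignment hit of length ≥ 8 residues and identity ≥ 80%** against a database
of experimentally verified linear epitope peptides.

Two prediction surfaces share that decision rule:

* **Peptide mode** (`classifyPeptide()`, `classifyPeptides()`): the query is
  an epitope iff at least one qualifying hit exists.
* **Protein mode** (`scanProtein()`): all qualifying hits over the protein
  are collected; the number of hits covering each residue is tallied into
  `B` (residues in no hit have `B = 0`) and standardized into

  $$ Z_B = \frac{B - \mu_B}{\sigma_B}, $$

  where $\mu_B$ and $\sigma_B$ are the mean and *population* standard
  deviation of `B` over **all** residues of the query protein. Because
  overlapping hits are common, reporting is simplified to **epitope
  cores**: non-overlapping segments of ≥ 8 residues whose $Z_B$ values are
  at least those of the immediately flanking residues.

## The search engine

Hits are found by an exhaustive diagonal scan (implemented in C++): every
database peptide is slid along every diagonal of the query and *all* ungapped
windows with length ≥ `minLength` and identity ≥ `minIdentity` are
enumerated; windows contained in a longer qualifying window on the same
diagonal are suppressed as non-maximal. This is deterministic and strictly
exhaustive — word-seeded heuristic search engines find a subset of these
windows — and with database peptides of at most 25 residues it is fast
enough for cross-validation at the tens-of-thousands-of-peptides scale.

Each hit is scored by its BLOSUM62 raw sum and converted to bits with the
Karlin–Altschul rescaling $(\lambda s - \ln K)/\ln 2$. The defaults
$\lambda = 0.3176$, $K = 0.134$ are the standard ungapped-BLOSUM62
constants; since the decision rule depends only on length and identity, the
bit score ranks hits but never changes a verdict. `perSubjectBestOnly`
(default `TRUE`) keeps one best hit per database record — ties broken by
longest hit, then smallest query start — so the residue tally `B`
approximates "number of distinct known epitopes supporting this residue"
rather than over-weighting a single subject with many overlapping windows.

### Identity conventions

Three procedures use three (deliberately distinct, each pinned) identity
denominators:

| context | denominator |
|---|---|
| ungapped hits | hit length (both segments equal length) |
| redundancy reduction | length of the shorter sequence (CD-HIT convention) |
| dataset similarity | full global-alignment length (needle convention) |

Global alignments are Needleman–Wunsch with affine gaps under BLOSUM62,
using the EMBOSS-needle default penalties (open 10, extend 0.5); a gap of
length $k$ costs $10 + 0.5k$. The implementation delegates to
`Biostrings::pairwiseAlignment()`; its optimal score is cross-checked in the
test suite against an independent dynamic-programming oracle. Traceback
tie-breaking among co-optimal alignments is the library's own; scores and
identity-from-alignment are what the package guarantees.

## Dataset curation

`readEpitopeFasta()` parses FASTA with an optional `neutralizing=true|false`
key in the description line and an optional sibling `<stem>.meta.tsv`
(columns `id`, `source`, `neutralizing`). Records containing letters outside
the 20 standard amino acids (B, J, O, U, X, Z) are dropped at load with a
warning: BLOSUM62 scoring and composition statistics are defined on the
20-letter alphabet, and silent recoding would distort both.

`filterByLength()` (default 8–25) and `reduceRedundancy()` (default
threshold 90%) implement the curation rules applied to epitope collections.
Redundancy reduction is greedy longest-first clustering: a record is kept
iff its identity (matches over the shorter length) to every already-kept
record is **below** the threshold, so a pair at exactly 90% is collapsed.
This reproduces CD-HIT's clustering logic with exact alignments instead of
CD-HIT's word-filter heuristics; the test suite verifies by brute force that
no kept pair reaches the threshold. Exact cluster membership can differ from
a CD-HIT run on the same input (tie handling and the word filter are not
emulated), which matters only if one tries to reconstruct a specific
published dataset byte-for-byte.

Statistics reported by `lengthStats()` use the population standard
deviation (divide by $N$) and the mid-mean median for even counts; the "±"
in all summaries is likewise a population standard deviation. These
conventions are stated because published dataset summaries rarely define
them and reproductions need a fixed choice.

## The synthetic benchmark

`simulateBenchmark()` builds the three datasets a full evaluation needs,
without any external downloads:

* a **parent database** of random peptides drawn from the Swiss-Prot
  background composition (`swissprotComposition()`, shipped as a
  configuration table) with lengths from `defaultLengthDistribution()` — a
  two-component lognormal mixture over 8–25 residues (70% of mass near 12,
  30% near 18) chosen to emulate the right-skewed length profile of curated
  epitope collections (mean ≈ 13.9, median 12);
* **positives**: `makeFixturePositives()` copies of random parent records
  with at most `floor(mismatchFrac × length)` substitutions — emulating
  held-out epitopes that are close variants of database entries;
* **negatives**: fresh random peptides with the same composition and length
  profile, redundancy-reduced at 90% like real negative sets.

What the generator emulates: the length range and skew, the background
residue usage, near-duplicate structure between positives and the database,
and the mutual non-redundancy of negatives. What it does **not** emulate:
the biased amino-acid composition of real epitopes (enrichment of W/P/H over
the proteome background), phylogenetic correlation between epitopes of
related antigens, and the ambiguity of real "negative" assay data. Passing
the synthetic benchmark therefore demonstrates that the machinery is
correct — exact recall of planted relatives, near-perfect rejection of
unrelated peptides — not that real-data accuracy will reach any particular
value; on published collections the same pipeline yields accuracies in the
70–80% range precisely because real positives are *not* all near-duplicates
of database entries.

With `mismatchFrac = 0` every positive is an exact copy of a parent, so
cross-validated sensitivity is 100% except in the measure-zero event that
every copy of some parent lands in a single test fold (with the default ~10
copies per parent this is vanishingly rare, and it does not occur at the
seeds the tests fix). Specificity against 8–25-mer random negatives is
≥ 99%: an unrelated peptide pair almost never shares an ≥ 8-residue window
at ≥ 80% identity, but with thousands of queries the occasional chance hit
does occur.

## Evaluation protocol

`tenfoldCV()` partitions positives and negatives independently into `k`
near-equal folds by a seeded uniform shuffle with round-robin slicing. In
round $r$ the database is built from the positives of the other $k-1$ folds
— negatives never enter the database — and the held-out positives (label 1)
and negatives (label 0) are classified against it. Sensitivity, specificity,
accuracy and the Matthews correlation coefficient follow the standard
definitions; MCC with a zero marginal is reported as `NaN` with a warning
rather than silently zeroed, so degenerate folds are visible. The summary is
mean ± population standard deviation across folds. The fold seed is a
required, logged argument: no split procedure or seed is canonical, and the
fold-to-fold standard deviation is the right yardstick for comparing runs
with different seeds.

Note one structural property the tests pin: per-fold sensitivity depends
only on the positives and the seed, never on which negative set accompanies
them, because negatives affect neither the database nor the positive folds.

## Core extraction

The published description of core extraction — segments of ≥ 8 residues
with $Z_B$ at least the flanking residues — underdetermines tie and plateau
handling, so the package fixes one deterministic operationalization:
within each maximal run of `B > 0`, seed at the leftmost maximum-$Z_B$
residue, extend outward while the next residue stays in the run and its
$Z_B$ does not exceed the current boundary's (non-increasing descent),
accept if ≥ `minCoreLen`, then recurse on the run remainders left and right
of the segment. This guarantees non-overlap, the length floor, and — on
plateau-shaped runs, which is what isolated or fully-overlapping hits
produce — the flanking-$Z_B$ condition. On staircase-shaped runs (partially
overlapping hits of different multiplicity) adjacent cores can abut, and the
residue flanking a core may belong to a higher neighbouring step; the
per-run recursion still reports each step at most once. Degenerate case:
if `B` is uniform over the whole protein, $\sigma_B = 0$ and $Z_B$ is
defined as identically zero; cores are then the maximal covered runs of
length ≥ 8.

Per-core annotations: `bit_score` is the **maximum** over supporting hits
(the strongest database match, not a sum — overlapping hit counts should not
inflate the score); `neutralizing_support` is true iff any supporting hit is
to a neutralizing-flagged record; accessibility and flexibility are
arithmetic means of user-supplied per-residue tracks over the core residues.
The package deliberately does not predict accessibility or flexibility
itself — those come from external structure-based predictors as two-column
TSV tracks.

## Numerical choices

* Identity thresholds compare as `matches × 100 ≥ threshold × length` with a
  `1e-9` slack, so exact boundary hits (e.g. 8/10 = 80%) qualify under a
  "≥" contract without floating-point surprises.
* MCC is computed in double precision; the product of marginals overflows
  32-bit integers already near $n = 500$ per class.
* All coordinates in reports are 1-based inclusive.
* Random generation (`randomPeptides()`, `makeFixturePositives()`, fold
  assignment, pair subsampling) runs under an isolated seeded RNG that
  restores the caller's RNG state, so results are reproducible given a seed
  and library calls do not perturb user scripts.

## Problem sizes used in the shipped checks

The packaged test-suite and the acceptance script validate at desk scale,
chosen so the full suite runs in a couple of minutes on one core: search
oracle equivalence on 200 random query/database instances (query ≤ 60
residues, ≤ 30 database peptides), 50 seeded planted-epitope protein scans,
and a 2,000 + 2,000 peptide synthetic benchmark under tenfold
cross-validation. The published-scale reproductions (62,730-epitope
collection statistics, cross-validated accuracy against assay-negative and
random-peptide sets, and the 503-epitope independent test) are implemented
as the same pipeline and activate when the journal supplementary FASTA
files are placed under `inst/extdata/supplementary/`; they are far too large
to ship with the package.

## Known limitations

* Gapped hit search is not supported (`allowGaps` must be `FALSE`); the
  validated operating point is ungapped, and gapped scoring would need its
  own Karlin–Altschul parameters.
* The exhaustive engine can find strictly more hits than a heuristic
  word-seeded search run at "default settings"; reproductions of published
  hit sets can therefore differ marginally in the conservative direction
  (more hits, never fewer).
* E-values and composition-based score adjustment are out of scope; the
  decision rule uses identity and length only.
* The classifier has no tunable score threshold: its operating point moves
  only via `minIdentity`/`minLength`.
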