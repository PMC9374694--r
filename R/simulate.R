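# run expr under a fixed RNG seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Epitope-like peptide length distribution
#'
#' The default length distribution used by the synthetic generators: a
#' two-component lognormal mixture over integer lengths 8-25, emulating the
#' right-skewed length profile of curated linear B cell epitope collections
#' (most peptides 10-15 residues with a secondary mode near 18; mean about
#' 13.9 residues, median 12).
#'
#' @return named probability vector over lengths 8..25, summing to 1.
#' @export
defaultLengthDistribution <- function() {
  l <- 8:25
  p <- 0.70 * stats::dlnorm(l, log(11.8), 0.10) +
       0.30 * stats::dlnorm(l, log(18.5), 0.12)
  setNames(p / sum(p), l)
}

#' Generate random peptides from a background composition
#'
#' Each peptide's length is drawn from \code{lengths} and its residues are
#' drawn i.i.d. from \code{background} — the construction used for the
#' random-peptide negative datasets (Swiss-Prot composition, length
#' distribution matched to known epitopes). Deterministic given \code{seed}.
#' Callers building a negative dataset should follow with
#' \code{\link{reduceRedundancy}}.
#'
#' @param n number of peptides.
#' @param background named 20-entry residue frequency vector (default
#'   \code{\link{swissprotComposition}()}).
#' @param lengths named probability vector over integer lengths (default
#'   \code{\link{defaultLengthDistribution}()}).
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return an \code{\link{EpitopeSet}} labelled \code{"negative"}.
#' @export
randomPeptides <- function(n, background = swissprotComposition(),
                           lengths = defaultLengthDistribution(),
                           seed = 1L, prefix = "rnd") {
  stopifnot(n >= 1)
  background <- background / sum(background)
  lens_vals <- as.integer(names(lengths))
  .withSeed(seed, {
    lens <- sample(lens_vals, n, replace = TRUE, prob = lengths)
    seqs <- vapply(lens, function(L)
      paste(sample(names(background), L, replace = TRUE, prob = background),
            collapse = ""), character(1))
  })
  EpitopeSet(seqs, ids = sprintf("%s%05d", prefix, seq_len(n)),
             label = "negative",
             provenance = sprintf("random peptides, seed %d", seed))
}

#' Generate near-duplicate positives from a database
#'
#' Test-fixture generator emulating held-out epitopes that are close variants
#' of database entries: each output peptide copies a random database record
#' and applies at most \code{floor(maxMismatchFrac * length)} substitutions
#' at random positions (substituted residues always differ from the
#' original). Records carry the parent id in their \code{source} column.
#'
#' @param db an \code{\link{EpitopeSet}} (non-empty).
#' @param n number of peptides to generate.
#' @param maxMismatchFrac maximum substituted fraction, in [0, 0.2).
#' @param seed integer seed.
#' @return an \code{\link{EpitopeSet}} labelled \code{"positive"}.
#' @export
makeFixturePositives <- function(db, n, maxMismatchFrac = 0, seed = 1L) {
  stopifnot(is(db, "EpitopeSet"), length(db) > 0,
            maxMismatchFrac >= 0, maxMismatchFrac < 0.2)
  seqs <- as.character(db)
  .withSeed(seed, {
    parent <- sample(length(db), n, replace = TRUE)
    out <- vapply(parent, function(j) {
      s <- strsplit(seqs[j], "")[[1]]
      k <- floor(maxMismatchFrac * length(s))
      if (k > 0) {
        pos <- sample(length(s), k)
        for (p in pos)
          s[p] <- sample(setdiff(AA_ALPHABET20, s[p]), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
  })
  EpitopeSet(out, ids = sprintf("fix%05d", seq_len(n)),
             source = names(db)[parent], label = "positive",
             provenance = sprintf(
               "near-duplicates of %d db records, mismatch frac %.2f, seed %d",
               length(db), maxMismatchFrac, seed))
}

#' Build a complete synthetic benchmark
#'
#' Generates the three datasets needed for a full evaluation run: a synthetic
#' epitope database of random peptides (the "known epitope" pool), a positive
#' set of near-duplicates of those database records, and a composition- and
#' length-matched random negative set. Negatives are redundancy-reduced at
#' 90% identity, mirroring the curation applied to real negative datasets.
#' Deterministic given \code{seed}.
#'
#' @param nPos,nNeg positive and negative set sizes (>= 10).
#' @param mismatchFrac maximum substituted fraction for positives.
#' @param seed integer seed.
#' @param nParents size of the synthetic parent database (default
#'   \code{max(50, nPos \%/\% 10)}, so each parent has ~10 positive copies).
#' @param reduceNegatives apply \code{\link{reduceRedundancy}} to negatives.
#' @param outDir if given, the three datasets are also written there as
#'   FASTA + metadata bundles.
#' @return list with \code{db}, \code{positives}, \code{negatives}.
#' @export
simulateBenchmark <- function(nPos, nNeg, mismatchFrac = 0, seed = 1L,
                              nParents = max(50L, nPos %/% 10L),
                              reduceNegatives = TRUE, outDir = NULL) {
  stopifnot(nPos >= 10, nNeg >= 10)
  comp <- swissprotComposition()
  lens <- defaultLengthDistribution()
  db <- randomPeptides(nParents, comp, lens, seed = seed, prefix = "db")
  db@label <- "positive"
  positives <- makeFixturePositives(db, nPos, mismatchFrac, seed = seed + 1L)
  negatives <- randomPeptides(nNeg, comp, lens, seed = seed + 2L,
                              prefix = "neg")
  if (reduceNegatives)
    negatives <- reduceRedundancy(negatives, 90, quiet = TRUE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeEpitopeFasta(db, file.path(outDir, "db.fasta"))
    writeEpitopeFasta(positives, file.path(outDir, "positives.fasta"))
    writeEpitopeFasta(negatives, file.path(outDir, "negatives.fasta"))
  }
  list(db = db, positives = positives, negatives = negatives)
}
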