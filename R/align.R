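#' Needleman-Wunsch global alignment of two peptides
#'
#' Optimal global alignment with affine gap penalties under BLOSUM62, using
#' the EMBOSS-needle default penalties (gap open 10, gap extension 0.5).
#' Identity is computed over the full alignment length, gap positions
#' included (the needle convention).
#'
#' @param a,b amino-acid sequences (character or AAString), non-empty.
#' @param gapOpen,gapExtend affine gap penalties.
#' @param matrix substitution matrix (default \code{\link{blosum62}()}).
#' @return list of class \code{"GlobalAlignment"} with \code{alignedA},
#'   \code{alignedB} (gapped strings of equal length), \code{identityPct},
#'   \code{matches}, \code{alignmentLength} and \code{score}.
#' @examples
#' globalAlign("HEAGAWGHEE", "PAWHEAE")$score
#' @export
globalAlign <- function(a, b, gapOpen = 10, gapExtend = 0.5,
                        matrix = blosum62()) {
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  aln <- pairwiseAlignment(a, b, type = "global",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
  pa <- as.character(alignedPattern(aln))
  pb <- as.character(alignedSubject(aln))
  structure(list(alignedA = unname(pa), alignedB = unname(pb),
                 identityPct = pid(aln, type = "PID1"),
                 matches = nmatch(aln), alignmentLength = nchar(pa),
                 score = Biostrings::score(aln)),
            class = "GlobalAlignment")
}

#' @export
print.GlobalAlignment <- function(x, ...) {
  cat(x$alignedA, "\n", x$alignedB, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.2f%% (%d/%d)\n", x$score,
              x$identityPct, x$matches, x$alignmentLength))
  invisible(x)
}

#' Mean pairwise sequence identity within or between datasets
#'
#' Within-dataset mode (\code{b = NULL}): identity is collected over all
#' ordered pairs (i, j), i != j — N x (N - 1) alignments for N sequences —
#' and summarized as mean and population standard deviation. Since identity
#' is symmetric, each unordered pair is aligned once and counted twice.
#' Cross-dataset mode: all pairs with one sequence from each set. Identity is
#' percent identical positions over the full global-alignment length.
#'
#' For large datasets an exhaustive all-vs-all run is quadratic; set
#' \code{maxPairs} to estimate the mean from a seeded random subsample of
#' pairs instead.
#'
#' @param a an \code{\link{EpitopeSet}}.
#' @param b optional second \code{EpitopeSet} for cross-dataset mode.
#' @param maxPairs subsample cap on the number of (unordered or cross) pairs
#'   aligned; \code{Inf} for exhaustive.
#' @param seed seed for the pair subsample.
#' @return list with \code{meanPct}, \code{sdPct} and \code{nPairs} (pairs
#'   actually aligned).
#' @export
meanPairwiseIdentity <- function(a, b = NULL, maxPairs = Inf, seed = 1L) {
  stopifnot(is(a, "EpitopeSet"), length(a) > 0)
  within <- is.null(b)
  if (within && length(a) < 2L)
    stop("within-dataset mode needs at least 2 sequences")
  if (within) {
    pairs <- t(utils::combn(length(a), 2L))
  } else {
    stopifnot(is(b, "EpitopeSet"), length(b) > 0)
    pairs <- as.matrix(expand.grid(i = seq_along(a), j = seq_along(b)))
  }
  if (nrow(pairs) > maxPairs)
    pairs <- .withSeed(seed,
                       pairs[sample(nrow(pairs), maxPairs), , drop = FALSE])
  sa <- as.character(a)
  sb <- if (within) sa else as.character(b)
  ids <- numeric(nrow(pairs))
  # group by second member so each pairwiseAlignment call is vectorized
  for (j in unique(pairs[, 2L])) {
    sel <- pairs[, 2L] == j
    aln <- pairwiseAlignment(sa[pairs[sel, 1L]], sb[j],
                             substitutionMatrix = blosum62(),
                             gapOpening = 10, gapExtension = 0.5)
    ids[sel] <- pid(aln, type = "PID1")
  }
  m <- mean(ids)
  list(meanPct = m, sdPct = sqrt(mean((ids - m)^2)), nPairs = nrow(pairs))
}

#' Convert a raw alignment score to a bit score
#'
#' Karlin-Altschul rescaling \code{(lambda * raw - ln K) / ln 2} with the
#' constants carried in \code{params} (defaults: the standard ungapped
#' BLOSUM62 values lambda = 0.3176, K = 0.134).
#'
#' @param rawScore summed substitution score of the hit.
#' @param params a \code{\link{SearchParams}} object.
#' @return bit score (bits).
#' @export
bitScore <- function(rawScore, params = SearchParams()) {
  stopifnot(is(params, "SearchParams"))
  (params@lambda * rawScore - log(params@K)) / log(2)
}
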