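#' Exhaustive ungapped hit search of a query against an epitope database
#'
#' Slides every database peptide along every diagonal of the query and
#' enumerates all ungapped windows of length >= \code{minLength} with
#' identity >= \code{minIdentity} percent. Only maximal windows are reported
#' (a qualifying window contained in a longer qualifying window on the same
#' diagonal is suppressed). With \code{perSubjectBestOnly} (the default) each
#' database subject contributes only its highest-raw-score hit (ties: longest
#' hit, then smallest query start). Unlike heuristic word-seeded search, the
#' scan is exhaustive: every qualifying window is found.
#'
#' Raw scores are BLOSUM62 sums over the hit; bit scores apply the
#' Karlin-Altschul conversion of \code{\link{bitScore}}. Coordinates are
#' 1-based inclusive.
#'
#' @param query amino-acid sequence (character or AAString).
#' @param db an \code{\link{EpitopeSet}} (non-empty).
#' @param params a \code{\link{SearchParams}} object.
#' @return data.frame with one row per hit, sorted by \code{query_start}
#'   then descending \code{bit_score}: \code{query_start}, \code{query_end},
#'   \code{subject_id}, \code{subject_start}, \code{subject_end},
#'   \code{length}, \code{identity_pct}, \code{raw_score}, \code{bit_score},
#'   \code{neutralizing}.
#' @examples
#' db <- EpitopeSet(c(e1 = "MKTAYIAK"))
#' findUngappedHits("MKTAYIAKQRQISFVK", db)
#' @export
findUngappedHits <- function(query, db, params = SearchParams()) {
  stopifnot(is(db, "EpitopeSet"), length(db) > 0,
            is(params, "SearchParams"))
  validObject(params)
  q <- .encodeSeqs(as.character(query))[[1]]
  subj <- .encodeSeqs(db)
  raw <- cpp_ungapped_hits(q, subj, params@minLength, params@minIdentity,
                           params@perSubjectBestOnly, blosum62())
  hits <- data.frame(
    query_start = raw$query_start,
    query_end = raw$query_end,
    subject_id = names(db)[raw$subject],
    subject_start = raw$subject_start,
    subject_end = raw$subject_end,
    length = raw$length,
    identity_pct = 100 * raw$matches / raw$length,
    raw_score = raw$raw_score,
    bit_score = bitScore(raw$raw_score, params),
    neutralizing = unname(neutralizing(db)[raw$subject]),
    stringsAsFactors = FALSE)
  hits[order(hits$query_start, -hits$bit_score), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Classify a peptide as epitope or non-epitope
#'
#' The core decision rule: a peptide is called an epitope when the ungapped
#' search against the database of known epitopes yields at least one
#' qualifying hit (by default length >= 8 and identity >= 80%).
#'
#' @param peptide amino-acid sequence.
#' @param db an \code{\link{EpitopeSet}} of known epitopes.
#' @param params a \code{\link{SearchParams}} object.
#' @param withHits attach the full hit table (set \code{FALSE} to use the
#'   early-exit existence test only).
#' @return list of class \code{"Prediction"} with \code{id}, \code{verdict}
#'   (\code{"epitope"} or \code{"non-epitope"}) and \code{hits} (a hit table,
#'   or \code{NULL} when \code{withHits = FALSE}).
#' @export
classifyPeptide <- function(peptide, db, params = SearchParams(),
                            withHits = TRUE) {
  id <- if (!is.null(names(peptide))) names(peptide)[1] else "query"
  if (withHits) {
    hits <- findUngappedHits(peptide, db, params)
    verdict <- if (nrow(hits) > 0) "epitope" else "non-epitope"
  } else {
    q <- .encodeSeqs(as.character(peptide))[[1]]
    verdict <- if (cpp_any_hit(q, .encodeSeqs(db), params@minLength,
                               params@minIdentity)) "epitope" else "non-epitope"
    hits <- NULL
  }
  structure(list(id = id, verdict = verdict, hits = hits),
            class = "Prediction")
}

#' @export
print.Prediction <- function(x, ...) {
  cat(sprintf("Prediction for '%s': %s", x$id, x$verdict))
  if (!is.null(x$hits)) cat(sprintf(" (%d qualifying hit(s))", nrow(x$hits)))
  if (!is.null(x$cores))
    cat(sprintf(" — %d epitope core(s)", nrow(x$cores)))
  cat("\n")
  invisible(x)
}

#' Batch epitope/non-epitope verdicts for a peptide set
#'
#' Early-exit existence search for every peptide of a dataset; equivalent to
#' \code{\link{classifyPeptide}} on each record but far faster for
#' cross-validation scale runs.
#'
#' @param x an \code{\link{EpitopeSet}} of query peptides.
#' @param db an \code{\link{EpitopeSet}} of known epitopes.
#' @param params a \code{\link{SearchParams}} object.
#' @return named logical vector, \code{TRUE} = epitope.
#' @export
classifyPeptides <- function(x, db, params = SearchParams()) {
  stopifnot(is(x, "EpitopeSet"), is(db, "EpitopeSet"), length(db) > 0)
  v <- cpp_classify_batch(.encodeSeqs(x), .encodeSeqs(db),
                          params@minLength, params@minIdentity)
  setNames(v, names(x))
}
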