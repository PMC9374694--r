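#' Filter an epitope dataset by sequence length
#'
#' Retains records whose length lies in \code{[minLen, maxLen]} (inclusive),
#' preserving input order. The method's validated operating range is 8-25
#' residues.
#'
#' @param x an \code{\link{EpitopeSet}}.
#' @param minLen,maxLen inclusive length bounds, residues.
#' @param quiet suppress the removal-count message.
#' @return the filtered \code{EpitopeSet}.
#' @export
filterByLength <- function(x, minLen = 8L, maxLen = 25L, quiet = FALSE) {
  stopifnot(is(x, "EpitopeSet"), minLen >= 1L, maxLen >= minLen)
  keep <- width(x) >= minLen & width(x) <= maxLen
  if (!quiet && any(!keep))
    message(sum(!keep), " record(s) outside length range [", minLen, ", ",
            maxLen, "] removed")
  x[keep]
}

# identity for redundancy reduction: matched positions in the global affine
# alignment, over the length of the SHORTER sequence (CD-HIT's convention)
.identity_vs_shorter <- function(candidate, kept_set) {
  aln <- pairwiseAlignment(kept_set, candidate,
                           substitutionMatrix = blosum62(),
                           gapOpening = 10, gapExtension = 0.5)
  100 * nmatch(aln) / pmin(nchar(candidate), width(kept_set))
}

#' Greedy redundancy reduction of a peptide dataset
#'
#' Emulates CD-HIT style clustering: records are visited longest-first (ties
#' broken by input order) and a record is kept only if its identity to every
#' already-kept record is below \code{maxIdentityPct}. Identity is the number
#' of matched positions in the Needleman-Wunsch global alignment divided by
#' the length of the shorter sequence, times 100. After reduction no kept
#' pair shares \code{>= maxIdentityPct} identity.
#'
#' @param x an \code{\link{EpitopeSet}}.
#' @param maxIdentityPct records at or above this identity to a kept record
#'   are discarded (default 90).
#' @param quiet suppress the removal-count message.
#' @return the reduced \code{EpitopeSet}, in original input order.
#' @export
reduceRedundancy <- function(x, maxIdentityPct = 90, quiet = FALSE) {
  stopifnot(is(x, "EpitopeSet"))
  n <- length(x)
  if (n <= 1L) return(x)
  ord <- order(-width(x), seq_len(n))  # longest first, ties by input order
  seqs <- as.character(x)
  kept_idx <- integer(0)
  kept_seqs <- character(0)
  for (i in ord) {
    cand <- seqs[i]
    if (length(kept_idx)) {
      # exact-duplicate shortcut, then full alignment against kept records
      if (cand %in% kept_seqs) next
      idents <- .identity_vs_shorter(cand, AAStringSet(kept_seqs))
      if (any(idents >= maxIdentityPct - 1e-9)) next
    }
    kept_idx <- c(kept_idx, i)
    kept_seqs <- c(kept_seqs, cand)
  }
  if (!quiet && length(kept_idx) < n)
    message(n - length(kept_idx), " redundant record(s) discarded at >= ",
            maxIdentityPct, "% identity")
  x[sort(kept_idx)]
}
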