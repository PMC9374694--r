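# recursive seeded plateau descent within one run of B > 0.
# [lo, hi] are 1-based residue bounds; returns rows of accepted segments.
.descendRun <- function(ZB, lo, hi, minLen) {
  if (hi - lo + 1L < minLen) return(NULL)
  seed <- lo - 1L + which.max(ZB[lo:hi])  # leftmost maximum
  L <- seed; R <- seed
  while (L - 1L >= lo && ZB[L - 1L] <= ZB[L]) L <- L - 1L
  while (R + 1L <= hi && ZB[R + 1L] <= ZB[R]) R <- R + 1L
  out <- NULL
  if (R - L + 1L >= minLen) out <- rbind(out, c(L, R))
  rbind(out,
        .descendRun(ZB, lo, L - 1L, minLen),
        .descendRun(ZB, R + 1L, hi, minLen))
}

#' Extract non-overlapping epitope cores from a residue profile
#'
#' Operates on maximal runs of residues with hit tally \code{B > 0}. Within
#' each run the segment is seeded at the leftmost maximum-\code{Z_B} residue
#' and extended outward while the next residue stays inside the run and its
#' \code{Z_B} does not exceed the current boundary residue's (non-increasing
#' descent from the peak). The segment is accepted when it spans at least
#' \code{minCoreLen} residues; the procedure then recurses on the remainders
#' of the run to the left and right of the segment. Accepted cores never
#' overlap, every core residue has \code{B > 0}, and on plateau-shaped runs
#' every core residue's \code{Z_B} is at least that of both residues
#' immediately flanking the core (sequence ends count as satisfied).
#'
#' @param profile a \code{\link{ResidueProfile}}.
#' @param minCoreLen minimum core length, residues (default 8).
#' @return data.frame ordered by \code{start}: \code{start}, \code{end}
#'   (1-based inclusive), \code{peptide}.
#' @export
extractCores <- function(profile, minCoreLen = 8L) {
  stopifnot(is(profile, "ResidueProfile"), minCoreLen >= 1L)
  B <- profile@B
  ZB <- profile@ZB
  segs <- NULL
  r <- rle(B > 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values))
    segs <- rbind(segs, .descendRun(ZB, starts[k], ends[k],
                                    as.integer(minCoreLen)))
  if (is.null(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  data.frame(start = segs[, 1L], end = segs[, 2L],
             peptide = substring(profile@sequence, segs[, 1L], segs[, 2L]),
             stringsAsFactors = FALSE)
}
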