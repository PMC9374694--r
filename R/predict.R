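#' Per-residue hit tally and z-score profile of a protein query
#'
#' Tallies, for each residue of the protein, the number of qualifying
#' ungapped hits whose query interval covers it (\code{B}; residues in no hit
#' get \code{B = 0}), then normalizes to z-scores
#' \code{Z_B = (B - mu_B) / sd_B}, where \code{mu_B} and \code{sd_B} are the
#' mean and population standard deviation of \code{B} over all residues of
#' the protein. Under uniform coverage (\code{sd_B = 0}) the z-score is
#' defined as zero everywhere.
#'
#' @param protein amino-acid sequence (character or AAString), optionally
#'   named.
#' @param hits hit table from \code{\link{findUngappedHits}} run on
#'   \code{protein}.
#' @param id protein identifier (defaults to the name of \code{protein}).
#' @return a \code{\link{ResidueProfile}}.
#' @export
residueProfile <- function(protein, hits, id = NULL) {
  seq <- as.character(protein)
  if (is.null(id))
    id <- if (!is.null(names(protein))) names(protein)[1] else "query"
  n <- nchar(seq)
  if (nrow(hits) > 0 &&
      (any(hits$query_start < 1L) || any(hits$query_end > n)))
    stop("hit coordinates outside protein bounds")
  B <- integer(n)
  for (k in seq_len(nrow(hits))) {
    idx <- hits$query_start[k]:hits$query_end[k]
    B[idx] <- B[idx] + 1L
  }
  mu <- mean(B)
  sdev <- sqrt(mean((B - mu)^2))
  Z <- if (sdev > 0) (B - mu) / sdev else numeric(n)
  new("ResidueProfile", proteinId = id, sequence = seq, B = B, ZB = Z,
      muB = mu, sdB = sdev)
}

#' Scan a protein for linear B cell epitope cores
#'
#' The full protein-mode pipeline: exhaustive ungapped hit search against the
#' epitope database, optional restriction to hits on neutralizing-antibody
#' epitopes, per-residue tally and z-score profile
#' (\code{\link{residueProfile}}), and extraction of non-overlapping epitope
#' cores of >= 8 residues (\code{\link{extractCores}}). When per-residue
#' accessibility or flexibility tracks are supplied (one value per protein
#' residue, e.g. from an external structure-based predictor), each core is
#' annotated with the arithmetic mean of the track over its residues.
#'
#' @param protein amino-acid sequence, optionally named.
#' @param db an \code{\link{EpitopeSet}} of known epitopes.
#' @param params a \code{\link{SearchParams}} object.
#' @param onlyNeutralizing keep only hits to neutralizing-flagged records.
#' @param accessibility,flexibility optional numeric per-residue tracks.
#' @param minCoreLen minimum reported core length, residues.
#' @return list of class \code{"Prediction"} with \code{id}, \code{cores}
#'   (data.frame ordered by start: \code{start}, \code{end}, \code{peptide},
#'   \code{bit_score}, \code{accessibility}, \code{flexibility},
#'   \code{neutralizing_support}, \code{n_hits}), \code{profile} (the
#'   \code{\link{ResidueProfile}}), \code{hits} and \code{supportingHits}
#'   (list of per-core hit tables).
#' @export
scanProtein <- function(protein, db, params = SearchParams(),
                        onlyNeutralizing = FALSE, accessibility = NULL,
                        flexibility = NULL, minCoreLen = 8L) {
  seq <- as.character(protein)
  id <- if (!is.null(names(protein))) names(protein)[1] else "query"
  n <- nchar(seq)
  for (trk in list(accessibility = accessibility, flexibility = flexibility))
    if (!is.null(trk) && length(trk) != n)
      stop("annotation track length (", length(trk),
           ") does not match protein length (", n, ")")
  hits <- findUngappedHits(seq, db, params)
  if (onlyNeutralizing) hits <- hits[hits$neutralizing, , drop = FALSE]
  profile <- residueProfile(seq, hits, id = id)
  cores <- extractCores(profile, minCoreLen = minCoreLen)
  support <- vector("list", nrow(cores))
  if (nrow(cores)) {
    cores$bit_score <- NA_real_
    cores$accessibility <- NA_real_
    cores$flexibility <- NA_real_
    cores$neutralizing_support <- FALSE
    cores$n_hits <- 0L
    for (k in seq_len(nrow(cores))) {
      ov <- hits$query_start <= cores$end[k] & hits$query_end >= cores$start[k]
      support[[k]] <- hits[ov, , drop = FALSE]
      cores$n_hits[k] <- sum(ov)
      if (any(ov)) {
        cores$bit_score[k] <- max(hits$bit_score[ov])
        cores$neutralizing_support[k] <- any(hits$neutralizing[ov])
      }
      rng <- cores$start[k]:cores$end[k]
      if (!is.null(accessibility))
        cores$accessibility[k] <- mean(accessibility[rng])
      if (!is.null(flexibility))
        cores$flexibility[k] <- mean(flexibility[rng])
    }
  } else {
    cores$bit_score <- numeric(0)
    cores$accessibility <- numeric(0)
    cores$flexibility <- numeric(0)
    cores$neutralizing_support <- logical(0)
    cores$n_hits <- integer(0)
  }
  structure(list(id = id, cores = cores, profile = profile, hits = hits,
                 supportingHits = support),
            class = "Prediction")
}

#' Write scan results as TSV files
#'
#' Writes the core table (\code{<stem>.cores.tsv}: protein_id, start, end,
#' peptide, bit_score, accessibility, flexibility, neutralizing_support) and
#' the per-residue profile track (\code{<stem>.profile.tsv}: position,
#' residue, B, Z_B).
#'
#' @param scan a protein-mode \code{"Prediction"} from
#'   \code{\link{scanProtein}}.
#' @param stem output path stem.
#' @return invisibly, the core-table path.
#' @export
writeScanTsv <- function(scan, stem) {
  cores <- cbind(protein_id = scan$id,
                 scan$cores[, c("start", "end", "peptide", "bit_score",
                                "accessibility", "flexibility",
                                "neutralizing_support")])
  write.table(cores, paste0(stem, ".cores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  prof <- scan$profile
  track <- data.frame(position = seq_along(prof@B),
                      residue = strsplit(prof@sequence, "")[[1]],
                      B = prof@B, Z_B = prof@ZB)
  write.table(track, paste0(stem, ".profile.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(stem, ".cores.tsv"))
}
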