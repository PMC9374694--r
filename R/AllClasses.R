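#' @useDynLib bepiscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment nmatch pid alignedPattern alignedSubject width
#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table
NULL

# The 20 standard amino acids, in the row/column order of the packaged
# BLOSUM62 matrix. All integer encodings index into this vector.
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' EpitopeSet: a curated set of epitope (or decoy) peptides
#'
#' An \code{EpitopeSet} is an \code{\link[Biostrings]{AAStringSet}} restricted
#' to the 20 standard amino acids, with unique record identifiers (the element
#' names), per-record metadata columns \code{source} (free-text antigen or
#' organism annotation) and \code{neutralizing} (whether the epitope is known
#' to be targeted by neutralizing antibodies), and dataset-level \code{label}
#' (\code{"positive"}, \code{"negative"} or \code{"unspecified"}) and
#' \code{provenance} slots.
#'
#' @slot label scalar character: \code{"positive"}, \code{"negative"} or
#'   \code{"unspecified"}.
#' @slot provenance free-text description of where the records came from.
#' @export
setClass("EpitopeSet",
  contains = "AAStringSet",
  representation(label = "character", provenance = "character"),
  prototype(label = "unspecified", provenance = "")
)

setValidity("EpitopeSet", function(object) {
  msg <- character()
  if (length(object)) {
    if (is.null(names(object)) || anyNA(names(object)) ||
        any(names(object) == ""))
      msg <- c(msg, "all records must be named with non-empty ids")
    else if (anyDuplicated(names(object)))
      msg <- c(msg, "record ids must be unique")
    if (any(width(object) == 0L))
      msg <- c(msg, "sequences must be non-empty")
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")),
                 as.character(object))
    if (any(bad))
      msg <- c(msg, sprintf(
        "%d sequence(s) contain letters outside the 20-residue alphabet",
        sum(bad)))
    mc <- mcols(object)
    if (is.null(mc) || !all(c("source", "neutralizing") %in% colnames(mc)))
      msg <- c(msg, "mcols must contain 'source' and 'neutralizing'")
    else if (!is.logical(mc$neutralizing) || anyNA(mc$neutralizing))
      msg <- c(msg, "'neutralizing' must be logical without NAs")
  }
  if (length(object@label) != 1L ||
      !object@label %in% c("positive", "negative", "unspecified"))
    msg <- c(msg, "label must be one of 'positive', 'negative', 'unspecified'")
  if (length(msg)) msg else TRUE
})

#' Construct an EpitopeSet
#'
#' Sequences are uppercased. Records containing letters outside the 20
#' standard amino acids (B, J, O, U, X, Z or anything non-alphabetic) are
#' dropped with a warning: substitution-matrix scoring and composition
#' statistics are defined on the 20-letter alphabet only.
#'
#' @param sequences character vector or \code{AAStringSet} of peptides.
#' @param ids unique record identifiers; defaults to existing names or
#'   \code{seq1..seqN}.
#' @param source per-record free-text annotation (recycled).
#' @param neutralizing per-record logical flag (recycled).
#' @param label dataset label: \code{"positive"}, \code{"negative"} or
#'   \code{"unspecified"}.
#' @param provenance free-text provenance note.
#' @return an \code{EpitopeSet}.
#' @examples
#' es <- EpitopeSet(c(e1 = "ACDEFGHI", e2 = "WLPKKYIVW"),
#'                  neutralizing = c(FALSE, TRUE))
#' neutralizing(es)
#' @export
EpitopeSet <- function(sequences = character(), ids = NULL, source = "",
                       neutralizing = FALSE, label = "unspecified",
                       provenance = "") {
  seqs <- toupper(as.character(sequences))
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids) && length(seqs))
      ids <- paste0("seq", seq_along(seqs))
  }
  if (length(seqs) && anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  source <- rep_len(as.character(source), length(seqs))
  neutralizing <- rep_len(as.logical(neutralizing), length(seqs))
  ok <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), seqs) &
        nchar(seqs) > 0L
  if (any(!ok)) {
    warning(sum(!ok), " record(s) dropped: empty or containing letters ",
            "outside the 20 standard amino acids (",
            paste(utils::head(ids[!ok], 5L), collapse = ", "), ")")
    seqs <- seqs[ok]; ids <- ids[ok]
    source <- source[ok]; neutralizing <- neutralizing[ok]
  }
  aas <- AAStringSet(setNames(seqs, ids))
  mcols(aas) <- DataFrame(source = source, neutralizing = neutralizing)
  new("EpitopeSet", aas, label = label, provenance = provenance)
}

#' @describeIn EpitopeSet neutralizing-antibody flags, one per record.
#' @param x an \code{EpitopeSet}.
#' @export
neutralizing <- function(x) {
  stopifnot(is(x, "EpitopeSet"))
  if (!length(x)) logical() else setNames(mcols(x)$neutralizing, names(x))
}

#' @describeIn EpitopeSet per-record source annotation.
#' @export
epitopeSource <- function(x) {
  stopifnot(is(x, "EpitopeSet"))
  if (!length(x)) character() else setNames(mcols(x)$source, names(x))
}

#' @describeIn EpitopeSet dataset label accessor.
#' @export
datasetLabel <- function(x) x@label

#' @describeIn EpitopeSet dataset provenance accessor.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "EpitopeSet", function(object) {
  cat("EpitopeSet of", length(object), "peptide(s)",
      sprintf("[label=%s]", object@label), "\n")
  if (length(object)) {
    w <- width(object)
    cat(sprintf("  lengths %d-%d, %d neutralizing\n", min(w), max(w),
                sum(mcols(object)$neutralizing)))
    callNextMethod()
  }
})

#' Search parameters for the ungapped epitope hit search
#'
#' Holds the hit-qualification thresholds and the Karlin-Altschul constants
#' used to convert raw BLOSUM62 scores into bit scores. The defaults are the
#' validated operating point of the method: ungapped hits of length >= 8
#' residues and identity >= 80%, one best hit per database subject, and the
#' standard ungapped-BLOSUM62 constants lambda = 0.3176, K = 0.134.
#'
#' @slot minLength minimum qualifying hit length, residues.
#' @slot minIdentity minimum qualifying hit identity, percent.
#' @slot allowGaps must be \code{FALSE}; gapped hit search is not supported.
#' @slot lambda,K Karlin-Altschul parameters for bit-score conversion.
#' @slot perSubjectBestOnly keep only the highest-scoring hit per database
#'   subject (ties: longest, then smallest query start).
#' @export
setClass("SearchParams",
  representation(minLength = "integer", minIdentity = "numeric",
                 allowGaps = "logical", lambda = "numeric", K = "numeric",
                 perSubjectBestOnly = "logical"),
  prototype(minLength = 8L, minIdentity = 80, allowGaps = FALSE,
            lambda = 0.3176, K = 0.134, perSubjectBestOnly = TRUE)
)

setValidity("SearchParams", function(object) {
  msg <- character()
  if (object@minLength < 1L) msg <- c(msg, "minLength must be >= 1")
  if (object@minIdentity <= 0 || object@minIdentity > 100)
    msg <- c(msg, "minIdentity must be in (0, 100]")
  if (isTRUE(object@allowGaps))
    msg <- c(msg, "gapped hit search is not supported (allowGaps must be FALSE)")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SearchParams constructor with the validated defaults.
#' @param minLength,minIdentity,allowGaps,lambda,K,perSubjectBestOnly see slots.
#' @export
SearchParams <- function(minLength = 8L, minIdentity = 80, allowGaps = FALSE,
                         lambda = 0.3176, K = 0.134,
                         perSubjectBestOnly = TRUE) {
  new("SearchParams", minLength = as.integer(minLength),
      minIdentity = as.numeric(minIdentity), allowGaps = allowGaps,
      lambda = lambda, K = K, perSubjectBestOnly = perSubjectBestOnly)
}

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(
    "SearchParams: length >= %d, identity >= %g%%, ungapped; lambda=%g, K=%g, bestPerSubject=%s\n",
    object@minLength, object@minIdentity, object@lambda, object@K,
    object@perSubjectBestOnly))
})

#' ResidueProfile: per-residue hit tally and z-score over a protein query
#'
#' For a scanned protein, \code{B[i]} counts the qualifying ungapped hits
#' whose query interval covers residue \code{i}; residues in no hit have
#' \code{B = 0}. \code{Z_B = (B - mu_B) / sd_B} where \code{mu_B} and
#' \code{sd_B} are the mean and population standard deviation of \code{B}
#' over all residues of the protein. When \code{sd_B = 0} (uniform coverage)
#' the z-score is defined as zero everywhere.
#'
#' @slot proteinId query identifier.
#' @slot sequence the query protein sequence.
#' @slot B integer hit tally per residue.
#' @slot ZB z-score per residue.
#' @slot muB,sdB mean and population standard deviation of \code{B}.
#' @export
setClass("ResidueProfile",
  representation(proteinId = "character", sequence = "character",
                 B = "integer", ZB = "numeric", muB = "numeric",
                 sdB = "numeric"))

setValidity("ResidueProfile", function(object) {
  msg <- character()
  if (length(object@B) != nchar(object@sequence))
    msg <- c(msg, "B must have one entry per protein residue")
  if (length(object@ZB) != length(object@B))
    msg <- c(msg, "ZB must have one entry per protein residue")
  if (any(object@B < 0L)) msg <- c(msg, "B must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn ResidueProfile the per-residue hit tally.
#' @param x a \code{ResidueProfile}.
#' @export
hitTally <- function(x) { stopifnot(is(x, "ResidueProfile")); x@B }

#' @describeIn ResidueProfile the per-residue z-score track.
#' @export
zScores <- function(x) { stopifnot(is(x, "ResidueProfile")); x@ZB }

setMethod("show", "ResidueProfile", function(object) {
  cat(sprintf(
    "ResidueProfile '%s': %d residues, %d covered (B > 0), muB=%.4g, sdB=%.4g\n",
    object@proteinId, length(object@B), sum(object@B > 0L),
    object@muB, object@sdB))
})

# integer-encode sequences for the C++ search engine (0-based indices into
# AA_ALPHABET20)
.encodeSeqs <- function(x) {
  lut <- integer(127)
  lut[utf8ToInt(paste(AA_ALPHABET20, collapse = ""))] <- seq_along(AA_ALPHABET20)
  lapply(as.character(x), function(s) {
    v <- lut[utf8ToInt(s)]
    if (any(v == 0L))
      stop("sequence contains letters outside the 20-residue alphabet")
    v - 1L
  })
}
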