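#' Pooled amino-acid composition of a dataset
#'
#' Residue counts pooled over all sequences, divided by the total residue
#' count. The result always sums to 1.
#'
#' @param x an \code{\link{EpitopeSet}} (non-empty).
#' @return named numeric vector of 20 frequencies.
#' @export
aaFrequencies <- function(x) {
  stopifnot(is(x, "EpitopeSet"))
  if (!length(x)) stop("cannot compute composition of an empty dataset")
  counts <- colSums(Biostrings::letterFrequency(x, AA_ALPHABET20))
  counts / sum(counts)
}

#' Log2 amino-acid enrichment against a background composition
#'
#' \code{log2(freq[a] / background[a])} per amino acid, e.g. epitope
#' composition relative to the Swiss-Prot proteome background.
#'
#' @param freq,background named 20-entry frequency vectors (see
#'   \code{\link{aaFrequencies}}, \code{\link{swissprotComposition}}).
#' @return named numeric vector of log2 ratios.
#' @export
aaEnrichment <- function(freq, background) {
  background <- background[names(freq)]
  if (anyNA(background) || any(background <= 0))
    stop("background composition must be positive for every amino acid")
  log2(freq / background)
}

#' Length statistics of a peptide dataset
#'
#' Mean, population standard deviation (divide by N), median (mean of the two
#' middle values for even counts) and the normalized empirical length
#' distribution.
#'
#' @param x an \code{\link{EpitopeSet}} (non-empty).
#' @return list with \code{mean}, \code{sd}, \code{median} and
#'   \code{distribution} (named probability vector over observed lengths).
#' @export
lengthStats <- function(x) {
  stopifnot(is(x, "EpitopeSet"))
  if (!length(x)) stop("cannot compute length statistics of an empty dataset")
  w <- width(x)
  tab <- table(w)
  list(mean = mean(w),
       sd = sqrt(mean((w - mean(w))^2)),
       median = median(w),
       distribution = setNames(as.numeric(tab) / length(w), names(tab)))
}

#' Swiss-Prot background amino-acid composition
#'
#' The amino-acid composition of the UniProtKB/Swiss-Prot proteome, shipped
#' as a configuration table and normalized to sum exactly to 1. Used as the
#' background for enrichment analysis and as the default residue distribution
#' for random-peptide generation.
#'
#' @param path optional path to an alternative two-column TSV
#'   (\code{aa<TAB>frequency}).
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
swissprotComposition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "swissprot_composition.tsv",
                        package = "bepiscan", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  freq <- setNames(as.numeric(tab[[2]]), tab[[1]])[AA_ALPHABET20]
  if (anyNA(freq)) stop("composition table must cover all 20 amino acids")
  freq / sum(freq)
}
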