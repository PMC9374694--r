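#' Build an epitope database bundle from FASTA input
#'
#' Applies the curation pipeline — alphabet policy (non-standard residues
#' dropped with a warning), length filter, optional greedy redundancy
#' reduction — and writes an engine-agnostic database bundle: normalized
#' FASTA, metadata TSV and a summary JSON (record count, neutralizing count,
#' length statistics, composition).
#'
#' @param fasta input FASTA path (a sibling \code{<stem>.meta.tsv} is merged
#'   when present).
#' @param out output directory.
#' @param minLen,maxLen length filter bounds.
#' @param reduceRedundancyPct if non-\code{NULL}, run
#'   \code{\link{reduceRedundancy}} at this identity threshold (off by
#'   default for pre-curated inputs).
#' @return invisibly, the curated \code{\link{EpitopeSet}}.
#' @export
makeDbBundle <- function(fasta, out, minLen = 8L, maxLen = 25L,
                         reduceRedundancyPct = NULL) {
  ds <- readEpitopeFasta(fasta, label = "positive")
  ds <- filterByLength(ds, minLen, maxLen)
  if (!is.null(reduceRedundancyPct))
    ds <- reduceRedundancy(ds, reduceRedundancyPct)
  if (!length(ds)) stop("no records left after curation")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeEpitopeFasta(ds, file.path(out, "db.fasta"))
  ls <- lengthStats(ds)
  summary <- list(
    n_records = length(ds),
    n_neutralizing = sum(neutralizing(ds)),
    length_mean = ls$mean, length_sd = ls$sd, length_median = ls$median,
    composition = as.list(aaFrequencies(ds)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

#' Read an epitope database bundle
#'
#' @param dir a bundle directory written by \code{\link{makeDbBundle}}.
#' @return the bundled \code{\link{EpitopeSet}}.
#' @export
readDbBundle <- function(dir) {
  readEpitopeFasta(file.path(dir, "db.fasta"), label = "positive")
}

#' Dataset composition and length reports
#'
#' Emits composition, log2-enrichment (when a background is given) and
#' length-distribution tables for a dataset, as TSV files under \code{out}.
#'
#' @param ds an \code{\link{EpitopeSet}}.
#' @param out output directory.
#' @param background optional named background frequency vector for
#'   enrichment.
#' @return invisibly, a list of the three tables.
#' @export
datasetStatsReport <- function(ds, out, background = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  comp <- aaFrequencies(ds)
  write.table(data.frame(aa = names(comp), frequency_pct = 100 * comp),
              file.path(out, "composition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  enr <- NULL
  if (!is.null(background)) {
    enr <- aaEnrichment(comp, background)
    write.table(data.frame(aa = names(enr), log2_enrichment = enr),
                file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  ls <- lengthStats(ds)
  write.table(data.frame(length = names(ls$distribution),
                         probability = ls$distribution),
              file.path(out, "length_distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(composition = comp, enrichment = enr, lengths = ls))
}
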