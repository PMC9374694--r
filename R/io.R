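#' Read an epitope dataset from FASTA
#'
#' One record per FASTA entry; sequences are uppercased. A
#' \code{neutralizing=true|false} key in the description line sets the
#' neutralizing flag (default \code{FALSE}); the remainder of the description
#' becomes the \code{source} annotation. If a sibling metadata table
#' \code{<stem>.meta.tsv} exists (tab-separated, header
#' \code{id<TAB>source<TAB>neutralizing}), its values override the in-header
#' annotation for matching ids. Records with letters outside the 20 standard
#' amino acids are dropped with a warning.
#'
#' @param path FASTA file.
#' @param label dataset label to attach (\code{"positive"}, \code{"negative"}
#'   or \code{"unspecified"}).
#' @return an \code{\link{EpitopeSet}}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">e1", "ACDEFGHI", ">e2 neutralizing=true", "WLPKKYIVW"), f)
#' es <- readEpitopeFasta(f)
#' neutralizing(es)
#' @export
readEpitopeFasta <- function(path, label = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(EpitopeSet(label = label, provenance = path))
  }
  aas <- readAAStringSet(path)
  hdr <- names(aas)
  ids <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  neut <- grepl("neutralizing=true", desc, ignore.case = TRUE)
  src <- trimws(gsub("neutralizing=(true|false)", "", desc,
                     ignore.case = TRUE))
  meta_path <- paste0(sub("\\.[^.]+$", "", path), ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                       colClasses = "character")
    if (!all(c("id", "source", "neutralizing") %in% colnames(meta)))
      stop("metadata table ", meta_path,
           " must have columns id, source, neutralizing")
    m <- match(ids, meta$id)
    hit <- !is.na(m)
    src[hit] <- meta$source[m[hit]]
    neut[hit] <- tolower(meta$neutralizing[m[hit]]) == "true"
  }
  EpitopeSet(as.character(aas), ids = ids, source = src, neutralizing = neut,
             label = label, provenance = path)
}

#' Write an epitope dataset as FASTA plus metadata table
#'
#' Writes \code{<path>} as FASTA (neutralizing flags encoded as
#' \code{neutralizing=true} in the description line) and a sibling
#' \code{<stem>.meta.tsv} with columns \code{id}, \code{source},
#' \code{neutralizing}.
#'
#' @param x an \code{EpitopeSet}.
#' @param path output FASTA path.
#' @return invisibly, the FASTA path.
#' @export
writeEpitopeFasta <- function(x, path) {
  stopifnot(is(x, "EpitopeSet"))
  aas <- AAStringSet(setNames(as.character(x), names(x)))
  names(aas) <- ifelse(neutralizing(x),
                       paste(names(x), "neutralizing=true"), names(x))
  writeXStringSet(aas, path)
  meta <- data.frame(id = names(x), source = epitopeSource(x),
                     neutralizing = ifelse(neutralizing(x), "true", "false"),
                     stringsAsFactors = FALSE)
  write.table(meta, paste0(sub("\\.[^.]+$", "", path), ".meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue annotation track
#'
#' Two-column tab-separated file (\code{position<TAB>value}, 1-based
#' positions, header optional) carrying an externally computed per-residue
#' value such as relative solvent accessibility or flexibility.
#'
#' @param path TSV file.
#' @param proteinLength expected number of residues; when given, the track is
#'   checked to cover positions \code{1..proteinLength} exactly.
#' @return numeric vector ordered by position.
#' @export
readTrackTsv <- function(path, proteinLength = NULL) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(raw[[1]]) || suppressWarnings(anyNA(as.numeric(raw[1, ]))))
    raw <- raw[-1, , drop = FALSE]  # header row
  pos <- as.integer(raw[[1]])
  val <- as.numeric(raw[[2]])
  if (anyNA(pos) || anyNA(val)) stop("malformed track file: ", path)
  v <- val[order(pos)]
  if (!is.null(proteinLength) &&
      (length(v) != proteinLength || !identical(sort(pos), seq_len(proteinLength))))
    stop("track in ", path, " does not cover positions 1..", proteinLength)
  v
}

#' Write an ungapped hit table as TSV
#'
#' @param hits a hit table from \code{\link{findUngappedHits}}.
#' @param path output path.
#' @param queryId query identifier written in the first column.
#' @return invisibly, the path.
#' @export
writeHitsTsv <- function(hits, path, queryId = "query") {
  out <- cbind(query_id = queryId,
               hits[, c("query_start", "query_end", "subject_id",
                        "subject_start", "subject_end", "length",
                        "identity_pct", "raw_score", "bit_score",
                        "neutralizing")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
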