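# BLOSUM62 restricted to the 20 standard amino acids, cached per session.
.blosum_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix (20 standard amino acids)
#'
#' The canonical NCBI BLOSUM62 matrix as shipped with Biostrings, restricted
#' to the 20 standard amino-acid letters and ordered to match the internal
#' alphabet. Symmetric integer matrix; e.g. W/W = 11, A/A = 4, W/A = -3.
#'
#' @return a 20 x 20 symmetric integer matrix with dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
    storage.mode(m) <- "integer"
    .blosum_env$B62 <- m
  }
  .blosum_env$B62
}
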