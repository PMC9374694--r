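# Independent oracles used to pin expected values. These deliberately share
# no code with the package implementation paths they check.

ALPHA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# --- naive ungapped hit search ---------------------------------------------
# Enumerate every (record, query offset, subject offset, window length)
# tuple, filter by length and identity, suppress windows contained in a
# qualifying window on the same diagonal, optionally keep the best hit per
# subject. Returns a data.frame comparable to findUngappedHits().
naive_hits <- function(query, db_seqs, min_len = 8L, min_id = 80,
                       best_only = TRUE) {
  B62 <- bepiscan::blosum62()
  q <- strsplit(query, "")[[1]]
  rows <- NULL
  for (j in seq_along(db_seqs)) {
    s <- strsplit(db_seqs[j], "")[[1]]
    wins <- NULL
    for (d in (-(length(s) - 1L)):(length(q) - 1L)) {
      qs0 <- max(0L, d); ss0 <- qs0 - d
      L <- min(length(q) - qs0, length(s) - ss0)
      if (L < min_len) next
      mt <- q[qs0 + seq_len(L)] == s[ss0 + seq_len(L)]
      cm <- c(0L, cumsum(mt))
      dwins <- NULL
      for (a in 0:(L - min_len)) for (len in min_len:(L - a)) {
        m <- cm[a + len + 1L] - cm[a + 1L]
        if (m * 100 >= min_id * len - 1e-9)
          dwins <- rbind(dwins, c(a, a + len - 1L, m))
      }
      if (is.null(dwins)) next
      # suppress contained windows (same diagonal)
      keep <- rep(TRUE, nrow(dwins))
      for (u in seq_len(nrow(dwins))) for (v in seq_len(nrow(dwins)))
        if (u != v && dwins[v, 1] <= dwins[u, 1] &&
            dwins[v, 2] >= dwins[u, 2]) { keep[u] <- FALSE; break }
      for (u in which(keep)) {
        a <- dwins[u, 1]; b <- dwins[u, 2]
        raw <- sum(vapply(a:b, function(i)
          B62[q[qs0 + i + 1L], s[ss0 + i + 1L]], numeric(1)))
        wins <- rbind(wins, data.frame(
          subject = j, query_start = qs0 + a + 1L, query_end = qs0 + b + 1L,
          subject_start = ss0 + a + 1L, subject_end = ss0 + b + 1L,
          length = b - a + 1L, matches = dwins[u, 3], raw_score = raw))
      }
    }
    if (is.null(wins)) next
    if (best_only) {
      o <- order(-wins$raw_score, -wins$length, wins$query_start)
      wins <- wins[o[1L], , drop = FALSE]
    }
    rows <- rbind(rows, wins)
  }
  if (is.null(rows))
    return(data.frame(subject = integer(0), query_start = integer(0),
                      query_end = integer(0), subject_start = integer(0),
                      subject_end = integer(0), length = integer(0),
                      matches = integer(0), raw_score = numeric(0)))
  rows[order(rows$subject, rows$query_start, rows$subject_start,
             rows$length), , drop = FALSE]
}

# canonical form of a package hit table for set comparison with the oracle
hit_key <- function(h, db_names) {
  if (nrow(h) == 0) return(character(0))
  subj <- if ("subject_id" %in% names(h)) match(h$subject_id, db_names)
          else h$subject
  sort(sprintf("%d:%d-%d/%d-%d", subj, h$query_start, h$query_end,
               h$subject_start, h$subject_end))
}

# --- affine-gap global alignment score (Gotoh) ------------------------------
# gap of length k costs open + k * ext
nw_affine_score <- function(a, b, open = 10, ext = 0.5, mat = blosum62()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- misc fixtures ----------------------------------------------------------
random_seq <- function(len, letters = ALPHA20) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

random_epitope_set <- function(n, len_range = c(8L, 25L), letters = ALPHA20,
                               prefix = "p") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  EpitopeSet(vapply(lens, random_seq, character(1), letters = letters),
             ids = paste0(prefix, seq_len(n)))
}

# independent checker for extracted cores: non-overlap, min length, coverage,
# and (for plateau-shaped runs) the flanking z-score condition
check_cores <- function(cores, profile, min_len = 8L) {
  B <- hitTally(profile); Z <- zScores(profile); n <- length(B)
  if (nrow(cores) == 0) return(TRUE)
  ok <- all(cores$end - cores$start + 1L >= min_len)
  ords <- cores[order(cores$start), ]
  if (nrow(ords) > 1)
    ok <- ok && all(ords$start[-1] > ords$end[-nrow(ords)])
  for (k in seq_len(nrow(cores))) {
    rng <- cores$start[k]:cores$end[k]
    ok <- ok && all(B[rng] > 0L)
    zmin <- min(Z[rng])
    if (cores$start[k] > 1) ok <- ok && zmin >= Z[cores$start[k] - 1L] - 1e-12
    if (cores$end[k] < n) ok <- ok && zmin >= Z[cores$end[k] + 1L] - 1e-12
  }
  ok
}
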