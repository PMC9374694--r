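test_that("peptide verdict is epitope iff a qualifying hit exists", {
  db <- EpitopeSet(c(e1 = "MKTAYIAKQRQISFVK"))
  expect_identical(classifyPeptide("MKTAYIAKQRQISFVK", db)$verdict, "epitope")
  # 7-mers can never qualify
  expect_identical(classifyPeptide("MKTAYIA", db)$verdict, "non-epitope")
  # 13-mer with substitutions at positions 1 and 13: interior 11-mer is 100%
  db13 <- EpitopeSet(c(p = "MKTAYIAKQRQIS"))
  q <- "WKTAYIAKQRQIW"
  expect_identical(classifyPeptide(q, db13)$verdict, "epitope")
  expect_gt(nrow(naive_hits(q, "MKTAYIAKQRQIS")), 0)  # oracle concurs
  # fast existence path agrees with the hit-table path
  expect_identical(unname(classifyPeptides(
    EpitopeSet(c(a = "MKTAYIAKQRQISFVK", b = "MKTAYIA", c = q)),
    db13)), c(TRUE, FALSE, TRUE))
})

test_that("classification is monotone in the database", {
  set.seed(41)
  db <- random_epitope_set(10, prefix = "d")
  extra <- random_epitope_set(10, prefix = "x")
  grown <- EpitopeSet(c(as.character(db), as.character(extra)),
                      ids = c(names(db), names(extra)))
  queries <- random_epitope_set(30, prefix = "q")
  v1 <- classifyPeptides(queries, db)
  v2 <- classifyPeptides(queries, grown)
  expect_true(all(v2[v1]))  # adding records never flips epitope -> non-epitope
})

test_that("residue profile implements the z-score normalization exactly", {
  # no hits: all zeros
  p0 <- residueProfile(strrep("A", 15),
                       data.frame(query_start = integer(0),
                                  query_end = integer(0)))
  expect_identical(hitTally(p0), integer(15))
  expect_identical(zScores(p0), numeric(15))

  # 20 residues, one hit 6-15: B is 0/1 balanced, so Z = +1 inside, -1 outside
  hits <- data.frame(query_start = 6L, query_end = 15L)
  p <- residueProfile(strrep("A", 20), hits)
  expect_identical(hitTally(p), c(rep(0L, 5), rep(1L, 10), rep(0L, 5)))
  expect_equal(p@muB, 0.5)
  expect_equal(p@sdB, 0.5)
  expect_equal(zScores(p), c(rep(-1, 5), rep(1, 10), rep(-1, 5)))
  expect_equal(mean(zScores(p)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zScores(p)^2)), 1, tolerance = 1e-12)

  # duplicated hits scale B but leave Z unchanged
  p2 <- residueProfile(strrep("A", 20), rbind(hits, hits))
  expect_identical(hitTally(p2), 2L * hitTally(p))
  expect_equal(zScores(p2), zScores(p))

  expect_error(residueProfile(strrep("A", 10),
                              data.frame(query_start = 5L, query_end = 12L)),
               "bounds")
})

test_that("z-profile is standardized for any non-degenerate tally", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    k <- sample(1:6, 1)
    qs <- sample(seq_len(n - 9), k, replace = TRUE)
    hits <- data.frame(query_start = qs,
                       query_end = pmin(n, qs + sample(7:14, k, replace = TRUE)))
    p <- residueProfile(random_seq(n), hits)
    if (p@sdB > 0) {
      expect_equal(mean(zScores(p)), 0, tolerance = 1e-10)
      expect_equal(sqrt(mean(zScores(p)^2)), 1, tolerance = 1e-10)
    }
  }
})

test_that("core extraction returns maximal plateau segments", {
  # single plateau 6-15 -> exactly that core
  p <- residueProfile(strrep("A", 20),
                      data.frame(query_start = 6L, query_end = 15L))
  cores <- extractCores(p)
  expect_identical(cores$start, 6L)
  expect_identical(cores$end, 15L)
  expect_identical(cores$peptide, strrep("A", 10))
  expect_true(check_cores(cores, p))

  # run of length 7: below the minimum, no cores
  p7 <- residueProfile(strrep("A", 20),
                       data.frame(query_start = 6L, query_end = 12L))
  expect_identical(nrow(extractCores(p7)), 0L)

  # two plateaus of different heights separated by a zero gap -> two cores
  h2 <- data.frame(query_start = c(3L, 3L, 20L), query_end = c(10L, 10L, 28L))
  p2 <- residueProfile(strrep("A", 30), h2)
  c2 <- extractCores(p2)
  expect_identical(nrow(c2), 2L)
  expect_identical(c2$start, c(3L, 20L))
  expect_identical(c2$end, c(10L, 28L))
  expect_true(check_cores(c2, p2))

  # degenerate uniform coverage: whole protein is one core
  pu <- residueProfile(strrep("A", 12),
                       data.frame(query_start = 1L, query_end = 12L))
  expect_identical(pu@sdB, 0)
  cu <- extractCores(pu)
  expect_identical(c(cu$start, cu$end), c(1L, 12L))
})

test_that("protein scan recovers a planted epitope with annotations", {
  set.seed(71)
  epi <- "WLPKKYIVWQACD"  # 13-mer planted epitope
  db <- EpitopeSet(c(known = epi), neutralizing = TRUE)
  # flank with low-complexity sequence that cannot hit the db record
  prot <- paste0(strrep("G", 15), epi, strrep("S", 15))
  sc <- scanProtein(c(myprotein = prot), db)
  expect_identical(sc$id, "myprotein")
  expect_identical(nrow(sc$cores), 1L)
  expect_identical(c(sc$cores$start, sc$cores$end), c(16L, 28L))
  expect_identical(sc$cores$peptide, epi)
  expect_true(sc$cores$neutralizing_support)
  expect_equal(sc$cores$bit_score, max(sc$hits$bit_score))
  expect_true(check_cores(sc$cores, sc$profile))

  # only_neutralizing filters out hits to non-neutralizing records
  db_nn <- EpitopeSet(c(known = epi), neutralizing = FALSE)
  sc2 <- scanProtein(prot, db_nn, onlyNeutralizing = TRUE)
  expect_identical(nrow(sc2$cores), 0L)

  # constant accessibility track averages to the constant on every core
  acc <- rep(0.42, nchar(prot))
  sc3 <- scanProtein(prot, db, accessibility = acc)
  expect_equal(sc3$cores$accessibility, 0.42)
  expect_error(scanProtein(prot, db, accessibility = c(1, 2, 3)),
               "track length")
})

test_that("scan output files carry the core table and residue track", {
  db <- EpitopeSet(c(known = "WLPKKYIVWQACD"), neutralizing = TRUE)
  prot <- paste0(strrep("G", 10), "WLPKKYIVWQACD", strrep("S", 10))
  sc <- scanProtein(c(p1 = prot), db)
  stem <- tempfile()
  writeScanTsv(sc, stem)
  cores <- read.delim(paste0(stem, ".cores.tsv"))
  expect_identical(colnames(cores)[1:4],
                   c("protein_id", "start", "end", "peptide"))
  track <- read.delim(paste0(stem, ".profile.tsv"))
  expect_identical(nrow(track), nchar(prot))
  expect_identical(colnames(track), c("position", "residue", "B", "Z_B"))
})

test_that("planted non-overlapping epitopes are all recovered by cores", {
  set.seed(333)
  for (rep in 1:8) {
    db <- random_epitope_set(15, c(10, 18), prefix = "d")
    k <- sample(2:4, 1)
    picks <- sample(length(db), k)
    gap <- strrep("G", 12)  # >= 10 zero-coverage residues between plants
    segs <- as.character(db)[picks]
    prot <- paste0(gap, paste(segs, collapse = gap), gap)
    sc <- scanProtein(prot, db)
    # locate each planted interval and require core coverage
    off <- nchar(gap)
    for (s in segs) {
      st <- off + 1L; en <- off + nchar(s)
      covered <- any(sc$cores$start <= st & sc$cores$end >= en)
      # a plant may pick up extra hits from similar db records; at minimum
      # every planted residue must lie inside some core
      in_core <- all(vapply(st:en, function(i)
        any(sc$cores$start <= i & sc$cores$end >= i), logical(1)))
      expect_true(covered || in_core)
      off <- en + nchar(gap)
    }
    expect_true(check_cores(sc$cores, sc$profile))
    # cores never overlap and every core has supporting hits
    expect_true(all(sc$cores$n_hits > 0))
  }
})
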