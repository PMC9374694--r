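test_that("confusion metrics reproduce the closed-form contingency cases", {
  perfect <- confusionMetrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(perfect$SE, 100)
  expect_equal(perfect$SP, 100)
  expect_equal(perfect$ACC, 100)
  expect_equal(perfect$MCC, 1, tolerance = 1e-12)

  inverted <- confusionMetrics(tp = 0, fp = 50, tn = 0, fn = 50)
  expect_equal(inverted$SE, 0)
  expect_equal(inverted$SP, 0)
  expect_equal(inverted$ACC, 0)
  expect_equal(inverted$MCC, -1, tolerance = 1e-12)

  # the mixed operating point, frozen from direct arithmetic:
  # MCC = 4900 / sqrt(149 * 100 * 100 * 51)
  m <- confusionMetrics(tp = 50, fp = 1, tn = 99, fn = 50)
  expect_equal(m$SE, 50)
  expect_equal(m$SP, 99)
  expect_equal(m$ACC, 74.5)
  expect_equal(m$MCC, 4900 / sqrt(149 * 100 * 100 * 51), tolerance = 1e-12)
  expect_equal(m$MCC, 0.5621055, tolerance = 1e-6)

  # zero marginals surface as NaN with a warning, not silent zeros
  expect_warning(z <- confusionMetrics(tp = 0, fp = 0, tn = 10, fn = 10),
                 "MCC")
  expect_true(is.nan(z$MCC))
  # an empty positive margin voids both SE and MCC
  expect_warning(expect_warning(
    confusionMetrics(tp = 0, fp = 5, tn = 5, fn = 0), "SE"), "MCC")
})

test_that("metrics agree with naive recomputation from stored verdicts", {
  set.seed(19)
  db <- random_epitope_set(25, prefix = "d")
  pos <- makeFixturePositives(db, 30, 0.05, seed = 1)
  neg <- randomPeptides(30, seed = 2)
  m <- holdoutEval(pos, neg, db)
  v <- attr(m, "verdicts")
  tp <- sum(v$label == 1 & v$verdict == "epitope")
  fn <- sum(v$label == 1 & v$verdict == "non-epitope")
  fp <- sum(v$label == 0 & v$verdict == "epitope")
  tn <- sum(v$label == 0 & v$verdict == "non-epitope")
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
  expect_equal(m$SE, 100 * tp / (tp + fn))
  expect_equal(m$ACC, 100 * (tp + tn) / nrow(v))
})

test_that("fold assignment is balanced, disjoint and exhaustive", {
  set.seed(3)
  pos <- random_epitope_set(53, prefix = "p")
  neg <- random_epitope_set(47, prefix = "n")
  cv <- suppressWarnings(tenfoldCV(pos, neg, k = 10, seed = 5))
  fp <- cv$foldsPositive
  fn <- cv$foldsNegative
  expect_identical(sort(names(fp)), sort(names(pos)))
  expect_lte(diff(range(tabulate(fp, 10))), 1L)
  expect_lte(diff(range(tabulate(fn, 10))), 1L)
  # every record tested exactly once
  expect_identical(sort(cv$verdicts$id), sort(c(names(pos), names(neg))))
  expect_identical(nrow(cv$verdicts), 100L)
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(8)
  db <- random_epitope_set(40, prefix = "d")
  pos <- makeFixturePositives(db, 60, 0, seed = 1)
  neg <- randomPeptides(60, seed = 2)
  cv1 <- tenfoldCV(pos, neg, k = 5, seed = 11)
  cv2 <- tenfoldCV(pos, neg, k = 5, seed = 11)
  expect_identical(cv1$perFold, cv2$perFold)
  expect_identical(cv1$foldsPositive, cv2$foldsPositive)
  expect_false(identical(tenfoldCV(pos, neg, k = 5, seed = 12)$foldsPositive,
                         cv1$foldsPositive))
})

test_that("guaranteed twins give SE = 100% and disjoint alphabets SP = 100%", {
  set.seed(2)
  # negatives use a disjoint residue-usage pattern: positives avoid F/W/Y/H
  # entirely, negatives are built only from them
  neg <- EpitopeSet(vapply(1:60, function(i)
    random_seq(12, letters = c("F", "W", "Y", "H")), character(1)),
    ids = paste0("n", 1:60))
  # six distinct base peptides, ten identical copies each: every positive has
  # an identical twin in every other fold (with overwhelming probability)
  pos <- EpitopeSet(vapply(1:60, function(i)
    random_seq(12, letters = setdiff(ALPHA20, c("F", "W", "Y", "H"))),
    character(1))[rep(1:6, each = 10)], ids = paste0("p", 1:60))
  cv <- tenfoldCV(pos, neg, k = 10, seed = 4)
  expect_true(all(cv$perFold$SE == 100))
  expect_true(all(cv$perFold$SP == 100))
  expect_equal(unname(cv$mean["ACC"]), 100)
  expect_equal(unname(cv$sd["ACC"]), 0)
})

test_that("sensitivity does not depend on the negative dataset", {
  set.seed(23)
  db <- random_epitope_set(40, prefix = "d")
  pos <- makeFixturePositives(db, 50, 0.05, seed = 3)
  negA <- randomPeptides(50, seed = 4, prefix = "na")
  negB <- randomPeptides(50, seed = 5, prefix = "nb")
  cvA <- tenfoldCV(pos, negA, k = 5, seed = 7)
  cvB <- tenfoldCV(pos, negB, k = 5, seed = 7)
  expect_identical(cvA$perFold$SE, cvB$perFold$SE)
})

test_that("holdout evaluation matches its constructed fixtures", {
  set.seed(29)
  db <- random_epitope_set(30, prefix = "d")
  # positives are exact copies drawn from the db; negatives disjoint alphabet
  pos <- makeFixturePositives(db, 20, 0, seed = 1)
  neg <- EpitopeSet(vapply(1:20, function(i)
    random_seq(10, letters = c("F", "W", "Y", "H")), character(1)),
    ids = paste0("n", 1:20))
  dbFWYH_free <- EpitopeSet(vapply(1:30, function(i)
    random_seq(14, letters = setdiff(ALPHA20, c("F", "W", "Y", "H"))),
    character(1)), ids = paste0("d", 1:30))
  posx <- makeFixturePositives(dbFWYH_free, 20, 0, seed = 1)
  m <- holdoutEval(posx, neg, dbFWYH_free)
  expect_equal(m$SE, 100)
  expect_equal(m$SP, 100)

  # half the positives carry a planted db match -> SE = 50%
  hit_half <- makeFixturePositives(dbFWYH_free, 10, 0, seed = 2)
  miss_half <- EpitopeSet(vapply(1:10, function(i)
    random_seq(10, letters = c("F", "W", "Y", "H")), character(1)),
    ids = paste0("m", 1:10), label = "positive")
  mixed <- EpitopeSet(c(as.character(hit_half), as.character(miss_half)),
                      ids = c(names(hit_half), names(miss_half)))
  m2 <- holdoutEval(mixed, neg, dbFWYH_free)
  expect_equal(m2$SE, 50)
})

test_that("reports format cross-validation and single runs to two decimals", {
  set.seed(31)
  db <- random_epitope_set(20, prefix = "d")
  pos <- makeFixturePositives(db, 20, 0, seed = 1)
  neg <- EpitopeSet(vapply(1:20, function(i)
    random_seq(10, letters = c("F", "W", "Y")), character(1)),
    ids = paste0("n", 1:20))
  # all-identical folds render "± 0.00"
  posx <- EpitopeSet(vapply(1:20, function(i)
    random_seq(12, letters = setdiff(ALPHA20, c("F", "W", "Y"))),
    character(1))[rep(1:4, each = 5)], ids = paste0("p", 1:20))
  cv <- tenfoldCV(posx, neg, k = 5, seed = 2)
  lines <- reportMetrics(cv, "tsv", label = "fixture")
  expect_match(lines[2], "± 0.00")
  ms <- confusionMetrics(tp = 101, fp = 4, tn = 499, fn = 99)
  md <- reportMetrics(ms, "markdown", label = "row")
  expect_length(md, 3)
  expect_match(md[3], "\\| row \\|")
  expect_error(reportMetrics(list()), "CVResult or MetricSet")
})

test_that("database bundles carry curated records and summary statistics", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">e1", "ACDEFGH",           # length 7: dropped
               ">e2 neutralizing=true", "WLPKKYIVW",
               ">e3", "MKTAYIAKQR",
               ">e4", "MKTAYIAKQR"), f)    # exact duplicate of e3
  out <- tempfile()
  ds <- suppressMessages(makeDbBundle(f, out, reduceRedundancyPct = 90))
  expect_identical(sort(names(ds)), c("e2", "e3"))
  expect_true(file.exists(file.path(out, "db.fasta")))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(summ$n_records, 2L)
  expect_identical(summ$n_neutralizing, 1L)
  back <- readDbBundle(out)
  expect_identical(sort(names(back)), sort(names(ds)))

  rep <- datasetStatsReport(back, tempfile(), background = swissprotComposition())
  expect_equal(sum(rep$composition), 1, tolerance = 1e-9)
  expect_length(rep$enrichment, 20)
})
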