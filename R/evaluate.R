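#' Classification metrics from a confusion table
#'
#' Sensitivity \code{SE = 100 TP / (TP + FN)}, specificity
#' \code{SP = 100 TN / (TN + FP)}, accuracy
#' \code{ACC = 100 (TP + TN) / (TP + FP + TN + FN)} and the Matthews
#' correlation coefficient
#' \code{MCC = (TP TN - FP FN) / sqrt((TN+FN)(TP+FN)(TN+FP)(TP+FP))}.
#' When a marginal of the confusion table is zero the corresponding metric is
#' reported as \code{NaN} with a warning rather than silently zeroed.
#'
#' @param tp,fp,tn,fn confusion counts, or a list/vector with those names as
#'   the first argument.
#' @return list of class \code{"MetricSet"}: \code{SE}, \code{SP}, \code{ACC}
#'   (percentages), \code{MCC}, and the counts.
#' @examples
#' confusionMetrics(tp = 50, fp = 1, tn = 99, fn = 50)
#' @export
confusionMetrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L && is.null(fp))) {
    counts <- as.list(tp)
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("no positives tested; SE undefined"); NaN
  }
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("no negatives tested; SP undefined"); NaN
  }
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  # double arithmetic: the denominator overflows 32-bit integers near n=500
  d <- lapply(list(tp = tp, fp = fp, tn = tn, fn = fn), as.numeric)
  denom <- (d$tn + d$fn) * (d$tp + d$fn) * (d$tn + d$fp) * (d$tp + d$fp)
  mcc <- if (denom > 0) (d$tp * d$tn - d$fp * d$fn) / sqrt(denom) else {
    warning("zero marginal in confusion table; MCC undefined"); NaN
  }
  structure(list(SE = se, SP = sp, ACC = acc, MCC = mcc,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "MetricSet")
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf("SE %.2f%%  SP %.2f%%  ACC %.2f%%  MCC %.2f  (TP %d FP %d TN %d FN %d)\n",
              x$SE, x$SP, x$ACC, x$MCC, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# seeded uniform shuffle + round-robin slicing into k near-equal folds
.assignFolds <- function(n, k, seed) {
  .withSeed(seed, {
    ord <- sample(n)
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

#' k-fold cross-validation of the epitope classifier
#'
#' Positives and negatives are each partitioned uniformly at random (seeded)
#' into \code{k} near-equal folds. In round r, the search database is built
#' from the positives of all folds except r (negatives never enter the
#' database), and the held-out positive fold (label 1) plus the negative fold
#' r (label 0) are classified against it. Per-round confusion tables give
#' per-round metric sets; the summary is the mean and population standard
#' deviation across rounds.
#'
#' @param positives,negatives \code{\link{EpitopeSet}}s of equal intent
#'   (typically equal size).
#' @param params a \code{\link{SearchParams}} object.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return list of class \code{"CVResult"}: \code{perFold} (data.frame of
#'   fold, TP, FP, TN, FN, SE, SP, ACC, MCC), \code{mean} and \code{sd}
#'   (named vectors over SE/SP/ACC/MCC), \code{foldsPositive},
#'   \code{foldsNegative} (record id -> fold index), \code{seed}, \code{k},
#'   and \code{verdicts} (per-item audit data.frame: id, label, verdict,
#'   fold).
#' @export
tenfoldCV <- function(positives, negatives, params = SearchParams(),
                      k = 10L, seed = 42L) {
  stopifnot(is(positives, "EpitopeSet"), is(negatives, "EpitopeSet"),
            length(positives) > 0, length(negatives) > 0, k >= 2L)
  fp_ <- .assignFolds(length(positives), k, seed)
  fn_ <- .assignFolds(length(negatives), k, seed + 1L)
  if (any(tabulate(fp_, k) == 0L) || any(tabulate(fn_, k) == 0L))
    stop("a fold has zero positives or zero negatives; reduce k")
  perFold <- NULL
  audit <- NULL
  for (r in seq_len(k)) {
    db <- positives[fp_ != r]
    test_pos <- positives[fp_ == r]
    test_neg <- negatives[fn_ == r]
    vp <- classifyPeptides(test_pos, db, params)
    vn <- classifyPeptides(test_neg, db, params)
    m <- confusionMetrics(tp = sum(vp), fn = sum(!vp),
                          fp = sum(vn), tn = sum(!vn))
    perFold <- rbind(perFold, data.frame(
      fold = r, TP = m$tp, FP = m$fp, TN = m$tn, FN = m$fn,
      SE = m$SE, SP = m$SP, ACC = m$ACC, MCC = m$MCC))
    audit <- rbind(audit,
      data.frame(id = c(names(vp), names(vn)),
                 label = rep(c(1L, 0L), c(length(vp), length(vn))),
                 verdict = ifelse(c(vp, vn), "epitope", "non-epitope"),
                 fold = r, stringsAsFactors = FALSE))
  }
  metric_cols <- c("SE", "SP", "ACC", "MCC")
  mu <- colMeans(perFold[metric_cols])
  sdev <- sqrt(colMeans(sweep(perFold[metric_cols], 2, mu)^2))
  structure(list(perFold = perFold, mean = mu, sd = sdev,
                 foldsPositive = setNames(fp_, names(positives)),
                 foldsNegative = setNames(fn_, names(negatives)),
                 seed = seed, k = k, verdicts = audit),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  for (m in c("SE", "SP", "ACC"))
    cat(sprintf("  %%%s  %.2f ± %.2f\n", m, x$mean[m], x$sd[m]))
  cat(sprintf("  MCC  %.2f ± %.2f\n", x$mean["MCC"], x$sd["MCC"]))
  invisible(x)
}

#' Independent-test evaluation against a fixed epitope database
#'
#' Classifies every positive and every negative against a fixed database and
#' summarizes the single resulting confusion table. Deterministic.
#'
#' @param positives,negatives test \code{\link{EpitopeSet}}s.
#' @param db the fixed epitope database (\code{\link{EpitopeSet}}).
#' @param params a \code{\link{SearchParams}} object.
#' @return a \code{"MetricSet"} (see \code{\link{confusionMetrics}}) with an
#'   additional \code{verdicts} audit data.frame attached as an attribute.
#' @export
holdoutEval <- function(positives, negatives, db, params = SearchParams()) {
  stopifnot(is(positives, "EpitopeSet"), is(negatives, "EpitopeSet"),
            is(db, "EpitopeSet"), length(positives) > 0,
            length(negatives) > 0, length(db) > 0)
  vp <- classifyPeptides(positives, db, params)
  vn <- classifyPeptides(negatives, db, params)
  m <- confusionMetrics(tp = sum(vp), fn = sum(!vp),
                        fp = sum(vn), tn = sum(!vn))
  attr(m, "verdicts") <- data.frame(
    id = c(names(vp), names(vn)),
    label = rep(c(1L, 0L), c(length(vp), length(vn))),
    verdict = ifelse(c(vp, vn), "epitope", "non-epitope"),
    stringsAsFactors = FALSE)
  m
}

#' Format evaluation results as a report table
#'
#' Renders a cross-validation result (mean ± population standard
#' deviation across folds, 2 decimals) or a single metric set as a one-row
#' table in TSV or markdown.
#'
#' @param results a \code{"CVResult"} or \code{"MetricSet"}.
#' @param format \code{"tsv"} or \code{"markdown"}.
#' @param label row label (e.g. the negative-dataset name).
#' @return character vector of report lines.
#' @export
reportMetrics <- function(results, format = c("tsv", "markdown"),
                          label = "run") {
  format <- match.arg(format)
  if (inherits(results, "CVResult")) {
    cells <- vapply(c("SE", "SP", "ACC", "MCC"), function(m)
      sprintf("%.2f ± %.2f", results$mean[m], results$sd[m]),
      character(1))
  } else if (inherits(results, "MetricSet")) {
    cells <- c(sprintf("%.2f", results$SE), sprintf("%.2f", results$SP),
               sprintf("%.2f", results$ACC), sprintf("%.2f", results$MCC))
  } else stop("results must be a CVResult or MetricSet")
  header <- c("dataset", "%SE", "%SP", "%ACC", "MCC")
  row <- c(label, cells)
  if (format == "tsv")
    c(paste(header, collapse = "\t"), paste(row, collapse = "\t"))
  else
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      paste0("| ", paste(row, collapse = " | "), " |"))
}
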