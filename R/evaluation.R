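## drop rf_confusion class and attributes, keep a plain numeric matrix
strip_confusion <- function(cm) {
  matrix(as.vector(unclass(cm)), nrow(cm), ncol(cm),
         dimnames = dimnames(cm))
}

#' Confusion-matrix metrics
#'
#' Computes the report metrics of a k x k confusion matrix with rows = true
#' class and columns = predicted class: row-wise sensitivity
#' `100 * cm[c, c] / row_sum(c)`, the column-wise "specificity as printed"
#' `100 * cm[c, c] / col_sum(c)` (numerically the positive predictive
#' value; the name follows the convention of the reference confusion
#' tables), overall accuracy `100 * trace / total` and the error
#' `100 - accuracy`.  Classes with empty rows or columns yield `NA`.
#'
#' @param cm A square count matrix (e.g. from [oob_confusion()]).
#' @return A list with `sensitivity`, `specificity_printed` (both named,
#'   in percent), `accuracy`, `error`, and a `rounded` copy of the metrics
#'   at one decimal for report output.
#' @export
confusion_metrics <- function(cm) {
  cm <- strip_confusion(cm)
  assert_that(nrow(cm) == ncol(cm) && nrow(cm) >= 1,
              "cm must be a square matrix")
  assert_that(sum(cm) > 0, "cm must contain counts")
  rs <- rowSums(cm)
  cs <- colSums(cm)
  sens <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  spec <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  names(sens) <- rownames(cm)
  names(spec) <- colnames(cm)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  list(sensitivity = sens,
       specificity_printed = spec,
       accuracy = acc,
       error = 100 - acc,
       rounded = list(sensitivity = round(sens, 1),
                      specificity_printed = round(spec, 1),
                      accuracy = round(acc, 1),
                      error = round(100 - acc, 1)))
}

#' Write a confusion matrix with appended metrics as CSV
#'
#' Layout mirrors the reference tables: the count matrix with a final
#' sensitivity column (row-wise, percent) and a final specificity row
#' (column-wise, percent).
#'
#' @param cm A square count matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- strip_confusion(cm)
  met <- confusion_metrics(cm)
  body <- cbind(as.data.frame(cm),
                `Sensitivity [%]` = met$rounded$sensitivity)
  spec_row <- c(met$rounded$specificity_printed, NA)
  out <- rbind(body, `Specificity [%]` = spec_row)
  write.csv(data.frame(class = rownames(out), out, check.names = FALSE),
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' Five-number summaries of class probabilities by true class
#'
#' Groups the samples by their true class and summarizes, per group and
#' per predicted class, the distribution of predicted probabilities with
#' the five-number summary (min, Q1, median, Q3, max; quartiles by linear
#' interpolation), the numbers underlying per-class probability boxplots.
#'
#' @param proba Probability matrix (samples x classes), rows summing to 1.
#' @param true_labels True class labels aligned with the rows.
#' @return A data frame with columns `true_class`, `predicted_class`,
#'   `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
probability_summary <- function(proba, true_labels) {
  proba <- as.matrix(proba)
  true_labels <- factor(true_labels,
                        levels = colnames(proba) %||%
                          levels(as.factor(true_labels)))
  rows <- list()
  for (tc in levels(true_labels)) {
    sel <- which(true_labels == tc & !is.na(true_labels) &
                   stats::complete.cases(proba))
    for (pc in colnames(proba)) {
      v <- proba[sel, pc]
      q <- if (length(v)) quantile(v, c(0, .25, .5, .75, 1), type = 7,
                                   names = FALSE) else rep(NA_real_, 5)
      rows[[length(rows) + 1]] <- data.frame(
        true_class = tc, predicted_class = pc,
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        n = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Overlap counts of selected-feature sets
#'
#' Counts all intersection regions of the selected sets of two or more
#' selection results (the numbers behind a Venn diagram).
#'
#' @param results A named list of `selection_result` objects (or plain
#'   character vectors of selected ids).
#' @return A data frame with one row per region: the membership pattern
#'   over the sets and the region count.  Region counts sum to the size of
#'   the union.
#' @export
selection_overlap <- function(results) {
  assert_that(length(results) >= 2, "need at least two selection results")
  sets <- lapply(results, function(r)
    if (inherits(r, "selection_result")) r$selected else as.character(r))
  nm <- names(sets) %||% sprintf("set%d", seq_along(sets))
  nm[nm == ""] <- sprintf("set%d", which(nm == ""))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  colnames(member) <- nm
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(patterns) <- nm
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  counts <- apply(patterns, 1, function(pat)
    sum(apply(member, 1, function(row) all(row == pat))))
  out <- cbind(patterns, count = as.integer(counts))
  rownames(out) <- NULL
  out
}
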