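#' LC-MS feature table
#'
#' The common currency of the package: a sample x feature intensity matrix
#' plus per-sample metadata (class labels for one or more classification
#' levels, batch, year) and per-feature metadata (m/z, retention time,
#' adduct label, adduct group).  Missing cells are `NA`.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Row and column names identify samples and features; default ids are
#'   generated when absent.
#' @param sample_meta Data frame with one row per sample (label schemes,
#'   `batch`, `year`, ...).  Row names must match the intensity row names.
#' @param feature_meta Data frame with one row per feature (`mz`, `rt`,
#'   `adduct_label`, `adduct_group`, ...).  Row names must match the
#'   intensity column names.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_meta = NULL, feature_meta = NULL) {
  assert_that(is.matrix(intensities) && is.numeric(intensities),
              "intensities must be a numeric matrix")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("sample_%03d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  assert_that(!anyDuplicated(colnames(intensities)), "feature ids must be unique")
  assert_that(!anyDuplicated(rownames(intensities)), "sample ids must be unique")
  if (is.null(sample_meta))
    sample_meta <- data.frame(row.names = rownames(intensities))
  if (is.null(feature_meta))
    feature_meta <- data.frame(row.names = colnames(intensities))
  assert_that(nrow(sample_meta) == nrow(intensities) &&
                all(rownames(sample_meta) == rownames(intensities)),
              "sample_meta rows must match intensity rows")
  assert_that(nrow(feature_meta) == ncol(intensities) &&
                all(rownames(feature_meta) == colnames(intensities)),
              "feature_meta rows must match intensity columns")
  structure(list(intensities = intensities, sample_meta = sample_meta,
                 feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  nmiss <- sum(is.na(x$intensities))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$intensities)))
  if (ncol(x$sample_meta))
    cat("  sample metadata:", paste(names(x$sample_meta), collapse = ", "), "\n")
  if (ncol(x$feature_meta))
    cat("  feature metadata:", paste(names(x$feature_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Number of samples / features of a feature table
#' @param table A [feature_table()].
#' @return Integer count.
#' @export
n_samples <- function(table) nrow(table$intensities)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$intensities)

#' Subset a feature table
#'
#' @param table A [feature_table()].
#' @param samples,features Index vectors (ids, positions or logical).
#' @return A `feature_table` restricted to the selection.
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  s <- samples %||% seq_len(n_samples(table))
  f <- features %||% seq_len(n_features(table))
  feature_table(table$intensities[s, f, drop = FALSE],
                table$sample_meta[s, , drop = FALSE],
                table$feature_meta[f, , drop = FALSE])
}

#' Read and write feature tables as CSV
#'
#' Three comma-separated UTF-8 files are used: the intensity matrix (samples
#' as rows, header row of feature ids, first column of sample ids, missing
#' cells empty or `NA`) and one metadata table each for samples and features.
#'
#' @param table A [feature_table()].
#' @param intensities_csv,samples_csv,features_csv File paths.  The metadata
#'   paths may be `NULL` when no metadata is present (reading) or wanted
#'   (writing).
#' @return `write_feature_table` returns the paths invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, intensities_csv, samples_csv = NULL,
                                features_csv = NULL) {
  df <- data.frame(sample_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE)
  write.csv(df, intensities_csv, row.names = FALSE, na = "")
  if (!is.null(samples_csv)) {
    sm <- data.frame(sample_id = rownames(table$sample_meta),
                     table$sample_meta, check.names = FALSE)
    write.csv(sm, samples_csv, row.names = FALSE, na = "")
  }
  if (!is.null(features_csv)) {
    fm <- data.frame(feature_id = rownames(table$feature_meta),
                     table$feature_meta, check.names = FALSE)
    write.csv(fm, features_csv, row.names = FALSE, na = "")
  }
  invisible(c(intensities_csv, samples_csv, features_csv))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(intensities_csv, samples_csv = NULL,
                               features_csv = NULL) {
  df <- read.csv(intensities_csv, check.names = FALSE,
                 na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  sm <- NULL
  if (!is.null(samples_csv)) {
    sdf <- read.csv(samples_csv, check.names = FALSE, na.strings = c("", "NA"))
    sm <- sdf[, -1, drop = FALSE]
    rownames(sm) <- as.character(sdf[[1]])
    sm <- sm[rownames(m), , drop = FALSE]
  }
  fm <- NULL
  if (!is.null(features_csv)) {
    fdf <- read.csv(features_csv, check.names = FALSE, na.strings = c("", "NA"))
    fm <- fdf[, -1, drop = FALSE]
    rownames(fm) <- as.character(fdf[[1]])
    fm <- fm[colnames(m), , drop = FALSE]
  }
  feature_table(m, sm, fm)
}
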