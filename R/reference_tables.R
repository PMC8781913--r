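#' Reference asparagus classification tables
#'
#' Reported results of a multi-level LC-MS classification of white
#' asparagus, shipped as plain-text fixtures for validation and examples:
#' the out-of-bag confusion matrices for the geographical-origin (5
#' classes, 317 samples) and botanical-variety (4 classes, 150 samples)
#' levels, and the per-year sample counts of both label schemes.  The
#' variety matrix is the version consistent with the class sizes and with
#' every reported per-class metric.
#'
#' @param level `"origin"` or `"variety"`.
#' @return `reference_confusion`: a square integer count matrix (rows =
#'   true class, columns = predicted class).  `reference_sample_counts`:
#'   a class x year count matrix.
#' @export
reference_confusion <- function(level = c("origin", "variety")) {
  level <- match.arg(level)
  path <- system.file("extdata",
                      sprintf("asparagus_%s_confusion.csv", level),
                      package = "rfmetab", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname reference_confusion
#' @export
reference_sample_counts <- function(level = c("origin", "variety")) {
  level <- match.arg(level)
  path <- system.file("extdata",
                      sprintf("asparagus_%s_year_counts.csv", level),
                      package = "rfmetab", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
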