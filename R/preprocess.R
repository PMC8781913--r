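#' Consolidate adduct groups to their most intense feature
#'
#' Within each adduct group (features annotated with the same
#' `adduct_group` in the feature metadata), only the feature with the
#' highest mean intensity across samples (missing cells ignored) is
#' retained.  Features labelled as ammonium adducts (adduct label containing
#' `NH3` or `NH4`) are never merged into a group and always pass through,
#' as do features without a group annotation.
#'
#' @param table A [feature_table()].
#' @return A `feature_table` with at most one non-ammonium feature per
#'   adduct group.
#' @export
consolidate_adducts <- function(table) {
  fm <- table$feature_meta
  if (!"adduct_group" %in% names(fm)) return(table)
  grp <- as.character(fm$adduct_group)
  ammonium <- if ("adduct_label" %in% names(fm))
    grepl("NH3|NH4", fm$adduct_label) else rep(FALSE, nrow(fm))
  grp[ammonium] <- NA_character_  # taken into account separately
  keep <- rep(TRUE, n_features(table))
  for (g in unique(grp[!is.na(grp)])) {
    members <- which(!is.na(grp) & grp == g)
    if (length(members) < 2) next
    mu <- colMeans(table$intensities[, members, drop = FALSE], na.rm = TRUE)
    if (all(is.nan(mu))) {
      warning(sprintf("adduct group '%s' has only all-missing features; %s",
                      g, "retaining the first arbitrarily"))
      best <- 1L
    } else {
      best <- which.max(ifelse(is.nan(mu), -Inf, mu))
    }
    keep[members[-best]] <- FALSE
  }
  subset_table(table, features = keep)
}

#' Prevalence filter
#'
#' Keeps exactly the features that are observed (non-missing) in at least
#' `min_fraction` of the samples; the boundary is inclusive.
#'
#' @param table A [feature_table()].
#' @param min_fraction Minimum fraction of samples a feature must be
#'   observed in, in `(0, 1]`.  Default 0.8.
#' @return A filtered `feature_table`.
#' @export
prevalence_filter <- function(table, min_fraction = 0.8) {
  assert_that(min_fraction > 0 && min_fraction <= 1,
              "min_fraction must be in (0, 1]")
  prev <- colMeans(!is.na(table$intensities))
  keep <- prev >= min_fraction
  if (!any(keep))
    warning("prevalence filter removed every feature")
  subset_table(table, features = keep)
}

#' Iterative random-forest imputation of missing intensities
#'
#' missForest-style scheme: missing cells are initialized with column
#' means; features are visited in order of increasing missingness, each
#' regressed on all other features with a regression forest and its missing
#' cells overwritten by the forest predictions.  Iteration stops when the
#' sum of squared changes of the imputed values increases for the first
#' time (the previous iterate is returned) or after `max_iter` iterations.
#' Observed cells are never altered.
#'
#' @param table A [feature_table()].
#' @param seed Integer seed (the per-feature forests are deterministic
#'   given it).
#' @param max_iter Maximum number of sweeps over the features.
#' @param num_trees,mtry Regression-forest size per feature; `mtry`
#'   defaults to `floor(sqrt(p - 1))`.
#' @return A list with elements `table` (complete `feature_table`) and
#'   `report` (a `preprocess_report` fragment with the iteration count).
#' @export
impute_rf <- function(table, seed = 1, max_iter = 10, num_trees = 100,
                      mtry = NULL) {
  x <- table$intensities
  miss <- is.na(x)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing))
    stop2(sprintf("feature(s) with no observed values cannot be imputed: %s",
                  paste(colnames(x)[all_missing], collapse = ", ")))
  if (!any(miss)) {
    return(list(table = table,
                report = list(imputation_iterations = 0L)))
  }
  p <- ncol(x)
  mtry <- mtry %||% max(1L, floor(sqrt(p - 1)))
  ## column-mean start
  for (j in which(colSums(miss) > 0))
    x[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
  visit <- order(colSums(miss))
  visit <- visit[colSums(miss)[visit] > 0]

  prev_delta <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    x_new <- x
    for (j in visit) {
      df <- as.data.frame(x_new[, -j, drop = FALSE])
      names(df) <- paste0("V", seq_len(ncol(df)))
      df$.y <- x_new[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y",
        data = df[!miss[, j], , drop = FALSE],
        num.trees = num_trees, mtry = min(mtry, p - 1),
        seed = derive_seed(seed, sprintf("impute_%d_%d", it, j)),
        num.threads = 1, verbose = FALSE)
      pred <- predict(fit, df[miss[, j], , drop = FALSE],
                      num.threads = 1)$predictions
      x_new[miss[, j], j] <- pred
    }
    delta <- sum((x_new[miss] - x[miss])^2)
    if (delta > prev_delta) {
      iters <- it - 1L  # divergence: keep the previous iterate (current x)
      break
    }
    x <- x_new
    prev_delta <- delta
    iters <- it
  }
  out <- table
  out$intensities <- x
  list(table = out, report = list(imputation_iterations = iters))
}

#' Batch-wise autoscaling
#'
#' Within each measurement batch every feature column is centered to mean 0
#' and scaled to sample standard deviation 1 (denominator n - 1).  Columns
#' that are constant within a batch become all-zero for that batch; a batch
#' with a single sample is centered but not scaled (with a warning).
#'
#' @param table A complete [feature_table()] whose sample metadata carries a
#'   `batch` column.
#' @return An autoscaled `feature_table`.
#' @export
autoscale_by_batch <- function(table) {
  assert_that(!anyNA(table$intensities),
              "autoscaling requires a complete table; impute first")
  assert_that("batch" %in% names(table$sample_meta),
              "sample metadata must contain a 'batch' column")
  x <- table$intensities
  batch <- as.character(table$sample_meta$batch)
  for (b in unique(batch)) {
    rows <- which(batch == b)
    xb <- x[rows, , drop = FALSE]
    mu <- colMeans(xb)
    xb <- sweep(xb, 2, mu)
    if (length(rows) == 1) {
      warning(sprintf("batch '%s' has a single sample; scaling skipped", b))
    } else {
      sds <- apply(xb, 2, stats::sd)
      nz <- sds > 0
      xb[, nz] <- sweep(xb[, nz, drop = FALSE], 2, sds[nz], `/`)
      xb[, !nz] <- 0
    }
    x[rows, ] <- xb
  }
  out <- table
  out$intensities <- x
  out
}

#' Full preprocessing chain for an LC-MS feature table
#'
#' Fixed stage order: adduct consolidation, prevalence filtering, iterative
#' random-forest imputation, batch-wise autoscaling.
#'
#' @param table A [feature_table()].
#' @param min_fraction Prevalence threshold, see [prevalence_filter()].
#' @param seed Seed for the imputation forests.
#' @param impute_num_trees Trees per imputation forest.
#' @param max_iter Maximum imputation sweeps.
#' @return A list with elements `table` (preprocessed) and `report`
#'   (class `preprocess_report`: feature counts per stage, imputation
#'   iterations, per-batch means/sds used for scaling).
#' @export
preprocess <- function(table, min_fraction = 0.8, seed = 1,
                       impute_num_trees = 100, max_iter = 10) {
  n_in <- n_features(table)
  tab <- consolidate_adducts(table)
  n_add <- n_features(tab)
  tab <- prevalence_filter(tab, min_fraction)
  n_prev <- n_features(tab)
  imp <- impute_rf(tab, seed = seed, max_iter = max_iter,
                   num_trees = impute_num_trees)
  tab <- imp$table
  ## per-batch statistics, recorded for the report before scaling
  batch <- as.character(tab$sample_meta$batch)
  stats_by_batch <- lapply(split(seq_len(n_samples(tab)), batch), function(rows) {
    xb <- tab$intensities[rows, , drop = FALSE]
    list(mean = colMeans(xb),
         sd = if (length(rows) > 1) apply(xb, 2, stats::sd) else
           rep(NA_real_, ncol(xb)))
  })
  tab <- autoscale_by_batch(tab)
  report <- structure(list(
    n_features_in = n_in,
    n_features_after_adducts = n_add,
    n_features_after_prevalence = n_prev,
    imputation_iterations = imp$report$imputation_iterations,
    batch_stats = stats_by_batch), class = "preprocess_report")
  list(table = tab, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report A `preprocess_report` from [preprocess()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  out <- report
  out$batch_stats <- lapply(out$batch_stats, function(s)
    list(mean = as.list(s$mean), sd = as.list(s$sd)))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
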