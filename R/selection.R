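#' Boruta configuration
#'
#' @param p_value Confidence level of the binomial decision test.
#' @param max_runs Maximum number of importance-source runs.
#' @param multiple_testing `"none"` (the stated confidence level is the
#'   operative per-feature level) or `"bonferroni"`.
#' @param forest A [forest_config()] used for every importance run; its
#'   `importance` field selects the importance source (`"air"` is the
#'   corrected impurity importance; `"none"` is promoted to `"air"`).
#' @return An object of class `boruta_config`.
#' @export
boruta_config <- function(p_value = 0.01, max_runs = 100,
                          multiple_testing = c("none", "bonferroni"),
                          forest = forest_config(n_surrogates = 0,
                                                 importance = "air")) {
  assert_that(p_value > 0 && p_value < 1, "p_value must be in (0, 1)")
  assert_that(max_runs >= 1, "max_runs must be >= 1")
  if (forest$importance == "none") forest$importance <- "air"
  structure(list(p_value = p_value, max_runs = as.integer(max_runs),
                 multiple_testing = match.arg(multiple_testing),
                 forest = forest),
            class = "boruta_config")
}

#' Two-sided binomial decisions on Boruta hit counts
#'
#' A feature with `h` hits in `r` runs is confirmed when the two-sided
#' exact binomial test (success probability 0.5) is significant in the
#' upper tail, rejected when significant in the lower tail, and left
#' undecided otherwise.
#'
#' @param hits Integer vector of hit counts.
#' @param runs Number of completed runs.
#' @param p_value Significance level.
#' @return Character vector: `"confirmed"`, `"rejected"` or `"tentative"`.
#' @export
boruta_decisions <- function(hits, runs, p_value = 0.01) {
  p_up <- pbinom(hits - 1, runs, 0.5, lower.tail = FALSE)  # P(X >= h)
  p_dn <- pbinom(hits, runs, 0.5)                          # P(X <= h)
  p_two <- pmin(1, 2 * pmin(p_up, p_dn))
  out <- rep("tentative", length(hits))
  out[p_two < p_value & hits > runs / 2] <- "confirmed"
  out[p_two < p_value & hits < runs / 2] <- "rejected"
  out
}

new_selection_result <- function(method, features, score, threshold,
                                 decision, extra = list()) {
  res <- c(list(method = method,
                feature = features,
                score = score,
                threshold = threshold,
                decision = decision,
                selected = features[decision == "confirmed"]),
           extra)
  structure(res, class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method: %s\n", x$method))
  cat(sprintf("  confirmed %d / rejected %d / tentative %d of %d features\n",
              sum(x$decision == "confirmed"), sum(x$decision == "rejected"),
              sum(x$decision == "tentative"), length(x$feature)))
  invisible(x)
}

#' Write a selection result as CSV plus JSON summary
#'
#' @param result A `selection_result`.
#' @param csv_path,json_path Output file paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_selection_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(data.frame(feature = result$feature, score = result$score,
                         decision = result$decision),
              csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(method = result$method, threshold = result$threshold,
           n_confirmed = sum(result$decision == "confirmed"),
           runs = result$runs, seed = result$seed,
           selected = result$selected),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' All-relevant feature selection with Boruta shadow variables
#'
#' Iterative scheme: each run appends one freshly permuted shadow copy per
#' undecided feature (at least 5 shadows), fits an importance forest on the
#' augmented table, and scores a "hit" for every undecided feature whose
#' importance exceeds the maximum shadow importance.  After each run a
#' two-sided exact binomial test on the hit counts confirms or rejects
#' features at the configured level; the loop ends when no feature is
#' undecided or `max_runs` is reached, and survivors are labelled
#' tentative.  Rejected features are removed from subsequent runs.
#'
#' @param table A preprocessed [feature_table()] or matrix.
#' @param labels Class labels.
#' @param config A [boruta_config()].
#' @param seed Integer seed for the shadow permutations and per-run forest
#'   seeds.
#' @return A `selection_result` with the hit fraction as score and the
#'   full importance history in `$importance_history`.
#' @export
boruta_select <- function(table, labels, config = boruta_config(), seed = 1) {
  x <- resolve_x(table)
  labels <- droplevels(as.factor(labels))
  p <- ncol(x)
  feats <- colnames(x) %||% sprintf("V%d", seq_len(p))
  colnames(x) <- feats
  if (config$max_runs < 5)
    warning("fewer than 5 Boruta runs; expect everything tentative")
  level <- config$p_value /
    (if (config$multiple_testing == "bonferroni") p else 1)

  decision <- rep("tentative", p)
  hits <- integer(p)
  runs_done <- 0L
  history <- list()
  for (run in seq_len(config$max_runs)) {
    und <- which(decision == "tentative")
    if (!length(und)) break
    active <- which(decision != "rejected")
    shadow_src <- und
    if (length(shadow_src) < 5)
      shadow_src <- rep_len(shadow_src, 5)
    shadows <- withr::with_seed(
      derive_seed(seed, sprintf("boruta_shadow_%d", run)),
      apply(x[, shadow_src, drop = FALSE], 2, sample))
    colnames(shadows) <- sprintf("shadow_%d", seq_len(ncol(shadows)))
    xrun <- cbind(x[, active, drop = FALSE], shadows)
    fc <- config$forest
    fc$mtry <- config$forest$mtry %||% mtry_default(ncol(xrun))
    fc$n_surrogates <- config$forest$n_surrogates %||% 0L
    fc$seed <- derive_seed(seed, sprintf("boruta_forest_%d", run))
    forest <- fit_forest(xrun, labels, fc)
    imp <- forest$importance
    shadow_max <- max(imp[colnames(shadows)])
    hits[und] <- hits[und] +
      as.integer(imp[feats[und]] > shadow_max)
    runs_done <- run
    history[[run]] <- imp
    dec <- boruta_decisions(hits[und], run, level)
    decision[und] <- dec
  }
  score <- ifelse(runs_done > 0, hits / runs_done, NA_real_)
  new_selection_result(
    "boruta", feats, score, threshold = NA_real_, decision,
    extra = list(hits = hits, runs = runs_done, seed = seed,
                 p_value = config$p_value,
                 importance_history = history))
}

#' Surrogate minimal depth of every feature
#'
#' Per tree, a feature's depth is the minimal depth over the nodes where it
#' is the primary splitter or appears in the stored surrogate list; a
#' feature absent from a tree is assigned that tree's maximal node depth.
#' The surrogate minimal depth (SMD) is the mean over trees; lower values
#' mean more important, and features that only ever mimic other features'
#' splits (e.g. adducts of the same metabolite) still obtain small values.
#'
#' @param forest An `rf_forest` grown with `n_surrogates >= 1`.
#' @return A named numeric vector of SMD values.
#' @export
surrogate_min_depth <- function(forest) {
  assert_not_air(forest)
  if (forest$config$n_surrogates < 1)
    stop2(paste("forest was grown without surrogates (s = 0);",
                "refit with n_surrogates >= 1 or use plain minimal depth"))
  stats::setNames(cpp_smd(forest$trees, forest$p), forest$feature_names)
}

#' SMD configuration
#'
#' @param s Surrogates per node; `NULL` resolves to
#'   `floor(0.05 p)` of the augmented table at selection time.
#' @param null_copies Number of permuted-feature null copies appended to
#'   the table; `NULL` resolves to `min(p, 100)`.
#' @param threshold_rule `"null_mean"` (threshold = mean SMD of the null
#'   copies) or `"null_quantile"` with `quantile` giving the level.
#' @param quantile Quantile level for `"null_quantile"`.
#' @param forest A [forest_config()] for the single surrogate forest.
#' @return An object of class `smd_config`.
#' @export
smd_config <- function(s = NULL, null_copies = NULL,
                       threshold_rule = c("null_mean", "null_quantile"),
                       quantile = 0.05,
                       forest = forest_config()) {
  structure(list(s = s, null_copies = null_copies,
                 threshold_rule = match.arg(threshold_rule),
                 quantile = quantile, forest = forest),
            class = "smd_config")
}

#' Feature selection by thresholded surrogate minimal depth
#'
#' Augments the table with permuted null copies of (a subset of) its
#' features, fits one surrogate forest on the augmented table, computes
#' SMD for every column and confirms the real features whose SMD falls
#' below a threshold estimated from the null copies (their mean by
#' default, or a lower quantile).
#'
#' @param table A preprocessed [feature_table()] or matrix.
#' @param labels Class labels.
#' @param config An [smd_config()].
#' @param seed Integer seed for the null-copy permutations and the forest.
#' @return A `selection_result` with SMD as score (lower = more
#'   important); `$null_smd` holds the null-copy SMD values.
#' @export
smd_select <- function(table, labels, config = smd_config(), seed = 1) {
  x <- resolve_x(table)
  labels <- droplevels(as.factor(labels))
  p <- ncol(x)
  feats <- colnames(x) %||% sprintf("V%d", seq_len(p))
  colnames(x) <- feats
  n_null <- config$null_copies %||% min(p, 100L)
  nulls <- withr::with_seed(derive_seed(seed, "smd_nulls"), {
    src <- if (n_null <= p) sample.int(p, n_null) else
      sample.int(p, n_null, replace = TRUE)
    apply(x[, src, drop = FALSE], 2, sample)
  })
  colnames(nulls) <- sprintf("null_%d", seq_len(n_null))
  xaug <- cbind(x, nulls)
  fc <- config$forest
  fc$mtry <- config$forest$mtry %||% mtry_default(ncol(xaug))
  fc$n_surrogates <- config$s %||% config$forest$n_surrogates %||%
    n_surrogates_default(ncol(xaug))
  if (fc$n_surrogates < 1)
    stop2("SMD needs s >= 1 surrogate splits per node")
  fc$seed <- derive_seed(seed, "smd_forest")
  forest <- fit_forest(xaug, labels, fc)
  smd <- surrogate_min_depth(forest)
  null_smd <- smd[colnames(nulls)]
  real_smd <- smd[feats]
  if (length(unique(null_smd)) == 1)
    stop2("null-copy SMD values are degenerate (all equal)")
  threshold <- switch(config$threshold_rule,
    null_mean = mean(null_smd),
    null_quantile = as.numeric(quantile(null_smd, config$quantile, type = 7)))
  decision <- ifelse(real_smd < threshold, "confirmed", "rejected")
  new_selection_result(
    "smd", feats, real_smd, threshold, decision,
    extra = list(null_smd = null_smd, seed = seed, forest = forest))
}
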