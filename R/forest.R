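#' Random-forest configuration
#'
#' Defaults follow the study parameterization for LC-MS feature tables:
#' 10,000 trees, `mtry = floor(p^(3/4))` candidate features per node,
#' terminal nodes of size 1, `s = floor(0.05 p)` surrogate splits per node,
#' and inverse-class-frequency case weights so that samples from rare
#' classes are drawn more frequently into the bootstrap samples.
#'
#' @param ntree Number of trees.
#' @param mtry Candidate features per node; `NULL` resolves to
#'   [mtry_default()] at fit time.
#' @param min_node_size Minimum node size eligible for splitting; 1 grows
#'   trees to purity.
#' @param n_surrogates Surrogate splits stored per internal node; `NULL`
#'   resolves to [n_surrogates_default()]; 0 disables surrogates.
#' @param case_weight_mode `"inverse_class_frequency"` or `"none"`.
#' @param mode `"classification"` or `"probability"` (probability machine:
#'   leaf class proportions averaged over trees).
#' @param importance `"none"`, `"air"` (corrected impurity importance),
#'   `"impurity"` (raw Gini importance, biased in favor of features with
#'   many split points; kept for comparison) or `"permutation"` (OOB
#'   accuracy decrease).
#' @param seed Integer seed; each tree derives its own RNG stream from
#'   `(seed, tree index)`, so results are independent of execution order.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(ntree = 10000, mtry = NULL, min_node_size = 1,
                          n_surrogates = NULL,
                          case_weight_mode = c("inverse_class_frequency",
                                               "none"),
                          mode = c("classification", "probability"),
                          importance = c("none", "air", "impurity",
                                         "permutation"),
                          seed = 1) {
  assert_that(ntree >= 1, "ntree must be >= 1")
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 n_surrogates = n_surrogates,
                 case_weight_mode = match.arg(case_weight_mode),
                 mode = match.arg(mode),
                 importance = match.arg(importance),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Default mtry and surrogate count for p features
#'
#' `mtry = floor(p^(3/4))` and `s = floor(0.05 p)`: for the study's 718
#' features these give 138 candidate features and 35 surrogate splits.
#'
#' @param p Number of features.
#' @return Integer parameter value.
#' @export
mtry_default <- function(p) as.integer(floor(p^0.75))

#' @rdname mtry_default
#' @export
n_surrogates_default <- function(p) as.integer(floor(0.05 * p))

#' Gini impurity of a node
#'
#' `1 - sum((n_c / n)^2)` over the class counts of a node; ranges from 0
#' (pure node) to `1 - 1/k`.
#'
#' @param class_counts Nonnegative integer vector of per-class counts with
#'   a positive sum.
#' @return The Gini impurity.
#' @export
gini_impurity <- function(class_counts) {
  assert_that(all(class_counts >= 0) && sum(class_counts) > 0,
              "class counts must be nonnegative with positive sum")
  1 - sum((class_counts / sum(class_counts))^2)
}

#' Best Gini split at a single node
#'
#' Among the candidate features, finds the (feature, threshold) pair
#' maximizing the weighted Gini decrease, with thresholds evaluated at
#' midpoints between consecutive distinct sorted values.  Ties are broken
#' by lowest feature index, then lowest threshold.
#'
#' @param x Numeric matrix of node samples (rows) by features (columns).
#' @param y Class vector (factor or coercible) aligned with the rows.
#' @param candidate_features Integer column indices to consider.
#' @return A list with `feature`, `threshold` and `decrease`, or `NULL`
#'   when no candidate admits a valid split (the node becomes a leaf).
#' @export
best_split <- function(x, y, candidate_features = seq_len(ncol(x))) {
  y <- as.factor(y)
  res <- cpp_best_split(as.matrix(x), as.integer(y) - 1L, nlevels(y),
                        as.integer(candidate_features))
  if (!res$found) return(NULL)
  list(feature = res$feature, threshold = res$threshold,
       decrease = res$decrease)
}

#' Surrogate splits for a primary split at a single node
#'
#' For every feature other than the primary one, finds the threshold (and
#' direction, allowing agreement by swapping children) that maximizes the
#' agreement `A` with the primary left/right assignment, and computes the
#' adjusted agreement `(A - maj) / (1 - maj)` where `maj` is the majority
#' fraction of the primary split.  The `s` features with the largest
#' positive adjusted agreement are returned in descending order.
#'
#' @param x Numeric matrix of node samples by features.
#' @param primary_feature Column index of the primary splitter.
#' @param threshold Primary split threshold (left: `x <= threshold`).
#' @param s Maximum number of surrogates to keep.
#' @return A data frame with columns `feature`, `threshold`, `flip`,
#'   `adjusted_agreement`.
#' @export
find_surrogates <- function(x, primary_feature, threshold,
                            s = ncol(x) - 1) {
  x <- as.matrix(x)
  is_left <- as.integer(x[, primary_feature] <= threshold)
  cpp_find_surrogates(x, is_left, as.integer(primary_feature), as.integer(s))
}

assert_not_air <- function(forest) {
  if (isTRUE(forest$air))
    stop2(paste("this forest was grown with AIR pseudo features and is an",
                "importance source only; refit with importance = 'none'"))
  invisible(TRUE)
}

resolve_x <- function(table) {
  if (inherits(table, "feature_table")) table$intensities else as.matrix(table)
}

#' Case weights for bootstrap sampling
#'
#' Inverse class frequency: `w_i = 1 / (k * n_class(i))`, normalized to sum
#' one, so every class contributes equal total weight and rare classes are
#' sampled more frequently into the bootstrap samples.
#'
#' @param labels Factor of class labels.
#' @param mode `"inverse_class_frequency"` or `"none"`.
#' @return Numeric weight vector summing to 1.
#' @export
case_weights <- function(labels, mode = "inverse_class_frequency") {
  labels <- as.factor(labels)
  n <- length(labels)
  if (mode == "none") return(rep(1 / n, n))
  tab <- table(labels)
  w <- 1 / (nlevels(labels) * as.numeric(tab[labels]))
  w / sum(w)
}

#' Fit a random forest with surrogate splits
#'
#' Grows `ntree` Gini classification trees on bootstrap samples of size n
#' drawn with replacement with probabilities proportional to the case
#' weights.  At each node `mtry` features are drawn uniformly without
#' replacement as split candidates; nodes are split until pure or below the
#' minimum size.  When `n_surrogates > 0`, surrogate splits over all other
#' features are recorded at every internal node together with their
#' adjusted agreement.  With `importance = "air"`, one row permutation per
#' tree defines a pseudo copy of every feature; the candidate pool doubles
#' and pseudo features are genuinely split on when they win, so the
#' corrected importance (actual-credit minus pseudo-credit) is exactly
#' mean-zero for uninformative features.  AIR forests are importance
#' sources only and cannot be used for prediction or surrogate analysis.
#'
#' @param table A [feature_table()] without missing cells, or a numeric
#'   matrix.
#' @param labels Class labels aligned with the samples (factor or
#'   coercible); at least two classes, no `NA`.
#' @param config A [forest_config()].
#' @return An object of class `rf_forest`.
#' @export
fit_forest <- function(table, labels, config = forest_config()) {
  x <- resolve_x(table)
  assert_that(!anyNA(x), "the feature matrix must not contain missing cells")
  labels <- droplevels(as.factor(labels))
  assert_that(!anyNA(labels), "labels must not contain NA")
  assert_that(length(labels) == nrow(x), "labels must align with samples")
  if (nlevels(labels) < 2)
    stop2("labels contain a single class; at least two are required")
  p <- ncol(x)
  air <- config$importance == "air"
  mtry <- as.integer(config$mtry %||% mtry_default(p))
  assert_that(mtry >= 1 && mtry <= (if (air) 2 * p else p),
              "mtry must be in [1, p] ([1, 2p] with AIR's pseudo features)")
  s <- as.integer(config$n_surrogates %||% n_surrogates_default(p))
  assert_that(s >= 0 && s <= p - 1, "n_surrogates must be in [0, p - 1]")
  if (air && s > 0) {
    ## AIR forests are importance sources; pseudo-feature splits make their
    ## trees unusable for surrogate bookkeeping
    s <- 0L
  }
  w <- case_weights(labels, config$case_weight_mode)
  fit <- cpp_fit_forest(x, as.integer(labels) - 1L, nlevels(labels), w,
                        config$ntree, mtry, config$min_node_size, s,
                        config$importance == "air",
                        as.double(config$seed))
  importance <- switch(config$importance,
    none = NULL,
    air = fit$importance_actual - fit$importance_shadow,
    impurity = fit$importance_actual,
    permutation = NULL)  # filled in below, needs the assembled forest
  resolved <- config
  resolved$mtry <- mtry
  resolved$n_surrogates <- s
  forest <- structure(list(
    trees = fit$trees, inbag = fit$inbag, p = p, n = nrow(x),
    classes = levels(labels), feature_names = colnames(x) %||%
      sprintf("V%d", seq_len(p)),
    train_x = x, air = air,
    config = resolved,
    importance = if (!is.null(importance))
      stats::setNames(importance, colnames(x)) else NULL),
    class = "rf_forest")
  if (config$importance == "permutation")
    forest$importance <- permutation_importance(forest, x, labels)
  forest
}

#' @export
print.rf_forest <- function(x, ...) {
  cat(sprintf("<rf_forest> %d trees, %d samples, %d features, classes: %s\n",
              length(x$trees), x$n, x$p, paste(x$classes, collapse = ", ")))
  cat(sprintf("  mode: %s, mtry: %d, surrogates/node: %d, seed: %d\n",
              x$config$mode, x$config$mtry, x$config$n_surrogates,
              x$config$seed))
  invisible(x)
}

## per-tree class votes (majority of the landed leaf, ties to the lowest
## class index) accumulated into an n x k vote-count matrix
vote_matrix <- function(forest, x, tree_filter = NULL) {
  leaves <- cpp_leaf_ids(forest$trees, x)
  n <- nrow(x)
  k <- length(forest$classes)
  votes <- matrix(0L, n, k)
  use <- tree_filter %||% matrix(TRUE, n, length(forest$trees))
  for (t in seq_along(forest$trees)) {
    rows <- which(use[, t])
    if (!length(rows)) next
    cnt <- forest$trees[[t]]$counts
    cls <- max.col(cnt[leaves[rows, t], , drop = FALSE], ties.method = "first")
    idx <- cbind(rows, cls)
    votes[idx] <- votes[idx] + 1L
  }
  votes
}

proba_matrix <- function(forest, x, tree_filter = NULL) {
  leaves <- cpp_leaf_ids(forest$trees, x)
  n <- nrow(x)
  k <- length(forest$classes)
  acc <- matrix(0, n, k)
  ntrees_used <- numeric(n)
  use <- tree_filter %||% matrix(TRUE, n, length(forest$trees))
  for (t in seq_along(forest$trees)) {
    rows <- which(use[, t])
    if (!length(rows)) next
    cnt <- forest$trees[[t]]$counts
    prop <- cnt[leaves[rows, t], , drop = FALSE]
    prop <- prop / rowSums(prop)
    acc[rows, ] <- acc[rows, ] + prop
    ntrees_used[rows] <- ntrees_used[rows] + 1
  }
  acc / ifelse(ntrees_used == 0, NA_real_, ntrees_used)
}

#' Predict classes with a forest
#'
#' Each tree votes the majority class of the leaf the sample lands in; the
#' forest returns the plurality vote, with ties broken by the lowest class
#' index.
#'
#' @param object An `rf_forest`.
#' @param newdata A [feature_table()] or matrix with the forest's features.
#' @param ... Unused.
#' @return A factor of predicted classes.
#' @export
predict.rf_forest <- function(object, newdata, ...) {
  assert_not_air(object)
  x <- resolve_x(newdata)
  assert_that(ncol(x) == object$p,
              "newdata feature count does not match the forest")
  votes <- vote_matrix(object, x)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Class probabilities from a probability forest
#'
#' Per sample, the mean over trees of the landed leaf's class-proportion
#' vector (the probability-machine estimator).  With `oob_only = TRUE` the
#' mean runs only over trees for which the sample is out-of-bag; samples
#' that are in-bag for every tree yield an `NA` row.
#'
#' @param forest An `rf_forest` grown with `mode = "probability"`.
#' @param table A [feature_table()] or matrix.  For `oob_only = TRUE` this
#'   must be the training table in the original row order.
#' @param oob_only Restrict averaging to out-of-bag trees.
#' @return A numeric matrix (samples x classes); rows sum to 1.
#' @export
predict_proba <- function(forest, table, oob_only = FALSE) {
  assert_not_air(forest)
  assert_that(forest$config$mode == "probability",
              "predict_proba requires a forest grown in probability mode")
  x <- resolve_x(table)
  assert_that(ncol(x) == forest$p,
              "table feature count does not match the forest")
  filter <- NULL
  if (oob_only) {
    assert_that(nrow(x) == forest$n,
                "oob_only requires the training samples")
    filter <- forest$inbag == 0
    if (any(rowSums(filter) == 0))
      warning("some samples are in-bag for every tree; their rows are NA")
  }
  out <- proba_matrix(forest, x, filter)
  dimnames(out) <- list(rownames(x), forest$classes)
  out
}

#' Out-of-bag confusion matrix
#'
#' Each sample is predicted by the plurality vote of the trees for which it
#' is out-of-bag; counts are tabulated with rows = true class and columns =
#' predicted class.  The OOB error is `1 - trace/total`.
#'
#' @param forest An `rf_forest` fitted on these samples.
#' @param labels True class labels in training row order.
#' @return An object of class `rf_confusion` (a k x k count matrix with an
#'   `oob_error` attribute).
#' @export
oob_confusion <- function(forest, labels) {
  assert_not_air(forest)
  labels <- factor(labels, levels = forest$classes)
  assert_that(length(labels) == forest$n,
              "labels must align with the training samples")
  oob <- forest$inbag == 0
  never <- rowSums(oob) == 0
  if (any(never))
    warning(sprintf("%d sample(s) never out-of-bag; excluded", sum(never)))
  x <- forest$train_x
  if (is.null(x))
    stop2("oob_confusion requires a forest with retained training data")
  votes <- vote_matrix(forest, x, oob)
  keep <- !never
  pred <- factor(forest$classes[max.col(votes[keep, , drop = FALSE],
                                        ties.method = "first")],
                 levels = forest$classes)
  cm <- table(true = labels[keep], predicted = pred)
  structure(unclass(cm), class = "rf_confusion",
            oob_error = 1 - sum(diag(cm)) / sum(cm))
}

#' Corrected impurity importance (AIR)
#'
#' Fits a forest with `importance = "air"` and returns the per-feature
#' corrected impurity importance: split-gain credit earned by a feature's
#' actual values minus the credit earned by its per-tree permuted pseudo
#' copy.  Scores can be negative and have expectation 0 for features
#' unrelated to the labels, removing the split-point bias of the raw Gini
#' importance.
#'
#' @param table A [feature_table()] or matrix without missing cells.
#' @param labels Class labels.
#' @param config A [forest_config()]; its `importance` field is overridden.
#' @return A named numeric vector of length p.
#' @export
air_importance <- function(table, labels, config = forest_config()) {
  config$importance <- "air"
  fit_forest(table, labels, config)$importance
}

## OOB permutation importance (mean decrease in OOB accuracy); available as
## an importance fallback for Boruta
permutation_importance <- function(forest, x, labels) {
  oob <- forest$inbag == 0
  base_votes <- vote_matrix(forest, x, oob)
  base_pred <- max.col(base_votes, ties.method = "first")
  ok <- rowSums(oob) > 0
  base_acc <- mean((forest$classes[base_pred] == labels)[ok])
  imp <- numeric(forest$p)
  withr::with_seed(derive_seed(forest$config$seed, "perm_imp"), {
    for (j in seq_len(forest$p)) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      votes <- vote_matrix(forest, xp, oob)
      pred <- max.col(votes, ties.method = "first")
      imp[j] <- base_acc - mean((forest$classes[pred] == labels)[ok])
    }
  })
  stats::setNames(imp, colnames(x))
}

#' Tree and surrogate structure of a fitted forest
#'
#' Serializes a forest into plain data frames (one node table and one
#' surrogate table per tree) for inspection and independent re-computation
#' of minimal depth and relation parameters.
#'
#' @param forest An `rf_forest`.
#' @return A list with one element per tree: `nodes` (id, feature,
#'   threshold, children, depth, node size, class counts) and `surrogates`
#'   (node id, feature, threshold, flip, adjusted agreement).  Feature
#'   columns use 1-based indices into `forest$feature_names`.
#' @export
forest_structure <- function(forest) {
  lapply(forest$trees, function(tr) {
    nn <- length(tr$feature)
    nodes <- data.frame(
      id = seq_len(nn),
      feature = ifelse(tr$feature >= 0, tr$feature + 1L, NA_integer_),
      threshold = tr$threshold,
      left = ifelse(tr$left >= 0, tr$left + 1L, NA_integer_),
      right = ifelse(tr$right >= 0, tr$right + 1L, NA_integer_),
      depth = tr$depth, n_node = tr$n_node)
    surr <- data.frame(
      node = tr$surr_node + 1L, feature = tr$surr_feature + 1L,
      threshold = tr$surr_threshold, flip = tr$surr_flip == 1L,
      adjusted_agreement = tr$surr_adj)
    list(nodes = nodes, surrogates = surr, max_depth = tr$max_depth,
         counts = tr$counts)
  })
}

#' Serialize a forest to JSON / restore it
#'
#' @param forest An `rf_forest`.
#' @param path File path.
#' @return `forest_write_json` returns the path invisibly;
#'   `forest_read_json` returns the restored `rf_forest` (without retained
#'   training data, so OOB routines require refitting).
#' @export
forest_write_json <- function(forest, path) {
  payload <- list(
    classes = forest$classes, p = forest$p, n = forest$n,
    feature_names = forest$feature_names,
    config = unclass(forest$config),
    inbag = forest$inbag,
    trees = lapply(forest$trees, function(tr)
      lapply(tr, function(el) if (is.matrix(el)) unclass(el) else el)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname forest_write_json
#' @export
forest_read_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- forest_config(ntree = cfg$ntree, mtry = cfg$mtry,
                          min_node_size = cfg$min_node_size,
                          n_surrogates = cfg$n_surrogates,
                          case_weight_mode = cfg$case_weight_mode,
                          mode = cfg$mode, importance = cfg$importance,
                          seed = cfg$seed)
  trees <- lapply(seq_len(nrow_or_len(payload$trees)), function(i)
    tree_from_json(payload$trees, i))
  structure(list(trees = trees, inbag = payload$inbag, p = payload$p,
                 n = payload$n, classes = payload$classes,
                 feature_names = payload$feature_names, config = config,
                 importance = NULL),
            class = "rf_forest")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

tree_from_json <- function(trees, i) {
  tr <- if (is.data.frame(trees)) lapply(trees, `[[`, i) else trees[[i]]
  tr$feature <- as.integer(tr$feature)
  tr$left <- as.integer(tr$left)
  tr$right <- as.integer(tr$right)
  tr$depth <- as.integer(tr$depth)
  tr$n_node <- as.integer(tr$n_node)
  tr$counts <- matrix(as.integer(tr$counts), nrow = length(tr$feature))
  tr$surr_node <- as.integer(tr$surr_node)
  tr$surr_feature <- as.integer(tr$surr_feature)
  tr$surr_flip <- as.integer(tr$surr_flip)
  tr$surr_threshold <- as.numeric(tr$surr_threshold)
  tr$surr_adj <- as.numeric(tr$surr_adj)
  tr$max_depth <- as.integer(tr$max_depth)
  tr
}
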