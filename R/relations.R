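#' Mean adjusted agreement relation matrix
#'
#' For each ordered feature pair (i, j), `M[i, j]` is the average over all
#' nodes of the forest where j is the primary splitter of i's recorded
#' surrogate adjusted agreement; nodes where i was crowded out of the
#' stored top-s surrogate list contribute 0, and `M[i, j] = 0` when j never
#' splits.  The relation parameter captures the mutual impact of features
#' on the outcome and goes beyond pairwise correlation.
#'
#' @param forest An `rf_forest` grown with surrogates.
#' @param feature_subset Character ids or integer indices of the features
#'   to restrict the matrix to (e.g. the selected features); `NULL` keeps
#'   all.
#' @return An object of class `relation_matrix`: list with the directed
#'   matrix `M` (diagonal set to 1 by convention), the symmetrized view
#'   `S = (M + t(M)) / 2` and a `kind` tag.
#' @export
mean_adjusted_agreement <- function(forest, feature_subset = NULL) {
  assert_not_air(forest)
  if (forest$config$n_surrogates < 1)
    stop2("relation analysis requires a forest grown with surrogates")
  res <- cpp_maa(forest$trees, forest$p)
  m <- res$relation
  dimnames(m) <- list(forest$feature_names, forest$feature_names)
  idx <- resolve_subset(feature_subset, forest$feature_names)
  m <- m[idx, idx, drop = FALSE]
  diag(m) <- 1
  new_relation_matrix(m, "maa")
}

resolve_subset <- function(subset, names) {
  if (is.null(subset)) return(seq_along(names))
  if (is.character(subset)) {
    missing <- setdiff(subset, names)
    if (length(missing))
      stop2(sprintf("features not in the forest/table: %s",
                    paste(missing, collapse = ", ")))
    return(match(subset, names))
  }
  as.integer(subset)
}

new_relation_matrix <- function(m, kind) {
  structure(list(M = m, S = (m + t(m)) / 2, kind = kind,
                 features = colnames(m)),
            class = "relation_matrix")
}

#' @export
print.relation_matrix <- function(x, ...) {
  cat(sprintf("<relation_matrix> kind: %s, %d features\n", x$kind,
              length(x$features)))
  invisible(x)
}

#' Pairwise absolute Pearson correlation as a relation matrix
#'
#' The comparison baseline for the mean adjusted agreement: absolute
#' pairwise Pearson correlation coefficients over the feature subset.
#' Zero-variance features yield 0 rows/columns with a warning.
#'
#' @param table A preprocessed [feature_table()] or matrix.
#' @param feature_subset Features to restrict to (ids or indices).
#' @return A `relation_matrix` with `kind = "pearson"`.
#' @export
pearson_relation <- function(table, feature_subset = NULL) {
  x <- resolve_x(table)
  idx <- resolve_subset(feature_subset, colnames(x))
  x <- x[, idx, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  m <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  ok <- sds > 0
  if (any(!ok))
    warning(sprintf("zero-variance feature(s) set to 0: %s",
                    paste(colnames(x)[!ok], collapse = ", ")))
  m[ok, ok] <- abs(cor(x[, ok, drop = FALSE]))
  diag(m) <- 1
  new_relation_matrix(m, "pearson")
}

#' Hierarchical clustering of a relation matrix
#'
#' Agglomerative clustering of the rows of the symmetrized relation matrix
#' with Euclidean distance and the Ward algorithm (`ward.D2`), as used for
#' the relation heatmaps.
#'
#' @param rel A `relation_matrix`.
#' @param n_clusters Number of flat clusters to cut the tree into.
#' @return An object of class `relation_clusters`: the `hclust` tree,
#'   integer cluster `labels`, and the dendrogram `leaf_order`.
#' @export
cluster_relations <- function(rel, n_clusters) {
  assert_that(inherits(rel, "relation_matrix"), "rel must be a relation_matrix")
  nf <- length(rel$features)
  assert_that(nf >= 2, "clustering needs at least 2 features")
  if (n_clusters > nf)
    stop2("n_clusters exceeds the number of features")
  hc <- hclust(dist(rel$S), method = "ward.D2")
  labels <- cutree(hc, k = n_clusters)
  structure(list(tree = hc, labels = labels, leaf_order = hc$order,
                 n_clusters = n_clusters),
            class = "relation_clusters")
}

#' Merge features that stem from the same metabolite
#'
#' Builds a graph on the features with edges where the symmetrized relation
#' is at least `threshold` and returns the connected components of size 2
#' or more.  With a high threshold the components collect adducts and
#' in-source fragments of one metabolite.
#'
#' @param rel A `relation_matrix`.
#' @param threshold Edge threshold in `(0, 1]`; default 0.9.
#' @return An object of class `merge_groups`: list with the `threshold`
#'   and `groups`, a list of feature-id vectors.
#' @export
merge_features <- function(rel, threshold = 0.9) {
  assert_that(inherits(rel, "relation_matrix"), "rel must be a relation_matrix")
  assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  s <- rel$S
  diag(s) <- 0
  adj <- s >= threshold
  nf <- nrow(adj)
  comp <- integer(nf)
  cur <- 0L
  for (v in seq_len(nf)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  groups <- split(rel$features, comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2])
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, character(1), 1))]
  structure(list(threshold = threshold, groups = groups),
            class = "merge_groups")
}

#' Write a relation matrix as a square CSV
#'
#' @param rel A `relation_matrix`.
#' @param path Output path; the directed matrix `M` is written with feature
#'   ids as header and first column.
#' @param which `"directed"` (`M`) or `"symmetrized"` (`S`).
#' @return The path, invisibly.
#' @export
write_relation_matrix <- function(rel, path, which = c("directed",
                                                       "symmetrized")) {
  m <- switch(match.arg(which), directed = rel$M, symmetrized = rel$S)
  write.csv(data.frame(feature = rownames(m), m, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Relation heatmap with dendrograms
#'
#' Renders the symmetrized relation matrix as a clustered heatmap
#' (Euclidean distance, Ward linkage) via pheatmap, when installed.
#'
#' @param rel A `relation_matrix`.
#' @param path Output image path (png or pdf, by extension).
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The path, invisibly.
#' @export
plot_relation_heatmap <- function(rel, path, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop2("package 'pheatmap' is required for heatmap rendering")
  pheatmap::pheatmap(rel$S, clustering_distance_rows = "euclidean",
                     clustering_distance_cols = "euclidean",
                     clustering_method = "ward.D2", filename = path, ...)
  invisible(path)
}
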