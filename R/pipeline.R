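#' Pipeline configuration
#'
#' One object drives the full study workflow: preprocess once, then per
#' label scheme classify (confusion matrix + metrics), run the probability
#' machine, select features with Boruta and SMD, and analyze relations of
#' the selected features.
#'
#' @param out_dir Output directory; one subdirectory per label scheme.
#' @param synthetic A [synthetic_spec()], or `NULL` when reading files.
#' @param input Named list with `intensities_csv`, `samples_csv`,
#'   `features_csv` paths (used when `synthetic` is `NULL`).
#' @param schemes Character vector of label schemes (columns of the sample
#'   metadata) to run.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @param min_fraction,impute_num_trees,impute_max_iter Preprocessing
#'   switches, see [preprocess()].
#' @param forest Base [forest_config()] for classification and probability
#'   forests.
#' @param boruta A [boruta_config()]; `NULL` uses the base forest with
#'   corrected impurity importance.
#' @param smd An [smd_config()]; `NULL` uses the base forest.
#' @param n_clusters Flat cluster count for the relation heatmap
#'   clustering (capped at the number of selected features).
#' @param merge_threshold Relation threshold for same-metabolite merging.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            input = NULL,
                            schemes = NULL,
                            seed = 1,
                            min_fraction = 0.8,
                            impute_num_trees = 100,
                            impute_max_iter = 10,
                            forest = forest_config(),
                            boruta = NULL,
                            smd = NULL,
                            n_clusters = 6,
                            merge_threshold = 0.9) {
  assert_that(!is.null(synthetic) || !is.null(input),
              "either a synthetic spec or input paths are required")
  if (is.null(schemes) && !is.null(synthetic))
    schemes <- names(synthetic$class_schemes)
  assert_that(length(schemes) >= 1, "at least one label scheme is required")
  fsel <- forest
  fsel$mode <- "classification"
  structure(list(out_dir = out_dir, synthetic = synthetic, input = input,
                 schemes = schemes, seed = as.integer(seed),
                 min_fraction = min_fraction,
                 impute_num_trees = impute_num_trees,
                 impute_max_iter = impute_max_iter,
                 forest = forest,
                 boruta = boruta %||% boruta_config(forest = {
                   b <- fsel; b$importance <- "air"; b$n_surrogates <- 0L
                   b$mtry <- NULL; b
                 }),
                 smd = smd %||% smd_config(forest = {
                   s <- fsel; s$importance <- "none"; s$n_surrogates <- NULL
                   s$mtry <- NULL; s
                 }),
                 n_clusters = n_clusters,
                 merge_threshold = merge_threshold),
            class = "pipeline_config")
}

with_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED.json")
    jsonlite::write_json(list(stage = stage, message = conditionMessage(e)),
                         marker, auto_unbox = TRUE)
    stop2(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, for each configured label scheme, the fixed stage order:
#' preprocessing (once, on the full table), classification forest with OOB
#' confusion matrix and metrics, probability forest with OOB class
#' probabilities and per-class summaries, Boruta and SMD feature
#' selection, selection overlap counts, and relation analysis (mean
#' adjusted agreement and Pearson baseline, Ward/Euclidean clustering,
#' same-metabolite merge groups) over the SMD-selected features.  Scheme
#' runs operate on the subset of samples carrying that scheme's label.
#' All outputs are plain CSV/JSON under `out_dir`, listed with checksums
#' in a machine-readable manifest; rerunning the same configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  artifacts <- list()
  add_artifact <- function(scheme, stage, path) {
    rel <- if (startsWith(path, paste0(out, "/")))
      substring(path, nchar(out) + 2) else path
    artifacts[[length(artifacts) + 1]] <<-
      list(scheme = scheme, stage = stage, file = rel)
  }

  ## ---- input ----
  truth <- NULL
  table <- with_stage(out, "input", {
    if (!is.null(config$synthetic)) {
      ds <- generate_dataset(config$synthetic)
      truth <- ds$truth
      dir.create(file.path(out, "input"), showWarnings = FALSE)
      write_feature_table(ds$table,
                          file.path(out, "input", "intensities.csv"),
                          file.path(out, "input", "samples.csv"),
                          file.path(out, "input", "features.csv"))
      write_ground_truth(truth, file.path(out, "input", "ground_truth.json"))
      add_artifact(NA, "input", file.path(out, "input", "intensities.csv"))
      ds$table
    } else {
      read_feature_table(config$input$intensities_csv,
                         config$input$samples_csv,
                         config$input$features_csv)
    }
  })

  ## ---- preprocessing, once on the full table ----
  prep <- with_stage(out, "preprocess",
    preprocess(table, min_fraction = config$min_fraction,
               seed = derive_seed(seed, "preprocess"),
               impute_num_trees = config$impute_num_trees,
               max_iter = config$impute_max_iter))
  write_preprocess_report(prep$report,
                          file.path(out, "preprocess_report.json"))
  add_artifact(NA, "preprocess", file.path(out, "preprocess_report.json"))
  tab <- prep$table

  for (scheme in config$schemes) {
    sdir <- file.path(out, scheme)
    dir.create(sdir, showWarnings = FALSE)
    assert_that(scheme %in% names(tab$sample_meta),
                sprintf("label scheme '%s' missing from sample metadata",
                        scheme))
    keep <- !is.na(tab$sample_meta[[scheme]])
    stab <- subset_table(tab, samples = keep)
    labels <- droplevels(as.factor(stab$sample_meta[[scheme]]))

    ## classification + confusion metrics
    with_stage(sdir, paste0(scheme, "/classify"), {
      fc <- config$forest
      fc$mode <- "classification"
      fc$importance <- "none"
      fc$n_surrogates <- 0L
      fc$seed <- derive_seed(seed, paste0(scheme, "_classify"))
      forest <- fit_forest(stab, labels, fc)
      cm <- oob_confusion(forest, labels)
      write_confusion_csv(cm, file.path(sdir, "confusion.csv"))
      met <- confusion_metrics(cm)
      jsonlite::write_json(
        list(accuracy = met$accuracy, oob_error = met$error,
             sensitivity = as.list(met$sensitivity),
             specificity_printed = as.list(met$specificity_printed)),
        file.path(sdir, "metrics.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      add_artifact(scheme, "classify", file.path(sdir, "confusion.csv"))
    })

    ## probability machine
    with_stage(sdir, paste0(scheme, "/probabilities"), {
      fp <- config$forest
      fp$mode <- "probability"
      fp$importance <- "none"
      fp$n_surrogates <- 0L
      fp$seed <- derive_seed(seed, paste0(scheme, "_proba"))
      pforest <- fit_forest(stab, labels, fp)
      proba <- predict_proba(pforest, stab, oob_only = TRUE)
      write.csv(data.frame(sample_id = rownames(stab$intensities),
                           true_class = labels, proba, check.names = FALSE),
                file.path(sdir, "oob_probabilities.csv"), row.names = FALSE)
      write.csv(probability_summary(proba, labels),
                file.path(sdir, "probability_summary.csv"), row.names = FALSE)
      add_artifact(scheme, "probabilities",
                   file.path(sdir, "oob_probabilities.csv"))
    })

    ## feature selection
    boruta_res <- with_stage(sdir, paste0(scheme, "/select_boruta"), {
      res <- boruta_select(stab, labels, config$boruta,
                           seed = derive_seed(seed, paste0(scheme, "_boruta")))
      write_selection_result(res, file.path(sdir, "boruta.csv"),
                             file.path(sdir, "boruta.json"))
      add_artifact(scheme, "select_boruta", file.path(sdir, "boruta.csv"))
      res
    })
    smd_res <- with_stage(sdir, paste0(scheme, "/select_smd"), {
      res <- smd_select(stab, labels, config$smd,
                        seed = derive_seed(seed, paste0(scheme, "_smd")))
      write_selection_result(res, file.path(sdir, "smd.csv"),
                             file.path(sdir, "smd.json"))
      add_artifact(scheme, "select_smd", file.path(sdir, "smd.csv"))
      res
    })
    with_stage(sdir, paste0(scheme, "/overlap"), {
      ov <- selection_overlap(list(smd = smd_res, boruta = boruta_res))
      write.csv(ov, file.path(sdir, "overlap.csv"), row.names = FALSE)
      add_artifact(scheme, "overlap", file.path(sdir, "overlap.csv"))
    })

    ## relation analysis over the SMD-selected features
    with_stage(sdir, paste0(scheme, "/relations"), {
      sel <- smd_res$selected
      if (length(sel) < 2)
        sel <- sort(union(smd_res$selected, boruta_res$selected))
      if (length(sel) >= 2) {
        fr <- config$forest
        fr$mode <- "classification"
        fr$importance <- "none"
        fr$n_surrogates <- config$smd$s %||%
          n_surrogates_default(n_features(stab))
        fr$seed <- derive_seed(seed, paste0(scheme, "_relations"))
        rforest <- fit_forest(stab, labels, fr)
        rel <- mean_adjusted_agreement(rforest, sel)
        pea <- pearson_relation(stab, sel)
        write_relation_matrix(rel, file.path(sdir, "relation_maa.csv"))
        write_relation_matrix(pea, file.path(sdir, "relation_pearson.csv"))
        cl <- cluster_relations(rel, min(config$n_clusters, length(sel)))
        write.csv(data.frame(feature = rel$features, cluster = cl$labels,
                             leaf_order = order(cl$leaf_order)),
                  file.path(sdir, "clusters.csv"), row.names = FALSE)
        mg <- merge_features(rel, config$merge_threshold)
        jsonlite::write_json(list(threshold = mg$threshold,
                                  groups = mg$groups),
                             file.path(sdir, "merge_groups.json"),
                             auto_unbox = FALSE, digits = NA, pretty = TRUE)
        add_artifact(scheme, "relations", file.path(sdir, "relation_maa.csv"))
      } else {
        jsonlite::write_json(list(note = "fewer than 2 selected features"),
                             file.path(sdir, "relations_skipped.json"),
                             auto_unbox = TRUE)
        add_artifact(scheme, "relations",
                     file.path(sdir, "relations_skipped.json"))
      }
    })
  }

  ## ---- manifest ----
  files <- vapply(artifacts, `[[`, character(1), "file")
  sums <- tools::md5sum(file.path(out, files))
  manifest <- list(
    config = serialize_config(config),
    seed = seed,
    n_samples = n_samples(tab), n_features = n_features(tab),
    schemes = config$schemes,
    artifacts = lapply(seq_along(artifacts), function(i)
      c(artifacts[[i]], md5 = unname(sums[i]))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  cfg <- strip(config)
  cfg$out_dir <- NULL  # path is machine-specific; not part of the identity
  cfg
}
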