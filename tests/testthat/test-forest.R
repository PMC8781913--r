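test_that("inverse-class-frequency weights oversample rare classes", {
  sizes <- c(Germany = 213, Greece = 25, Netherlands = 31, Peru = 13,
             Poland = 35)
  labels <- factor(rep(names(sizes), sizes))
  w <- case_weights(labels, "inverse_class_frequency")
  expect_equal(sum(w), 1)
  # a sample from the rarest class is drawn 213/13 times more often
  expect_equal(w[labels == "Peru"][1] / w[labels == "Germany"][1], 213 / 13)
})

test_that("fitting is deterministic under a fixed seed", {
  d <- make_twoclass(n = 60, p = 10, seed = 31)
  cfg <- forest_config(ntree = 40, n_surrogates = 3, seed = 9,
                       mode = "probability")
  f1 <- fit_forest(d$x, d$y, cfg)
  f2 <- fit_forest(d$x, d$y, cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(predict(f1, d$x), predict(f2, d$x))
})

test_that("single-class labels are rejected", {
  d <- make_twoclass(n = 20, p = 5)
  expect_error(fit_forest(d$x, rep("A", 20), forest_config(ntree = 5)),
               "single class")
})

test_that("per-tree OOB fraction approaches exp(-1)", {
  spec <- synthetic_spec(n_samples = 317,
                         class_schemes = list(grp = c(A = 160, B = 157)),
                         n_metabolites = 10, adduct_multiplicity = 1,
                         missing_base_rate = 0, missing_intensity_slope = 0,
                         seed = 37)
  d <- generate_dataset(spec)
  f <- fit_forest(d$table, d$table$sample_meta$grp,
                  forest_config(ntree = 100, n_surrogates = 0,
                                case_weight_mode = "none", seed = 5))
  oob_frac <- mean(colMeans(f$inbag == 0))
  expect_lt(abs(oob_frac - exp(-1)) / exp(-1), 0.02)
})

test_that("probability rows sum to one and argmax agrees with voting", {
  d <- make_twoclass(n = 80, p = 12, n_informative = 4, seed = 41)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 60, mode = "probability",
                                          n_surrogates = 0, seed = 3))
  proba <- predict_proba(f, d$x)
  expect_true(all(abs(rowSums(proba) - 1) < 1e-12))
  hard <- predict(f, d$x)
  agree <- colnames(proba)[max.col(proba, ties.method = "first")] ==
    as.character(hard)
  # argmax of averaged proportions can differ from plurality voting only
  # where the two are nearly tied
  near_tie <- abs(proba[, 1] - proba[, 2]) < 0.1
  expect_true(all(agree | near_tie))
  expect_gt(mean(agree), 0.9)
})

test_that("probability mode is required for predict_proba", {
  d <- make_twoclass(n = 30, p = 5)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 10, n_surrogates = 0,
                                          mode = "classification"))
  expect_error(predict_proba(f, d$x), "probability mode")
})

test_that("OOB confusion error equals 1 - trace/total and is consistent", {
  d <- make_twoclass(n = 100, p = 15, n_informative = 5, delta = 3,
                     seed = 43)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 150, n_surrogates = 0,
                                          seed = 7))
  cm <- oob_confusion(f, d$y)
  expect_equal(attr(cm, "oob_error"),
               1 - sum(diag(cm)) / sum(cm))
  met <- confusion_metrics(cm)
  expect_equal(met$error / 100, attr(cm, "oob_error"))
  # informative data: clearly better than guessing
  expect_lt(attr(cm, "oob_error"), 0.3)
})

test_that("OOB error is near 80% for permuted 5-class labels", {
  withr::with_seed(47, {
    n <- 150; p <- 40
    x <- matrix(rnorm(n * p), n, p)
    y <- factor(sample(rep(letters[1:5], each = 30)))
  })
  f <- fit_forest(x, y, forest_config(ntree = 300, n_surrogates = 0,
                                      case_weight_mode = "none", seed = 13))
  cm <- oob_confusion(f, y)
  expect_lt(abs(attr(cm, "oob_error") - 0.8), 0.05)
})

test_that("corrected impurity importance is centered for pure noise", {
  withr::with_seed(53, {
    n <- 100; p <- 30
    x <- matrix(rnorm(n * p), n, p)
    y <- factor(rep(c("A", "B"), each = 50))
  })
  imp <- air_importance(x, y, forest_config(ntree = 500, n_surrogates = 0,
                                            case_weight_mode = "none",
                                            seed = 17))
  se <- sd(imp) / sqrt(length(imp))
  expect_lt(abs(mean(imp)), 2 * se)
})

test_that("a perfectly separating feature dominates the importance", {
  withr::with_seed(59, {
    n <- 80
    x <- matrix(rnorm(n * 10), n, 10)
    y <- factor(rep(c("A", "B"), each = 40))
  })
  x[, 4] <- as.numeric(y == "A") + rnorm(n, sd = 0.01)
  imp <- air_importance(x, y, forest_config(ntree = 100, seed = 19))
  expect_equal(which.max(imp), 4L, ignore_attr = TRUE)
  expect_gt(imp[4], 0)
})

test_that("AIR does not inherit the many-split-points bias of raw Gini", {
  withr::with_seed(61, {
    n <- 120
    y <- factor(rep(c("A", "B"), each = 60))
    x <- cbind(
      informative = round(as.numeric(y == "A") + rnorm(n, sd = 0.6)),
      highcard = rnorm(n),           # continuous noise, many split points
      lowcard = sample(0:1, n, TRUE) # binary noise
    )
  })
  cfg <- forest_config(ntree = 300, mtry = 2, case_weight_mode = "none",
                       seed = 23)
  raw_cfg <- cfg
  raw_cfg$importance <- "impurity"
  raw <- fit_forest(x, y, raw_cfg)$importance
  air <- air_importance(x, y, cfg)
  # raw Gini rewards the continuous noise feature with substantial credit;
  # the corrected measure keeps it near zero and below the informative one
  expect_gt(air[["informative"]], air[["highcard"]])
  expect_gt(raw[["highcard"]], air[["highcard"]])
  expect_gt(raw[["highcard"]] / max(raw), 0.2)
})

test_that("OOB error agrees with an independent forest implementation", {
  d <- cache_fixture("ranger_crosscheck_data", {
    spec <- synthetic_spec(
      n_samples = 150, class_schemes = list(grp = c(A = 75, B = 75)),
      n_metabolites = 30, adduct_multiplicity = 1,
      informative_groups = list(
        list(metabolites = 1:5, classes = "A", delta = 1.5)),
      missing_base_rate = 0, missing_intensity_slope = 0, batch_sd = 0,
      seed = 107)
    generate_dataset(spec)
  })
  lab <- d$table$sample_meta$grp
  own <- fit_forest(d$table, lab,
                    forest_config(ntree = 500, n_surrogates = 0,
                                  case_weight_mode = "none", seed = 3))
  own_err <- attr(oob_confusion(own, lab), "oob_error")
  df <- as.data.frame(d$table$intensities)
  df$.y <- lab
  rg <- ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = 500, mtry = own$config$mtry,
                       min.node.size = 1, seed = 3, num.threads = 1)
  expect_lt(abs(own_err - rg$prediction.error), 0.05)
})

test_that("forests survive a JSON round trip", {
  d <- make_twoclass(n = 40, p = 6, seed = 67)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 15, n_surrogates = 2,
                                          mode = "probability", seed = 29))
  path <- withr::local_tempfile(fileext = ".json")
  forest_write_json(f, path)
  g <- forest_read_json(path)
  expect_equal(surrogate_min_depth(g), surrogate_min_depth(f))
  expect_identical(predict(g, d$x), predict(f, d$x))
  expect_equal(mean_adjusted_agreement(g)$M, mean_adjusted_agreement(f)$M)
})
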