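test_that("binomial decisions match exact tail probabilities", {
  # 10 hits in 10 runs: two-sided p = 2 * 0.5^10 ~ 0.00195 < 0.01
  expect_equal(boruta_decisions(10, 10, 0.01), "confirmed")
  # the mirror case is rejected by the same test
  expect_equal(boruta_decisions(0, 10, 0.01), "rejected")
  # middling hit counts stay undecided
  expect_equal(boruta_decisions(7, 10, 0.01), "tentative")
  # decisions are monotone in the hit count
  dec <- boruta_decisions(0:20, 20, 0.01)
  expect_true(all(diff(match(dec, c("rejected", "tentative",
                                    "confirmed"))) >= 0))
})

test_that("boruta flags shadows and separates informative from noise", {
  d <- cache_fixture("boruta_small", {
    spec <- synthetic_spec(
      n_samples = 100, class_schemes = list(grp = c(A = 50, B = 50)),
      n_metabolites = 60, adduct_multiplicity = 1,
      informative_groups = list(
        list(metabolites = 1:8, classes = "A", delta = 3)),
      missing_base_rate = 0, missing_intensity_slope = 0, batch_sd = 0,
      seed = 7)
    generate_dataset(spec)
  })
  res <- boruta_select(
    d$table, d$table$sample_meta$grp,
    boruta_config(max_runs = 25,
                  forest = forest_config(ntree = 200, n_surrogates = 0,
                                         importance = "air",
                                         case_weight_mode = "none")),
    seed = 3)
  inf <- d$truth$informative_features
  expect_gte(sum(inf %in% res$selected), 7)
  expect_lte(length(setdiff(res$selected, inf)), 3)
  expect_true(all(res$decision %in% c("confirmed", "rejected", "tentative")))
  expect_setequal(res$selected, res$feature[res$decision == "confirmed"])
})

test_that("boruta warns when too few runs are allowed", {
  d <- make_twoclass(n = 40, p = 8, seed = 71)
  expect_warning(
    boruta_select(d$x, d$y,
                  boruta_config(max_runs = 3,
                                forest = forest_config(ntree = 30)),
                  seed = 1),
    "tentative")
})

test_that("surrogate minimal depth is zero for dominant features and their duplicates", {
  withr::with_seed(73, {
    n <- 120
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, sprintf("F%d", 1:8)))
    y <- factor(rep(c("A", "B"), each = 60))
  })
  x[, 1] <- as.numeric(y == "A") + rnorm(n, sd = 0.05)
  x[, 2] <- x[, 1]  # exact duplicate
  f <- fit_forest(x, y, forest_config(ntree = 50, mtry = 8, n_surrogates = 2,
                                      case_weight_mode = "none", seed = 5))
  smd <- surrogate_min_depth(f)
  expect_equal(unname(smd["F1"]), 0)
  expect_equal(unname(smd["F2"]), 0)
  expect_true(all(smd[3:8] > 0))
  # the duplicate reaches depth 0 through surrogacy in trees where the
  # original is the primary root splitter
  st <- forest_structure(f)
  via_surrogate <- vapply(st, function(tr) {
    root_primary <- tr$nodes$feature[1]
    root_surr <- tr$surrogates$feature[tr$surrogates$node == 1]
    root_primary == 1 && 2 %in% root_surr
  }, logical(1))
  expect_gt(sum(via_surrogate), 0)
})

test_that("surrogate minimal depth requires surrogates", {
  d <- make_twoclass(n = 40, p = 6, seed = 79)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 10, n_surrogates = 0))
  expect_error(surrogate_min_depth(f), "s = 0")
})

test_that("surrogate minimal depth matches hand enumeration on a toy forest", {
  d <- make_twoclass(n = 30, p = 6, n_informative = 2, seed = 83)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 5, n_surrogates = 3,
                                          case_weight_mode = "none",
                                          seed = 11))
  expect_equal(unname(surrogate_min_depth(f)), oracle_smd(f),
               tolerance = 1e-12)
})

test_that("smd_select confirms a correlated informative block entirely", {
  withr::with_seed(89, {
    n <- 100; p <- 30
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("F%02d", 1:p)))
    y <- factor(rep(c("A", "B"), each = 50))
  })
  x[, 1] <- x[, 1] + 2 * (y == "A")
  x[, 2] <- x[, 1]
  x[, 3] <- x[, 1]
  res <- smd_select(x, y,
                    smd_config(forest = forest_config(
                      ntree = 100, case_weight_mode = "none")),
                    seed = 5)
  expect_true(all(c("F01", "F02", "F03") %in% res$selected))
  expect_true(res$threshold > 0)
  mean_depth <- mean(vapply(res$forest$trees, `[[`, numeric(1), "max_depth"))
  expect_lt(res$threshold, mean_depth)
  expect_true(all(res$score >= 0))
})

test_that("smd_select null level is near nominal with the quantile rule", {
  fracs <- vapply(1:5, function(s) {
    withr::with_seed(s + 500, {
      x <- matrix(rnorm(100 * 100), 100, 100)
      y <- factor(rep(c("A", "B"), each = 50))
    })
    r <- smd_select(x, y,
                    smd_config(threshold_rule = "null_quantile",
                               quantile = 0.05,
                               forest = forest_config(
                                 ntree = 150, case_weight_mode = "none")),
                    seed = s)
    mean(r$decision == "confirmed")
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("duplicating a confirmed feature never unconfirms it", {
  withr::with_seed(97, {
    n <- 100; p <- 20
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("F%02d", 1:p)))
    y <- factor(rep(c("A", "B"), each = 50))
  })
  x[, 1] <- x[, 1] + 2.5 * (y == "A")
  cfg <- smd_config(forest = forest_config(ntree = 150,
                                           case_weight_mode = "none"))
  base <- smd_select(x, y, cfg, seed = 7)
  expect_true("F01" %in% base$selected)
  x2 <- cbind(x, F01dup = x[, 1])
  dup <- smd_select(x2, y, cfg, seed = 7)
  expect_true("F01" %in% dup$selected)
  expect_true("F01dup" %in% dup$selected)
})

test_that("degenerate null-copy depths abort selection", {
  # a table the forest cannot split informatively in one node: constant x
  x <- matrix(1, 30, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- factor(rep(c("A", "B"), each = 15))
  expect_error(
    smd_select(x, y, smd_config(s = 1, forest = forest_config(ntree = 5))),
    "degenerate")
})

test_that("selection results round-trip through CSV and JSON", {
  d <- make_twoclass(n = 60, p = 10, n_informative = 2, delta = 3,
                     seed = 101)
  res <- smd_select(d$x, d$y,
                    smd_config(forest = forest_config(
                      ntree = 60, case_weight_mode = "none")),
                    seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, csv, js)
  back <- read.csv(csv)
  expect_equal(back$feature, res$feature)
  expect_equal(back$decision, unname(res$decision))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$threshold, res$threshold)
  expect_setequal(meta$selected, res$selected)
})
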