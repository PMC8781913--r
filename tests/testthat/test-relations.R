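# shared fixture: a forest with an exact duplicate pair and noise
relation_fixture <- function() {
  cache_fixture("relation_forest", {
    withr::with_seed(81, {
      n <- 200; p <- 20
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("F%02d", 1:p)))
      y <- factor(rep(c("A", "B"), each = 100))
    })
    x[, 1] <- x[, 1] + 2 * (y == "A")
    x[, 2] <- x[, 1]  # exact duplicate of the informative feature
    f <- fit_forest(x, y, forest_config(ntree = 100, n_surrogates = 5,
                                        min_node_size = 20,
                                        case_weight_mode = "none", seed = 3))
    list(x = x, y = y, forest = f, rel = mean_adjusted_agreement(f))
  })
}

test_that("exact duplicates reach mean adjusted agreement one", {
  fx <- relation_fixture()
  expect_equal(fx$rel$M["F02", "F01"], 1)
  expect_equal(fx$rel$S["F01", "F02"], 1)
})

test_that("independent noise has mean adjusted agreement near zero", {
  # averaged over five refits on fresh noise: relation of the informative
  # primary to unrelated features stays below 0.1 at large nodes
  vals <- vapply(1:5, function(s) {
    withr::with_seed(200 + s, {
      n <- 200; p <- 20
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("F%02d", 1:p)))
      y <- factor(rep(c("A", "B"), each = 100))
    })
    x[, 1] <- x[, 1] + 2 * (y == "A")
    f <- fit_forest(x, y, forest_config(ntree = 100, n_surrogates = 5,
                                        min_node_size = 20,
                                        case_weight_mode = "none", seed = s))
    rel <- mean_adjusted_agreement(f)
    mean(rel$M[3:20, "F01"])
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("relation values are bounded and the diagonal is one", {
  fx <- relation_fixture()
  m <- fx$rel$M
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diag(m) == 1))
  expect_true(all(fx$rel$S >= 0 & fx$rel$S <= 1))
})

test_that("mean adjusted agreement matches hand computation on a toy forest", {
  d <- make_twoclass(n = 30, p = 6, n_informative = 2, seed = 103)
  f <- fit_forest(d$x, d$y, forest_config(ntree = 5, n_surrogates = 3,
                                          case_weight_mode = "none",
                                          seed = 13))
  rel <- mean_adjusted_agreement(f)
  want <- oracle_maa(f)
  diag(want) <- 1
  dimnames(want) <- dimnames(rel$M)
  expect_equal(rel$M, want, tolerance = 1e-12)
})

test_that("feature subsets restrict the matrix and unknown ids error", {
  fx <- relation_fixture()
  sub <- mean_adjusted_agreement(fx$forest, c("F01", "F02", "F05"))
  expect_equal(sub$features, c("F01", "F02", "F05"))
  expect_equal(sub$M["F02", "F01"], fx$rel$M["F02", "F01"])
  expect_error(mean_adjusted_agreement(fx$forest, "nope"), "not in")
})

test_that("pearson relation matches closed forms", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  rel <- pearson_relation(x)
  expect_equal(rel$M["a", "a"], 1)
  expect_equal(rel$M["a", "b"], 1)  # collinear
  expect_equal(rel$M["a", "c"], 1)  # exact anti-correlation, absolute value
  x2 <- cbind(x, d = c(5, 5, 5, 5))
  expect_warning(rel2 <- pearson_relation(x2), "zero-variance")
  expect_equal(unname(rel2$M["d", "a"]), 0)
})

test_that("ward clustering recovers block-diagonal relation structure", {
  nm <- sprintf("F%02d", 1:10)
  m <- matrix(0.05, 10, 10, dimnames = list(nm, nm))
  m[1:5, 1:5] <- 0.9
  m[6:10, 6:10] <- 0.9
  diag(m) <- 1
  rel <- structure(list(M = m, S = m, kind = "maa", features = nm),
                   class = "relation_matrix")
  cl <- cluster_relations(rel, 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_false(cl$labels[1] == cl$labels[6])
  # permutation invariance of the partition
  perm <- c(7, 2, 9, 4, 1, 6, 3, 8, 10, 5)
  relp <- structure(list(M = m[perm, perm], S = m[perm, perm], kind = "maa",
                         features = nm[perm]), class = "relation_matrix")
  clp <- cluster_relations(relp, 2)
  same_orig <- outer(cl$labels, cl$labels, `==`)
  same_perm <- outer(clp$labels[match(nm, nm[perm])],
                     clp$labels[match(nm, nm[perm])], `==`)
  expect_equal(same_perm, same_orig, ignore_attr = TRUE)
  expect_error(cluster_relations(rel, 11), "exceeds")
})

test_that("merge groups are threshold-monotone connected components", {
  nm <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(nm, nm))
  m["a", "b"] <- m["b", "a"] <- 0.95
  m["c", "d"] <- m["d", "c"] <- 0.85
  diag(m) <- 1
  rel <- structure(list(M = m, S = m, kind = "maa", features = nm),
                   class = "relation_matrix")
  mg <- merge_features(rel, 0.9)
  expect_equal(mg$groups, list(c("a", "b")))
  mg2 <- merge_features(rel, 0.8)
  expect_equal(mg2$groups, list(c("a", "b"), c("c", "d")))
  expect_equal(merge_features(rel, 1.0)$groups, list())
  # raising the threshold never enlarges a group
  sizes_hi <- vapply(mg$groups, length, integer(1))
  sizes_lo <- vapply(mg2$groups, length, integer(1))
  expect_lte(sum(sizes_hi), sum(sizes_lo))
})

test_that("same-metabolite adduct triplets merge and never cross metabolites", {
  counts <- vapply(1:3, function(sd_) {
    spec <- synthetic_spec(
      n_samples = 300,
      class_schemes = list(grp = c(A = 100, B = 100, C = 100)),
      n_metabolites = 12, adduct_multiplicity = 3,
      within_metabolite_corr = 0.98,
      informative_groups = list(
        list(metabolites = 1:4, classes = "A", delta = 2.5),
        list(metabolites = 5:8, classes = "B", delta = 2.5),
        list(metabolites = 9:12, classes = c("A", "C"), delta = 2)),
      missing_base_rate = 0, missing_intensity_slope = 0, batch_sd = 0,
      seed = sd_)
    d <- generate_dataset(spec)
    f <- fit_forest(d$table, d$table$sample_meta$grp,
                    forest_config(ntree = 800, n_surrogates = 12,
                                  min_node_size = 100,
                                  case_weight_mode = "none",
                                  seed = sd_ * 13))
    rel <- mean_adjusted_agreement(f)
    mg <- merge_features(rel, 0.8)
    met <- d$truth$metabolite_of_feature
    pure <- vapply(mg$groups, function(g) length(unique(met[g])) == 1,
                   logical(1))
    expect_true(all(pure))  # no cross-metabolite merges
    sum(pure & vapply(mg$groups, length, integer(1)) == 3)
  }, numeric(1))
  expect_gte(sum(counts), 0.9 * 36)
})

test_that("relations link outcome partners that correlation misses", {
  # A drives the outcome through |A|; B = A^2 is uncorrelated with A but
  # mimics its splits, so the relation sees what Pearson cannot
  s_ab <- numeric(3); r_ab <- numeric(3); s_noise <- numeric(3)
  for (s in 1:3) {
    withr::with_seed(s * 31, {
      n <- 300
      a <- rnorm(n)
      b <- a^2 + rnorm(n, sd = 0.1)
      x <- cbind(A = a, B = b, matrix(rnorm(n * 10), n, 10))
      colnames(x) <- c("A", "B", sprintf("N%02d", 1:10))
      y <- factor(ifelse(abs(a) > median(abs(a)), "hi", "lo"))
    })
    f <- fit_forest(x, y, forest_config(ntree = 300, n_surrogates = 4,
                                        min_node_size = 50,
                                        case_weight_mode = "none", seed = s))
    rel <- mean_adjusted_agreement(f)
    pea <- pearson_relation(x)
    s_ab[s] <- rel$S["A", "B"]
    s_noise[s] <- mean(rel$S["A", sprintf("N%02d", 1:10)])
    r_ab[s] <- pea$S["A", "B"]
  }
  expect_gt(mean(s_ab), 2 * mean(s_noise))
  expect_lt(mean(r_ab), 0.2)
})

test_that("relation matrices round-trip through CSV", {
  fx <- relation_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_relation_matrix(fx$rel, path)
  back <- read.csv(path, check.names = FALSE)
  m <- as.matrix(back[, -1])
  rownames(m) <- back[[1]]
  expect_equal(m, fx$rel$M, tolerance = 1e-12)
})
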