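# Shared fixtures, built in code.  Expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-class matrix with a handful of informative features
make_twoclass <- function(n = 100, p = 20, n_informative = 3, delta = 2,
                          seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%03d", seq_len(n)),
                                sprintf("F%02d", seq_len(p))))
    y <- factor(rep(c("A", "B"), length.out = n))
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
      delta * (y == "A")
    list(x = x, y = y)
  })
}

# tiny feature table with adduct annotations for preprocessing tests
make_adduct_table <- function() {
  x <- cbind(f1 = c(100, 100, 100, 100),
             f2 = c(80, 80, 80, 80),
             f3 = c(200, 200, 200, 200),
             f4 = c(50, 50, 50, 50))
  rownames(x) <- paste0("s", 1:4)
  fm <- data.frame(row.names = colnames(x),
                   adduct_label = c("[M+Na]+", "[M+K]+", "[M-NH3-H]+",
                                    "fragment"),
                   adduct_group = c("g1", "g1", "g1", NA))
  sm <- data.frame(row.names = rownames(x), batch = factor(c(1, 1, 2, 2)))
  feature_table(x, sm, fm)
}

# R-side brute-force split oracle: enumerate every feature and every
# midpoint between consecutive distinct sorted values
oracle_best_split <- function(x, y, candidates = seq_len(ncol(x))) {
  y <- as.factor(y)
  gini <- function(yy) 1 - sum((table(yy) / length(yy))^2)
  parent <- gini(y)
  best <- NULL
  for (j in candidates) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (thr in (head(v, -1) + diff(v) / 2)) {
      left <- x[, j] <= thr
      dec <- parent - mean(left) * gini(y[left]) -
        mean(!left) * gini(y[!left])
      if (is.null(best) || dec > best$decrease + 1e-12 ||
          (abs(dec - best$decrease) <= 1e-12 &&
           (j < best$feature ||
            (j == best$feature && thr < best$threshold)))) {
        best <- list(feature = j, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

# compare best_split with the oracle; when several features tie for the
# best gain (to within floating tolerance) only the gain is compared
expect_split_matches <- function(x, y, candidates = seq_len(ncol(x))) {
  got <- best_split(x, y, candidates)
  want <- oracle_best_split(x, y, candidates)
  if (is.null(want)) {
    testthat::expect_null(got)
    return(invisible())
  }
  testthat::expect_equal(got$decrease, want$decrease, tolerance = 1e-10)
  per_feature <- vapply(candidates, function(j) {
    b <- oracle_best_split(x, y, j)
    if (is.null(b)) -Inf else b$decrease
  }, numeric(1))
  tied <- sum(per_feature > want$decrease - 1e-9)
  if (tied == 1) {
    testthat::expect_equal(got$feature, want$feature)
    testthat::expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
  invisible()
}

# R-side brute-force surrogate oracle: all thresholds, both directions
oracle_surrogates <- function(x, primary_feature, threshold, s) {
  is_left <- x[, primary_feature] <= threshold
  m <- nrow(x)
  maj <- max(sum(is_left), sum(!is_left)) / m
  res <- NULL
  for (j in seq_len(ncol(x))) {
    if (j == primary_feature) next
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    best_cnt <- -1L; best_thr <- NA; best_flip <- NA
    for (thr in (head(v, -1) + diff(v) / 2)) {
      cand_left <- x[, j] <= thr
      cnt_norm <- sum(cand_left == is_left)
      cnt_flip <- m - cnt_norm
      if (cnt_norm > best_cnt) {
        best_cnt <- cnt_norm; best_thr <- thr; best_flip <- FALSE
      }
      if (cnt_flip > best_cnt) {
        best_cnt <- cnt_flip; best_thr <- thr; best_flip <- TRUE
      }
    }
    adj <- (best_cnt / m - maj) / (1 - maj)
    if (adj > 0)
      res <- rbind(res, data.frame(feature = j, threshold = best_thr,
                                   flip = best_flip,
                                   adjusted_agreement = adj))
  }
  if (is.null(res)) return(res)
  res <- res[order(-res$adjusted_agreement, res$feature), ]
  head(res, s)
}

# R-side oracle for surrogate minimal depth from the serialized forest
oracle_smd <- function(forest) {
  p <- forest$p
  total <- numeric(p)
  st <- forest_structure(forest)
  for (tr in st) {
    md <- rep(tr$max_depth, p)
    inner <- tr$nodes[!is.na(tr$nodes$feature), ]
    for (i in seq_len(nrow(inner))) {
      f <- inner$feature[i]
      md[f] <- min(md[f], inner$depth[i])
    }
    if (nrow(tr$surrogates)) {
      for (i in seq_len(nrow(tr$surrogates))) {
        f <- tr$surrogates$feature[i]
        d <- tr$nodes$depth[tr$surrogates$node[i]]
        md[f] <- min(md[f], d)
      }
    }
    total <- total + md
  }
  total / length(st)
}

# R-side oracle for the mean adjusted agreement from the serialized forest
oracle_maa <- function(forest) {
  p <- forest$p
  m <- matrix(0, p, p)
  cnt <- numeric(p)
  st <- forest_structure(forest)
  for (tr in st) {
    primaries <- tr$nodes$feature
    inner <- which(!is.na(primaries))
    for (nd in inner) cnt[primaries[nd]] <- cnt[primaries[nd]] + 1
    if (nrow(tr$surrogates)) {
      for (i in seq_len(nrow(tr$surrogates))) {
        j <- primaries[tr$surrogates$node[i]]
        m[tr$surrogates$feature[i], j] <-
          m[tr$surrogates$feature[i], j] + tr$surrogates$adjusted_agreement[i]
      }
    }
  }
  for (j in seq_len(p)) if (cnt[j] > 0) m[, j] <- m[, j] / cnt[j]
  m
}
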