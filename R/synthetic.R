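#' Specification for a synthetic LC-MS-like feature table
#'
#' Describes the generative model used by [generate_dataset()]: one latent
#' intensity per metabolite per sample; each feature of a metabolite (its
#' adducts / in-source fragments) is a scaled copy of the latent plus
#' independent noise, calibrated so that same-metabolite features reach a
#' target pairwise correlation; class-discriminative metabolite groups
#' receive additive mean shifts; per-feature per-batch offsets emulate batch
#' effects; missingness is Bernoulli per cell with a logit that is linear in
#' the (globally standardized, log-scale) intensity, so low-intensity
#' features go missing more often.
#'
#' @param n_samples Number of samples.
#' @param class_schemes Named list of named integer vectors, one per label
#'   scheme, mapping class label to class size.  The first scheme must cover
#'   all samples (sizes sum to `n_samples`); further schemes may cover a
#'   subset, the remaining samples carry `NA` for that scheme.
#' @param n_batches Number of measurement batches.
#' @param n_metabolites Number of simulated metabolites.
#' @param adduct_multiplicity Features per metabolite, in 1..3; scalar or a
#'   vector of length `n_metabolites`.
#' @param within_metabolite_corr Target pairwise correlation of features
#'   belonging to one metabolite, in `[0.9, 1]` for realistic adduct blocks
#'   (smaller values are accepted for experiments).
#' @param informative_groups List of groups, each a list with elements
#'   `metabolites` (integer metabolite ids), `classes` (labels of one
#'   scheme whose samples are shifted) and `delta` (standardized effect
#'   size, i.e. the class-mean shift in units of the feature noise sd;
#'   must be >= 0).
#' @param noise_sd Feature noise standard deviation (arbitrary intensity
#'   units before per-feature scaling).
#' @param missing_base_rate Missingness probability at average intensity, in
#'   `[0, 1)`.
#' @param missing_intensity_slope Slope of the missingness logit per unit of
#'   standardized log-intensity; positive values make low-intensity cells go
#'   missing more often.
#' @param batch_sd Batch offset sd in units of the feature sd.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @seealso [default_synthetic_spec()] for the study-design defaults.
#' @export
synthetic_spec <- function(n_samples,
                           class_schemes,
                           n_batches = 3,
                           n_metabolites,
                           adduct_multiplicity = 3,
                           within_metabolite_corr = 0.95,
                           informative_groups = list(),
                           noise_sd = 1,
                           missing_base_rate = 0,
                           missing_intensity_slope = 0,
                           batch_sd = 1,
                           seed = 1) {
  assert_that(is.list(class_schemes) && length(class_schemes) >= 1 &&
                !is.null(names(class_schemes)),
              "class_schemes must be a named list of named class-size vectors")
  first <- class_schemes[[1]]
  if (sum(first) != n_samples)
    stop2(sprintf("class sizes of scheme '%s' sum to %d, not n_samples = %d",
                  names(class_schemes)[1], sum(first), n_samples))
  for (nm in names(class_schemes)) {
    sc <- class_schemes[[nm]]
    assert_that(!is.null(names(sc)) && all(sc > 0),
                sprintf("scheme '%s' needs named positive class sizes", nm))
    if (sum(sc) > n_samples)
      stop2(sprintf("class sizes of scheme '%s' exceed n_samples", nm))
  }
  mult <- rep_len(as.integer(adduct_multiplicity), n_metabolites)
  assert_that(all(mult %in% 1:3), "adduct_multiplicity must be in 1..3")
  assert_that(within_metabolite_corr >= 0 && within_metabolite_corr <= 1,
              "within_metabolite_corr must be in [0, 1]")
  all_classes <- unlist(lapply(class_schemes, names), use.names = FALSE)
  assert_that(!anyDuplicated(all_classes),
              "class labels must be unique across schemes")
  for (g in informative_groups) {
    assert_that(all(c("metabolites", "classes", "delta") %in% names(g)),
                "each informative group needs metabolites, classes, delta")
    assert_that(all(g$metabolites >= 1 & g$metabolites <= n_metabolites),
                "informative group metabolite ids out of range")
    assert_that(g$delta >= 0, "effect size delta must be >= 0")
    assert_that(all(g$classes %in% all_classes),
                "informative group classes must exist in some scheme")
  }
  assert_that(missing_base_rate >= 0 && missing_base_rate < 1,
              "missing_base_rate must be in [0, 1)")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  structure(list(n_samples = n_samples, class_schemes = class_schemes,
                 n_batches = n_batches, n_metabolites = n_metabolites,
                 adduct_multiplicity = mult,
                 within_metabolite_corr = within_metabolite_corr,
                 informative_groups = informative_groups,
                 noise_sd = noise_sd,
                 missing_base_rate = missing_base_rate,
                 missing_intensity_slope = missing_intensity_slope,
                 batch_sd = batch_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic specification mirroring the asparagus study design
#'
#' 317 samples in 3 batches; a 5-class origin scheme with imbalanced sizes
#' 213/25/31/13/35 and a 4-class variety scheme covering a 150-sample
#' subset (56/23/42/29); 240 metabolites with 3 features each (720 features
#' before filtering); intensity-dependent missingness and additive batch
#' effects.  The informative groups mirror the structure of the asparagus
#' findings: shared blocks separating groups of classes (e.g. the
#' North-European origins) plus smaller marker groups specific to single
#' classes, so that every class is in principle distinguishable.
#'
#' @param seed Integer seed.
#' @param n_metabolites,adduct_multiplicity,missing_base_rate Overridable
#'   scale knobs, passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
default_synthetic_spec <- function(seed = 1, n_metabolites = 240,
                                   adduct_multiplicity = 3,
                                   missing_base_rate = 0.1) {
  synthetic_spec(
    n_samples = 317,
    class_schemes = list(
      origin = c(Germany = 213, Greece = 25, Netherlands = 31,
                 Peru = 13, Poland = 35),
      variety = c(Backlim = 56, Cumulus = 23, Gijnlim = 42, Grolim = 29)),
    n_batches = 3,
    n_metabolites = n_metabolites,
    adduct_multiplicity = adduct_multiplicity,
    within_metabolite_corr = 0.95,
    informative_groups = list(
      list(metabolites = 1:12,
           classes = c("Germany", "Netherlands", "Poland"), delta = 2),
      list(metabolites = 13:24, classes = c("Greece", "Peru"), delta = 1.5),
      list(metabolites = 25:30, classes = "Germany", delta = 1.5),
      list(metabolites = 31:34, classes = "Netherlands", delta = 1.5),
      list(metabolites = 35:38, classes = "Poland", delta = 1.2),
      list(metabolites = 39:40, classes = "Peru", delta = 2),
      list(metabolites = 41:48, classes = c("Gijnlim", "Grolim"),
           delta = 1.5),
      list(metabolites = 49:56, classes = c("Backlim", "Gijnlim"),
           delta = 1.2),
      list(metabolites = 57:60, classes = "Cumulus", delta = 1.5),
      list(metabolites = 61:62, classes = "Grolim", delta = 1.2)),
    noise_sd = 1,
    missing_base_rate = missing_base_rate,
    missing_intensity_slope = 2,
    batch_sd = 1,
    seed = seed)
}

#' Generate a synthetic LC-MS-like feature table with ground truth
#'
#' Draws a dataset from the model described in [synthetic_spec()].  The
#' returned ground truth records exactly which features are informative
#' (those belonging to a metabolite of any informative group), the
#' feature-to-metabolite map and the injected class-mean shifts, so that
#' downstream selection and relation analyses can be validated.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (class `ground_truth`).
#' @export
generate_dataset <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  withr::with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  n <- spec$n_samples
  nm <- spec$n_metabolites
  mult <- spec$adduct_multiplicity
  p <- sum(mult)
  rho <- spec$within_metabolite_corr

  ## sample metadata: first scheme in class blocks, further schemes on a
  ## random subset; batches assigned at random in near-equal sizes
  sample_ids <- sprintf("S%03d", seq_len(n))
  sample_meta <- data.frame(row.names = sample_ids)
  schemes <- spec$class_schemes
  for (k in seq_along(schemes)) {
    sc <- schemes[[k]]
    lab <- rep(NA_character_, n)
    if (k == 1) {
      lab <- rep(names(sc), sc)
    } else {
      idx <- sort(sample.int(n, sum(sc)))
      lab[idx] <- rep(names(sc), sc)
    }
    sample_meta[[names(schemes)[k]]] <- factor(lab, levels = names(sc))
  }
  batch <- sample(rep_len(seq_len(spec$n_batches), n))
  sample_meta$batch <- factor(batch)
  sample_meta$year <- 2015L + batch

  ## feature metadata: adduct labels cycle through sodium adduct, ammonium
  ## adduct and in-source fragment; m/z and RT are placeholders
  met_of_feature <- rep(seq_len(nm), mult)
  adduct_cycle <- c("[M+Na]+", "[M-NH3-H]+", "fragment")
  within_idx <- unlist(lapply(mult, seq_len))
  feature_ids <- sprintf("M%03d_%s", met_of_feature,
                         c("a", "b", "c")[within_idx])
  feature_meta <- data.frame(
    row.names = feature_ids,
    mz = round(runif(p, 100, 1500), 4),
    rt = round(runif(p, 0.5, 20), 3),
    adduct_label = adduct_cycle[within_idx],
    adduct_group = NA_character_,
    metabolite = sprintf("M%03d", met_of_feature),
    stringsAsFactors = FALSE)

  ## latent metabolite intensities and class-mean shifts (in latent units,
  ## which equal standardized feature units)
  latent <- matrix(rnorm(n * nm), n, nm)
  shift <- matrix(0, n, nm)
  truth_means <- list()
  for (g in spec$informative_groups) {
    scheme_name <- names(schemes)[vapply(schemes, function(sc)
      all(g$classes %in% names(sc)), logical(1))][1]
    in_class <- !is.na(sample_meta[[scheme_name]]) &
      sample_meta[[scheme_name]] %in% g$classes
    shift[in_class, g$metabolites] <- shift[in_class, g$metabolites] + g$delta
    truth_means[[length(truth_means) + 1]] <-
      expand.grid(class = g$classes, metabolite = sprintf("M%03d", g$metabolites),
                  stringsAsFactors = FALSE)
    truth_means[[length(truth_means)]]$delta <- g$delta
    truth_means[[length(truth_means)]]$scheme <- scheme_name
  }

  ## features: scaled latent copies plus independent noise, plus baseline
  baseline <- exp(rnorm(p, log(1e4), 1))
  fscale <- runif(p, 0.5, 1.5)
  z <- sqrt(rho) * latent[, met_of_feature, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p) +
    shift[, met_of_feature, drop = FALSE]
  x <- sweep(sweep(z, 2, fscale * spec$noise_sd, `*`), 2, baseline, `+`)

  ## batch effects: per-feature per-batch additive offsets
  if (spec$n_batches > 1 && spec$batch_sd > 0) {
    off <- matrix(rnorm(spec$n_batches * p), spec$n_batches, p)
    off <- sweep(off, 2, spec$batch_sd * fscale * spec$noise_sd, `*`)
    x <- x + off[batch, , drop = FALSE]
  }
  x <- pmax(x, 0)
  dimnames(x) <- list(sample_ids, feature_ids)

  ## intensity-dependent missingness on the globally standardized log scale
  if (spec$missing_base_rate > 0 || spec$missing_intensity_slope != 0) {
    lz <- log1p(x)
    zg <- (lz - mean(lz)) / stats::sd(lz)
    pmiss <- stats::plogis(stats::qlogis(spec$missing_base_rate) -
                             spec$missing_intensity_slope * zg)
    x[matrix(runif(n * p), n, p) < pmiss] <- NA_real_
  }

  informative_mets <- sort(unique(unlist(
    lapply(spec$informative_groups, `[[`, "metabolites"))))
  truth <- structure(list(
    informative_features = feature_ids[met_of_feature %in% informative_mets],
    informative_metabolites = sprintf("M%03d", informative_mets),
    metabolite_of_feature = stats::setNames(sprintf("M%03d", met_of_feature),
                                            feature_ids),
    true_class_means = if (length(truth_means))
      do.call(rbind, truth_means) else
        data.frame(class = character(), metabolite = character(),
                   delta = numeric(), scheme = character())),
    class = "ground_truth")

  list(table = feature_table(x, sample_meta, feature_meta), truth = truth)
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth` object from [generate_dataset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(informative_features = truth$informative_features,
         informative_metabolites = truth$informative_metabolites,
         metabolite_of_feature = as.list(truth$metabolite_of_feature),
         true_class_means = truth$true_class_means),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
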