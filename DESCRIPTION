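Package: rfmetab
Title: Random-Forest Classification, Feature Selection and Relation
    Analysis for LC-MS Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-level classification of LC-MS metabolomics feature
    tables with case-weighted random forests and probability machines,
    all-relevant feature selection with Boruta shadow variables and with
    Surrogate Minimal Depth (SMD), and analysis of feature relations via
    the mean adjusted agreement of surrogate splits, including
    Ward/Euclidean relation clustering and merging of features that stem
    from the same metabolite (adducts and in-source fragments).  Includes
    the standard preprocessing chain for untargeted LC-MS feature tables
    (adduct consolidation, prevalence filtering, iterative random-forest
    imputation, batch-wise autoscaling) and a synthetic feature-table
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
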