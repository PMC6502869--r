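Package: stainmap
Title: Colorimetric Analysis of Paired H&E/IHC Slide Images for Tumor Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automatic identification of prostate cancer from paired
    hematoxylin-and-eosin (H&E) and triple-antibody immunohistochemistry (IHC)
    whole-slide image tiles. Implements positive pixel counting in
    hue-saturation-brightness space, Beer-Lambert color deconvolution with
    configurable stain optical-density vectors, a co-expression statistic that
    excludes double-stained pixels, rigid registration of IHC to H&E tiles,
    analysis-square grid generation with overlap-based labeling, elastic-net
    regression of the percentage of malignant epithelium per square, and
    ROC/bootstrap evaluation with Youden cutoffs and grade-group breakdowns.
    A seedable phantom-slide generator renders paired H&E/IHC tiles by forward
    Beer-Lambert stain synthesis with exact per-pixel ground truth, so the
    whole pipeline can be exercised end-to-end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
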