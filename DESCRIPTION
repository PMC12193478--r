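Package: gaitvar
Title: Markerless Gait Variability Analysis from Skeletal Keypoint Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for vision-based gait variability analysis in older
    adults. Reads per-trial 2-D skeletal keypoint JSON streams (17-point
    skeleton, indices 15/16 = left/right foot), computes frame-to-frame foot
    displacement series, per-foot per-trial displacement variances, and the
    composite var_mean gait-variability index; reduces the four variance
    features to a two-component PCA gait index (muscle-control reserve and
    learning-fatigue response); and correlates gait features against walking
    test scores and durations with a mixed-variable-type correlation engine
    (point-biserial, Kendall tau-b, Spearman, Pearson) and Benjamini-Hochberg
    false discovery rate adjustment. Includes a synthetic-data generator for
    walking-trial keypoint streams and cohort tables with configurable
    coupling between gait variance and test duration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'pose-io.R'
    'gait-features.R'
    'simulate.R'
    'pca-index.R'
    'correlation.R'
    'cohort-report.R'
    'pipeline.R'
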