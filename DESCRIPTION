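Package: tractreli
Title: Template-Based Tractography Clustering and Reliability Assessment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters template tractograms of diffusion MRI streamlines with
    spectral clustering or QuickBundles over minimum average direct-flip (MDF)
    distances, propagates template cluster labels to analysis tractograms by
    maximum similarity, extracts short-range "U"-shaped (superficial white
    matter) streamlines by geometric constraints, and computes a reliability
    metric suite: centroid MDF distances, weighted Dice overlap of tract
    density maps, along-tract scalar ICC (two-way random effects, absolute
    agreement), streamline-count coefficients of variation, and inter-metric
    Spearman correlations with Benjamini-Hochberg correction. Includes a
    seeded synthetic multi-subject tractography generator with planted bundle
    ground truth, and TCK/TRK/NIfTI input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
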