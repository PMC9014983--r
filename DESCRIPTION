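Package: wmskeleton
Title: Skeletonized White-Matter Statistics with TFCE Permutation
    Inference and Voxelwise Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@wmskeleton.org",
           role = c("aut", "cre"))
Description: Voxelwise statistics for skeletonized diffusion-MRI scalar
    maps in aging cohorts. Provides S4 containers for tract skeletons and
    subject-by-voxel metric stacks, voxelwise general linear models with
    directional contrasts, threshold-free cluster enhancement (TFCE) with
    max-statistic Freedman-Lane permutation inference and family-wise
    error corrected p-maps, a voxelwise Sobel test for mediation of age
    effects on working memory through white-matter integrity, genotype
    group contrasts with Hardy-Weinberg statistics, reporting utilities
    (slice profiles, tract coverage, cross-metric overlap), and a
    synthetic cohort generator that emulates a narrow-age-cohort design
    with planted, tract-structured age and mediation effects so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
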