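Package: npairspls
Title: Contrast-Based Partial Least Squares with NPAIRS Split-Half Validation
    for Parametric Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate group analysis of parametric 3-D brain images
    (e.g. PET binding-potential volumes) with contrast-based Partial Least
    Squares: the cross-product of a standardized scans-by-voxels data matrix
    and a scans-by-conditions design matrix is decomposed by SVD into latent
    variables pairing design contrasts with voxel salience patterns.
    Validation follows the NPAIRS framework: matched stratified split-half
    resampling yields per-split prediction and spatial-reproducibility
    correlations, empirical p-values against zero, and voxelwise salience
    standard errors and Z-maps.  Model complexity is set adaptively by
    optimizing a principal-component subspace against the joint
    prediction/reproducibility objective D(k).  Reporting includes
    cluster-extent thresholded Z-maps with local maxima, grand-mean-centered
    condition brain scores with bootstrap confidence intervals, and
    Bonferroni-corrected condition contrasts.  A synthetic cohort generator
    plants a group-by-season covariance pattern in phantom volumes so the
    whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
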