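Package: rbcmorph
Title: Semi-Automated Red Blood Cell Morphology Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A hybrid pipeline for building expert-validated red blood cell
    (RBC) morphology datasets from stained blood-smear images. Provides
    region-of-interest quality screening, watershed-based single-cell patch
    extraction with category routing and size binning, direct least-squares
    ellipse fitting with aspect-ratio/size/area-completeness morphometric
    classification, dense and convolutional autoencoders for latent feature
    learning, k-means clustering with silhouette and Davies-Bouldin model
    selection sweeps, cluster-level expert label application, and
    count-exact geometry-preserving minority-class augmentation. A seeded
    synthetic smear generator with per-cell ground truth makes every stage
    testable without access to patient slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    png,
    yaml,
    uwot,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
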