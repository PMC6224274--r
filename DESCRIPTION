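Package: naupliomorph
Title: Outline Morphometrics and Comparative Analysis of Barnacle Nauplius Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative outline morphometrics of barnacle nauplius
    larvae (cephalic shield shape). Implements normalized elliptic Fourier
    analysis of closed outlines, principal-component morphospaces with
    hypothetical shape reconstruction and thin-plate-spline deformation grids,
    multivariate regression of shape on size (allometry) with shape scores and
    allometry-free residual shapes, sequential (Type I) MANCOVA with residual
    randomization permutation tests, vector correlations between regression
    vectors and morphospace axes, balanced group bootstraps, and
    Brownian-motion comparative methods (Blomberg's K, its multivariate
    generalization K_mult, maximum-likelihood ancestral states,
    phylomorphospace coordinates and phylogenetic MANCOVA). A synthetic
    nauplius outline generator with known ground truth supports testing and
    method validation, and a config-driven pipeline reproduces the full
    analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    Matrix,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
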