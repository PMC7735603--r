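Package: crownmap
Title: Landmark-Free Morphometric Mapping of Tooth Crowns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts 3D surface meshes of tooth crowns into polar
    morphometric maps (surface curvature, height, radius and vertex normal),
    Fourier-transforms the maps for low-pass shape filtering and rotational
    alignment, and selects map-variable combinations and filter sizes by
    cross-validated classification accuracy or multivariate phylogenetic
    signal (Blomberg's K generalized to high-dimensional traits). Downstream
    comparative tools include between-group principal component analysis,
    pseudo-genetic dosage distances, Mantel tests, phylogenetic generalized
    least squares with permutation inference, squared-change-parsimony
    ancestral states and morphospace convex-hull coverage. A parametric
    crown generator produces ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    MASS,
    class,
    rpart,
    nnet,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
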