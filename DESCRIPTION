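Package: morphomod
Title: Geometric Morphometrics of Equid Skull Shape, Disparity and Cranial Modularity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Landmark-based geometric morphometrics for the comparative analysis of
    equid crania, mandibles and cheek teeth. Implements generalized Procrustes
    superimposition with object-symmetry decomposition of bilateral landmark
    configurations, merging of separately digitized dorsal and ventral views,
    principal component ordination, cross-validated selection of discriminant
    dimensionality under unbalanced group sizes, permutation Procrustes ANOVA,
    canonical variates classification with Mahalanobis distances and predictive
    assignment of excluded groups, Foote partial disparity, and maximum-likelihood
    comparison of cranial modularity hypotheses on landmark correlation matrices
    with AICc, together with per-module integration (relative eigenvalue standard
    deviation) and disparity. A synthetic landmark generator emulating bilaterally
    symmetric, group-structured, modular configurations makes every stage testable
    without access to museum specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
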