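Package: gmkit
Title: Procrustes-Based Geometric Morphometrics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for landmark-based analysis of biological shape
    and form: generalized Procrustes analysis with shape, Boas, and size-shape
    coordinate systems; thin-plate spline interpolation, bending energy,
    partial warps, and deformation grids; sliding semilandmarks on curves and
    surfaces under bending-energy or Procrustes-distance criteria; symmetry
    decomposition with Procrustes ANOVA of directional and fluctuating
    asymmetry; principal component, between-group PCA and canonical variate
    ordinations with cross-validated quadratic classification; relative
    eigenanalysis and generalized-variance comparison of covariance matrices;
    two-block latent-variable analyses (partial least squares, reduced rank
    regression, canonical correlation); spatial-scale analysis of shape
    variance via partial-warp spectra; and seeded simulation models
    (Mardia-Dryden and self-similar shape distributions, group-structured and
    bilaterally asymmetric samples) so every method can be exercised on
    synthetic data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
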