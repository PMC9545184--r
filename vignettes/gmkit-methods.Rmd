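---
title: "Models and methods in gmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmkit)
```

gmkit is a toolkit for landmark-based shape analysis. This vignette is the
package's own account of the models it implements, the parameters that
matter, the simulation conditions under which everything is tested, and
the numerical decisions taken where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Superimposition

A landmark configuration is a `p × k` matrix of corresponding point
locations (`k` = 2 or 3). Shape is geometry modulo location, orientation,
and scale; form retains scale. `gpa()` implements *partial* Procrustes
superimposition: configurations are centered, scaled to unit centroid
size, and iteratively rotated to the running consensus until the total
summed squared deviation changes by less than `tol = 1e-10` (at most 100
iterations; the objective is non-increasing by construction and the loop
warns and returns its last iterate if the cap is hit). The scaling step is
the geometrically convenient unit-size convention rather than a
least-squares optimal scaling; the full least-squares variant is out of
scope. Rotations are always proper (determinant +1) — reflections are
never introduced silently, and a reflected copy of a shape keeps a
positive Procrustes distance from the original.

The consensus of a converged GPA is unique only up to rotation, so for
reproducibility the final consensus (and with it the whole aligned
sample) is rotated to align optimally with configuration 1. Aligned
coordinates are therefore invariant to arbitrary similarity transforms of
the input *up to that orientation convention*; the test suite verifies
invariance after mapping one fit's orientation onto the other's.

Boas (form-space) coordinates are computed by re-multiplying each
specimen's shape coordinates by its centroid size. Of the two equivalent
constructions in the literature — skipping the scaling step versus
re-multiplying — the second is used because it makes the relationship
between the two coordinate systems exact row by row. Size-shape
coordinates augment the `pk` shape coordinates with log centroid size;
reconstructing a form from such a vector requires one explicit scaling
step by `exp(log cs)` (`form_from_size_shape()`).

`tangent_coordinates()` returns mean-centered aligned coordinates
orthogonally projected onto the tangent subspace at the consensus. The
projection is linear — no stereographic rescaling — because all
downstream methods are linear and the package targets small shape
variation. The projection matters for rank accounting: centering and the
optimal rotations already annihilate the translation and rotation
directions *exactly*, but the scaling constraint leaves a second-order
residual along the consensus direction that would otherwise register as a
spurious dimension at any realistic rank threshold (singular values below
`1e-8` of the largest are treated as zero). After projection the
covariance rank equals the geometric count: `pk − 4` in 2D, `pk − 7` in
3D, one more in Boas mode where scale is a real degree of freedom — for
four 2D landmarks, four shape and five form dimensions.

## Thin-plate splines, bending energy, partial warps

`fit_tps()` interpolates one configuration onto another with the standard
radial-basis construction: kernel `U(r) = r² log r` in 2D and
`U(r) = −r` in 3D. The 3D sign was chosen so that the bending-energy
matrix (the upper-left block of the inverse bordered kernel system) is
positive semidefinite — with `+r` the quadratic form is negative
definite. Any consistent positive rescaling of the kernel rescales all
bending-energy eigenvalues equally and cancels in every ratio, regression
slope, and relative eigenanalysis in the package, so nothing downstream
depends on the convention. The matrix is symmetrized as `(B + Bᵀ)/2`;
eigenvalues in `[−1e-10, 0)` are clipped to zero, anything more negative
is treated as a numerical failure; the bordered system must have a
reciprocal condition number above `1e-12`.

The bending-energy matrix has exactly `k + 1` zero eigenvalues (the
affine null space); the remaining eigenvectors, ordered by ascending
eigenvalue, are the partial warps — a spatial-scale-ordered orthonormal
basis for nonaffine shape change, with small eigenvalues corresponding to
large-scale smooth deformation. `partial_warp_scores()` projects
residuals from the reference onto each warp per coordinate axis;
`uniform_component()` spans the affine deformations of the reference with
the similarity transforms removed (2 dimensions in 2D, 5 in 3D), built by
orthogonal projection rather than the classical two-vector
parameterization — the same subspace, in a form that makes the
completeness identity (warps + uniform = tangent-projected residuals)
exact. Unless a reference is supplied, partial warps are computed from
the sample consensus.

## Sliding semilandmarks

Semilandmarks carry anatomical information only orthogonal to their curve
or surface; their position along the structure is estimated by sliding.
`slide()` iterates: GPA, optional symmetrization of the consensus (needed
in asymmetry studies so an asymmetric initial placement does not
masquerade as biological asymmetry), tangent re-estimation from the
*current* positions, one constrained least-squares step per specimen, and
reprojection onto the specimen's geometry. Under the `d2` criterion
(minimize Procrustes distance to the consensus) the step decouples into
independent orthogonal projections per semilandmark and the sample
variance is non-increasing — the algorithm converges. Under the `bending`
criterion the TPS quadratic form of the residual is minimized jointly
over all tangent amplitudes; because affine deformation carries no
bending penalty, this need not converge, and with weakly anchored schemes
the unpenalized directions can run away until the consensus degenerates —
the loop detects this, stops, and reports rather than erroring. Both
behaviors are exercised in the tests; the bending step itself is verified
against a direct numerical optimizer.

Defaults: `step_fraction` 1 for curve-only schemes and 0.5 when surface
semilandmarks are present (damped steps re-estimate tangents at smaller
intervals and track curvature better), `max_iter = 10`, amplitude
tolerance `1e-6` of centroid size. Tangents are central differences of
chain neighbors (one-sided at the ends), with the difference window
widened when neighbors coincide — the `d2` criterion permits
semilandmarks to pass each other, so coincidences can occur transiently.
Reprojection defaults to each specimen's own initial chain polyline;
shared dense geometry can be supplied (`curve_polylines`), which is also
how the suite verifies that sliding removes arbitrary re-spacing along a
common curve. Surface normals come from supplied arrays or the nearest
face of a triangulated OBJ mesh.

## Symmetry decomposition

A `symmetry_map()` lists paired left/right landmarks, midline landmarks,
and the coordinate axis negated by reflection (default the first; the
decomposition is invariant to this labeling choice and to rigid motion of
the input, which the suite asserts). `symmetry_gpa()` superimposes the
`2n` originals and relabelled reflections jointly, then rotates the
consensus into its *symmetric pose* before projecting it onto the
reflection-invariant subspace. The pose has a closed form: minimizing the
distance between the consensus and its relabelled reflection over
rotations reduces to taking the reflection axis along the
smallest-eigenvalue eigenvector of the symmetric part of `mᵀPm` (with `P`
the landmark permutation). Without this step the decomposition would
depend on the arbitrary orientation of configuration 1.

Each aligned case then splits exactly: symmetric component
`s = (o + reflect(o))/2`, asymmetry vector `a = o − reflect(o)`, with
`o = s + a/2`. Because the reflection operator is a fixed orthogonal
involution, the symmetric and asymmetric subspaces are exactly
orthogonal and the variance identity
`total = symmetric + asymmetry/4` holds to machine precision. Directional
asymmetry is the mean of the `a` vectors; fluctuating asymmetry the
deviations. Sums of squares are reported on the `2n`-copy convention,
`SS_DA = n·|mean a|²/2`, with proportions of both the total and of the
asymmetric part alone (the literature is ambiguous about which
denominator a "percent of total" refers to, so both are given). With
balanced replicates, `procrustes_anova_symmetry()` adds a measurement
error stratum; degrees of freedom come from counting the symmetric and
asymmetric tangent-subspace dimensions. The uncentered asymmetry PCA
maximizes mean squared deviation from *zero* (perfect symmetry) via the
SVD of the uncentered asymmetry matrix, so a directional pattern emerges
along leading axes that ordinary (mean-centered) PCA cannot show.

## Ordination and covariance comparison

`pca()` is the covariance eigendecomposition (denominator `n − 1`
throughout; group-mean covariances use `g − 1`), with the deterministic
sign convention that each axis's largest loading is positive. `bgpca()`
takes the PCs of the unweighted group-mean matrix (a weighted option
exists for unbalanced designs) and projects all cases; with two groups
the single axis is the normalized mean difference. Because the axes are
chosen to spread the very group means being scored, identical
distributions separate spuriously when variables are numerous; the
`cross_validate` option scores each case on axes computed without it,
which the suite shows removes most of that artifact. `cva_on_pcs()`
performs CVA on a stated number of leading PCs (the within-group
covariance must be inverted, so reduction is mandatory — shape
coordinates are never full rank), whitens within-group variance so CV
scores have unit pooled within-group variance, and back-transforms axes
to coordinate space for visualization as deformations. Run on half as
many PCs as cases, it separates even identically distributed groups
completely — reproduced in the tests as a caution, with classification
rates (LOOCV QDA with the PCA recomputed inside each fold, equal priors,
ties to the lower group index) as the honest check: identical
distributions classify at chance.

Relative eigenanalysis generalizes variance *ratios*: the generalized
eigendecomposition of one covariance with respect to another, whose
eigenvalues (descending) are the extreme variance ratios, invariant under
any common nonsingular transform of both matrices and hence largely
independent of landmark spacing. The product of relative eigenvalues
equals the generalized variance ratio `det(A)/det(B)`, and the root
summed squared log relative eigenvalues is a symmetric affine-invariant
covariance metric; both identities are asserted numerically. There is no
automatic PC-count selection anywhere: a default of the smallest count
reaching 90% cumulative variance would invite exactly the artifacts the
package documents, so the count is always an explicit argument.

## Association methods

`shape_regression()` fits per-coordinate OLS of all shape/form
coordinates on one or more numeric predictors and reports two summary
statistics with deliberately different behavior: the multivariate R²
(explained share of total coordinate variance — shrinks as uninformative
coordinates are added) and the per-predictor score R² (association along
the normalized coefficient vector only — creeps upward as noise
dimensions accumulate weak sample associations). `pc_sensitivity_curve()`
recomputes either statistic, or the angle between group-wise coefficient
vectors, across PC counts, reproducing the characteristic
peak-then-decline, monotone-creep, and rising-angle patterns on simulated
signal-plus-noise data.

The latent-variable trio shares one scaffold: center both blocks, take an
SVD, read coefficient pairs off the singular vectors. PLS decomposes the
raw cross-covariance (coefficients proportional to covariances; no
inversion, but the maximized covariances grow with variable count even on
pure noise — asserted); reduced rank regression decomposes
`Sxx^(−1/2) Sxy` (x coefficients proportional to *partial* regression
coefficients; the leading singular value is the maximal slope of the
dependent latent variable on a unit-variance independent latent
variable); CCA whitens both sides (correlations in [0, 1]). Each is
verified against brute-force grid maximization or `stats::cancor` on
small blocks, and the characteristic invariances hold: RRR to nonsingular
transforms of x, CCA of both blocks, PLS of neither. Reported slopes use
two documented normalizations: the singular values (descending by
construction) and `slope_unit_norm`, the slope recomputed with unit-norm
coefficients, which reduces to the OLS slope in the univariate case.
Latent-score signs are fixed by positive covariance with the first x
variable. Default regularization is PC reduction rather than ridge, to
keep the reduced axes inspectable as shape features.

## Spatial scale

The variance of each partial warp's scores (summed over axes) against its
inverse bending-energy eigenvalue is the package's scale spectrum. Under
the isotropic Mardia-Dryden model the spectrum is flat (slope ≈ 0, the
orthonormal warp basis preserves isotropy); under the self-similar model
nonaffine variance is constant per scale, giving a log-log OLS slope of 1
in 2D and 2 in 3D. Slopes above the self-similar value indicate
coordinated variation, below it compensatory variation. The regression is
unweighted over distinct eigenvalues with ties averaged first; zero
variances are dropped with a warning; affine variation is excluded
throughout (bending energy is undefined for it). `relative_intrinsic_warps()`
runs relative eigenanalysis of the nonaffine score covariance against the
diagonal self-similar reference `λ^(−s)` per warp (`s` = 1 or 2 by
dimension, exposed as a parameter since the defining slopes, not the
generative exponent, are the primary statement) — directions of maximal
variance *relative to what their spatial scale predicts*, invariant to a
uniform rescaling of all eigenvalues. `per_cell_nonaffine_variance()`
implements the per-cell comparison: isotropic samples lose
size-standardized nonaffine shape variance with cell size, self-similar
samples keep it constant.

## Simulation models and what they do (not) emulate

The generators define the study conditions under which everything above
is tested.

* `sample_mardia_dryden()` — iid Gaussian coordinate noise around a
  template; the "pure noise" null under which centroid size is
  uncorrelated with shape.
* `sample_self_similar()` — independent partial-warp scores with SD
  `σ (λ/λ_min)^(−s/2)`, so the largest-scale warp has SD `σ` (default
  0.05 on unit-spaced grids) and affine variation is zero. With `s = 0`
  it spreads equal variance over every warp: the flat nonaffine spectrum
  of the isotropic model, against which the suite cross-checks it (the
  two generators are distinct constructions — warp-basis versus
  coordinate-basis noise — that share the nonaffine second moments at
  `s = 0`).
* `four_landmark_demo()` — the minimal integration demonstration: four
  landmarks on a unit square (`σ = 0.05` of the side) whose six
  interlandmark distances and eight shape coordinates are necessarily
  correlated because shape has only four degrees of freedom. The square
  template makes the leading shared-distance correlation `cos 45°/2 ≈
  0.354` analytically; the template is a parameter for exploring other
  mean shapes.
* `sample_group_study()` — two groups of 100 (defaults) with a group
  mean-shape difference (0.1), allometric shape change per unit log size
  (0.3), a continuous covariate effect (0.08 per covariate SD), lognormal
  sizes (log-SD 0.1, about ±10% size variation, typical of a
  within-age-group biological sample; the second group 5% larger), and
  isotropic noise (σ = 0.02). Effect magnitudes were chosen once so that
  effects are clearly present yet far from trivially separable, and so
  that coefficient directions are recoverable at the default n = 200 —
  e.g. the allometric signal-to-noise at these settings puts the
  coefficient cosine recovery just above 0.95. Effect vectors default to
  random smooth patterns (weights on the largest-scale partial warps) so
  simulated "biology" looks like coherent deformation, not white noise.
* `sample_bilateral_asymmetry()` — symmetric individual variation plus a
  directional asymmetry vector, fluctuating asymmetry, and per-replicate
  error. DA/FA vectors are projected onto the asymmetric *tangent*
  subspace (similarity components removed) because superimposition would
  silently absorb any rotation/translation content of a raw antisymmetric
  vector and the generated effect would not be the recovered one.

What these generators do **not** emulate: landmark digitizing error
structure (correlated within observer sessions), curved-surface geometry
of real anatomy (grids are flat), allometric curvature (effects are
linear in log size), non-Gaussian tails, and missing landmarks. Passing
tests therefore show that the algorithms are correct under their stated
models — not that real data meet those models.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible
from it. The test suite and the acceptance script run at desk scale:
n = 5000 four-landmark configurations for the correlation demonstration,
n = 1000 for each self-similar slope, 20 × n = 100 for the chance
classification average, and a few hundred cases elsewhere — sizes at
which the Monte-Carlo error is comfortably below the assertion tolerances
while the whole suite completes in well under a minute per file.
`scripts/acceptance.R --seed <s> --out <path>` recomputes the headline
numbers from scratch and writes them as JSON.

## Known limitations

Full least-squares and resistant (median) Procrustes variants, EDMA,
rotational/nested symmetries, permutation tests of latent-variable
statistics, automated landmark placement, image/pixel warping, and
phylogenetic methods are out of scope. The mesh tooling is a minimal OBJ
reader and exact-but-brute-force nearest-point projection, adequate for
the semilandmark primitive chain on desk-scale meshes, not a general mesh
library. Tangent-space linearization assumes small shape variation;
samples with very large deformations should be examined with care.
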