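---
title: "Shape variation, disparity and modularity of equid skulls with morphomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape variation, disparity and modularity of equid skulls with morphomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomod)
```

## The analysis

`morphomod` implements a complete landmark-based workflow for comparing
skull shape across the extant equids — domesticated horses (H),
Przewalski's horses (P), donkeys (D) and zebras (Z) — and for asking how
cranial shape variation is organized into modules. The same machinery
applies to any landmark dataset with bilateral (object) symmetry and
group structure. This vignette explains the statistical procedures, the
parameters that matter, and the design decisions taken where the
methodology left genuine choices.

## Superimposition

All analyses start from a generalized Procrustes analysis (`gpa()`).
Every configuration is centred, scaled to unit centroid size, and rotated
to the running consensus; the consensus is re-estimated as the arithmetic
mean and iteration stops when its root-mean-square change falls below
`tol = 1e-10` (at most 100 iterations — converged runs typically need
fewer than ten). Two numerical choices deserve note:

* **Proper rotations only.** Reflections are excluded from every
  superimposition, so specimen handedness is preserved. Reflection enters
  in exactly one place, inside the symmetry decomposition.
* **No tangent-space projection by default.** For the small shape
  distances typical of congeneric skulls the spherical-to-tangent
  distortion is negligible; the aligned coordinates are analysed as is.

Crania are digitized in two sessions (dorsal and ventral side up), with
three reference landmarks captured twice. `merge_views()` maps the
ventral view into the dorsal frame by the least-squares **rigid**
transform fitted on the references — no scaling, because both views are
the same physical specimen in the same units. With exactly three
references the fit is near-exact, so the root-mean-square misfit over the
references is reported as a digitizing-error diagnostic rather than
consumed silently.

## The symmetric component

Skulls have object symmetry: the left and right sides are parts of one
structure. `symmetric_component()` follows the standard
reflect-and-relabel protocol. Each aligned configuration is reflected
(first coordinate axis negated) and its bilateral landmark pairs swapped
according to a `pairing_scheme()`; originals and reflections are
superimposed jointly; and the symmetric component of a specimen is the
average of its original with its reflected copy. The bundled pairing
tables for the 62-landmark cranium (26 pairs, 10 midline points) and the
24-landmark mandible (11 pairs, 2 midline points) are read from plain
two-column config files, so other schemes can be substituted.

Two implementation details make the decomposition exact rather than
approximate:

1. After the joint superimposition the consensus is rotated into the
   canonical orientation in which its symmetry plane coincides with the
   coordinate plane. The rotation is obtained in closed form: the optimal
   rotation `Q` carrying the reflected-relabelled consensus onto the
   consensus defines a symmetric orthogonal matrix `Q'F` (with `F` the
   axis reflection), whose eigenvector with eigenvalue −1 is the normal
   of the symmetry plane.
2. The per-specimen average of original and reflection is then projected
   onto the reflection-invariant subspace, `(s + rr(s))/2`. This
   projection is idempotent and linear, so `symmetric + asymmetric`
   reconstructs the aligned coordinates exactly and the symmetric
   component is a fixed point of reflect-and-relabel to machine
   precision — both properties are asserted in the test suite.

Tooth datasets (2D occlusal landmarks) have no object symmetry and skip
this stage entirely; `run_pipeline()` enforces that.

## Ordination, dimensionality and classification

The symmetric coordinates are ordinated by covariance PCA
(`shape_pca()`). Because the landmark count (186 coordinates for the
cranium) exceeds what discriminant analysis can stomach at these sample
sizes, the downstream analyses use only the first N principal components.

N is chosen by `select_dimensions()`: for each candidate N, the
leave-one-out cross-validated accuracy of an LDA on the first N scores is
averaged over repeated **balanced subsamples**, each group subsampled to
the smallest group's size. Balancing matters with group sizes as skewed
as 133/47/31/5 — without it the classifier is rewarded for guessing the
majority group. Priors are equal across groups for the same reason. Ties
are broken toward the smallest N (parsimony), and the default of 1000
resamples keeps the Monte-Carlo error on the accuracy curve well below
one percentage point. Two cautions from the method's behaviour under
pure noise, both exercised in the tests: the LOO accuracy of an LDA sits
slightly *below* chance for null data (the left-out specimen drags its
own group mean away from itself), and a single dataset's LOO accuracy is
itself a noisy draw around chance, so calibration checks must average
over independent datasets.

Group differences are tested by permutation ANOVA
(`procrustes_anova()`): the pseudo-F statistic
`(SSB/(g−1)) / (SSW/(n−g))` on the first N PCs, with the p-value the
fraction of group-label permutations (observed labelling included)
reaching the observed F. The p-value is therefore bounded below by
`1/(permutations+1)`; the default is 999 permutations. The statistic is
identical to the distance-based pseudo-F of permutational MANOVA on
Euclidean distances, and the test suite cross-checks it against
`vegan::adonis2`.

Classification (`cva_classify()`) reports leave-one-out accuracy with a
percentile confidence interval over balanced resampled designs, the
confusion matrix, per-specimen posteriors, and squared Mahalanobis
distances between group means in the N-PC space using the pooled
within-group covariance. Distances print as `D = sqrt(D²)`, the
convention of published distance tables. Groups too small to classify
reliably (the five Przewalski's crania; threshold `exclude_below = 6`)
are held out and assigned afterwards by `predict_excluded()`, whose
identification probability for a specimen is the fraction of resampled
balanced LDA fits assigning it to each group.

One ambiguity is deliberately left to the user: published analyses of
this design quote both a cross-validation-selected N (three PCs) and a
different N for the ANOVA (six PCs) and CVA (seventeen PCs for the
three-group analysis). `run_pipeline()` therefore exposes `N_anova` and
`N_cva` as explicit overrides and never infers one from the other.

## Disparity

Total disparity is the Procrustes variance: the summed squared distances
to the grand mean divided by `n − 1`. Foote's partial disparity
(`partial_disparity()`) attributes to each group the part of that sum
contributed by its members, `PD_g = Σ_{i∈g} d²(x_i, x̄)/(n−1)`, so that
partial disparities are exactly additive and percentages sum to 100 —
the property that makes the partition interpretable. A frequently seen
verbal description of the procedure (within-group-mean residuals
rescaled by group size) conflicts with this additivity; it is available
as `method = "literal"` for sensitivity analysis but is not the default.

## Modularity

The modularity analysis works on a **landmark correlation matrix**
(`landmark_correlation_matrix()`): for each pair of landmarks, the
congruence coefficient of their deviation vectors across specimens and
coordinate axes, in absolute value. For 62 landmarks this gives
`C(62,2) = 1891` unique correlations — which is also why the matrix must
be landmark-level rather than coordinate-level. Whether such matrices
should use congruence coefficients or per-axis correlations averaged is
not settled; congruence is the recorded choice here and the function is
the single place to swap it.

`emmli_fit()` compares correlation-partition models in the EMMLi style.
Each of four modularity hypotheses (tissue origin; six mammalian
modules; six functional modules; a horse-specific face/neurocranium
split) is expanded into four variants — pooled/separate within-module
and between-module correlations — and a no-modularity null completes
the 17-model set. Per correlation set, a single parameter ρ maximizes
the Gaussian likelihood of the Fisher-z transformed correlations with
standard deviation `1/sqrt(n_like − 3)`, with ρ searched on a grid over
[0, 0.995] in steps of 0.001. `K` counts the ρ parameters plus one, and
models are ranked by `AICc = −2logL + 2K + 2K(K+1)/(n_corr − K − 1)`
with the number of unique correlations as the AICc sample size. The
likelihood sample size `n_like` defaults to the specimen count carried
by the correlation matrix but is exposed as an argument, because usage
in the literature varies between specimen count and correlation count.
Refining a partition can only increase the maximized likelihood, so
nested variants satisfy `logL(d) ≥ logL(a)` — a property the tests
assert.

Module-level integration is the relative eigenvalue standard deviation
(`eigenvalue_dispersion()`), ψ ∈ [0, 1], computed on each module's own
correlation matrix after the module's landmarks are re-superimposed with
their own GPA; module disparity is the maximum (and mean) Procrustes
distance of specimens to the module consensus. Both max and mean are
reported because verbal definitions of "module disparity" vary; the
comparison tables default to the max. `compare_wild_domestic()` applies
the best-supported hypothesis separately to the domesticated pool (H)
and the wild pool (P/D/Z).

The landmark-to-module assignment tables bundled under `extdata` are
**synthetic reconstructions** from the anatomical definitions of the 62
landmarks (files are suffixed `_synthetic`); analyses of real specimen
data should substitute measured assignment tables via
`read_module_hypothesis()`.

## The synthetic generator — what it emulates, and what it cannot

`generate_dataset()` produces datasets with the statistical structure
the analyses assume: a bilaterally symmetric base shape respecting a
pairing scheme; symmetric group mean offsets (groups can share an offset
direction through a `family` column — the equid preset points the
Przewalski offset along the domestic-horse direction, mimicking the
caballine clade); per-specimen shape deviations with compound-symmetry
block correlation (`rho_within` inside modules, `rho_between` across)
projected onto the symmetric subspace; independent asymmetric noise; and
a random rigid motion plus scale per specimen so that superimposition is
genuinely exercised. Everything is a deterministic function of the seed.

The `equid_preset()` mirrors the study design: 62 landmarks in 3D with
the cranial pairing, groups of 133/47/31/5, six modules, and magnitudes
chosen so the generated data land in the empirically realistic regime —
total Procrustes variance around 0.002, three-group classification in
the mid-90s percent, and the small caballine group assigned to the
horses by predictive LDA.

Two consequences of Procrustes superimposition limit what
compound-symmetry simulations can show, and both are worth knowing when
reading test results:

* **Exchangeable module factors are partly translations.** A factor that
  shifts all landmarks of a module equally is removed by centring in
  proportion to the module's share of the landmarks. With exactly two
  modules the two factors alias into a single ± contrast whose
  between-module correlation is strongly *negative* — and absolute-value
  correlation matrices then show no within/between gap at all. The
  generator's default module map therefore uses at least three (by
  default up to six) blocks, and the block signal survives
  superimposition comfortably (the tests require a gap ≥ 0.3 at
  ρ_w = 0.8, ρ_b = 0.1).
* **Module-wise GPA absorbs the module's own common factor.** After a
  module is re-superimposed on its own, its exchangeable factor is
  largely gone, so ψ computed on compound-symmetry simulations is much
  lower than ψ on real skulls, and responds only weakly to ρ_w through
  that route. The monotonicity of ψ in ρ_w is therefore verified on
  simulated module data directly; real cranial modules owe their high
  integration to geometrically structured covariation that pure
  exchangeable simulation does not produce.

Neither limitation affects the real-data pipeline; they delimit what
passing synthetic tests demonstrate.

## Problem sizes and reproducibility

The test suite runs entirely on generated data: property checks use
12–20 landmarks and 14–45 specimens; calibration and recovery checks use
200 permutation-ANOVA null runs, 20 EMMLi recovery replicates
(k = 20, n = 100) and sweeps at n = 200; the end-to-end pipeline tests
use a scaled-down four-group design (14/8/8/3). The acceptance script
runs the preset at the full study size (216 specimens, 62 landmarks)
and completes in seconds. Every stochastic stage takes an explicit seed,
reruns with the same configuration are bit-identical, and each pipeline
run writes a manifest (versions, seeds, parameters) sufficient to replay
it.

## Known limitations

* Missing landmarks are rejected, not estimated; sliding semilandmarks
  are out of scope.
* The symmetrisation assumes matched object symmetry; it is not a
  matching-symmetry (paired-structure) analysis.
* Classification assumes the pooled within-group covariance is
  invertible in the chosen N — the error message advises reducing N.
* EMMLi-style model comparison treats correlations as independent data
  points; this is the method's standard simplification, inherited here.
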