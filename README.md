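# morphomod

Geometric morphometrics of equid skulls: shape variation, disparity and
cranial modularity.

## What this package is for

Extant equids — domesticated horses (H), Przewalski's horses (P),
donkeys (D) and zebras (Z) — differ subtly but consistently in skull
shape, and domestication is suspected of having reorganized how cranial
variation is structured. `morphomod` implements the full analysis
pipeline used to ask such questions with landmark data:

* **Superimposition** — generalized Procrustes analysis (GPA):
  configurations are centred, scaled to unit centroid size and rotated
  (proper rotations only) to minimize the summed squared distances to
  the consensus; separately digitized dorsal/ventral views are merged by
  a rigid transform fitted on shared reference landmarks.
* **Object symmetry** — each configuration is reflected and its
  bilateral landmark pairs relabelled; after joint superimposition the
  symmetric component `s = (x + rr(x))/2` is extracted exactly, and only
  it feeds the downstream analyses.
* **Ordination & classification** — covariance PCA of the symmetric
  shape data; cross-validated selection of the number of PCs under
  balanced subsampling (robust to group sizes as skewed as 133/47/31/5);
  permutation Procrustes ANOVA with pseudo-F
  `(SSB/(g−1))/(SSW/(n−g))`; leave-one-out LDA classification with
  resampled confidence intervals; Mahalanobis distances
  `D² = (μ₁−μ₂)ᵀ S⁻¹ (μ₁−μ₂)` on pooled within-group covariance;
  predictive assignment of held-out small groups.
* **Disparity** — total Procrustes variance `Σᵢ d²(xᵢ, x̄)/(n−1)` and its
  additive partition into Foote partial disparities
  `PD_g = Σ_{i∈g} d²(xᵢ, x̄)/(n−1)`.
* **Modularity** — landmark congruence-coefficient correlation matrices;
  maximum-likelihood comparison of 17 modularity models (4 hypotheses ×
  4 within/between variants + null) on Fisher-z transformed correlations
  ranked by AICc; per-module integration as relative eigenvalue standard
  deviation ψ and per-module disparity, compared between wild and
  domesticated pools.
* **Synthetic data** — a seeded generator of bilaterally symmetric,
  group-structured, modular landmark datasets (including an equid preset
  with the study's 62-landmark scheme and sample sizes), so the whole
  pipeline is testable without museum specimens.

Standard formats are supported: TPS files (TPSDig dialect) for 2D tooth
landmarks, wide coordinate tables with encoded specimen identifiers for
3D digitizer output, and plain-text config files for pairing schemes and
module hypotheses.

## Worked example

```r
library(morphomod)

cfg <- equid_preset(seed = 1)            # 62 landmarks, H/Z/D/P = 133/47/31/5
res <- run_pipeline(config = list(
  simulate = cfg, structure = "cranium",
  pairing  = cranium_pairing(),
  hypotheses = cranium_hypotheses(),
  max_N = 20, resamples = 200, permutations = 999, seed = 1))
```

The run logs one line per stage:

```
[simulate] n=216 k=62 m=3 seed=1
[gpa] converged=TRUE iterations=3
[symmetrise] asymmetric SS=0.02863
[pca] PC1-3=21.7%
[select-n] chosen N=16
[anova] F=7.995 p=0.001 (N=16)
[classify] accuracy=97.2% (N=16)
[predict] 5 excluded specimens from groups {P}
[disparity] total variance=0.002158
[modularity] best model=six_modules.d
[integration] psi domestic=0.178 wild=0.187
```

Reading the output: the four simulated groups differ strongly in mean
shape (permutation p = 0.001, the smallest value 999 permutations can
produce); leave-one-out LDA on the first 16 PCs classifies 97.2% of the
H/Z/D specimens correctly; the five Przewalski-like specimens — too few
to classify — are assigned to the horse group by predictive LDA;

```r
res$disparity
#> Disparity (total Procrustes variance 0.002158, method foote)
#>  group   n        PD percent
#>      D  31 3.016e-04   13.97
#>      H 133 1.334e-03   61.82
#>      P   5 4.789e-05    2.22
#>      Z  47 4.745e-04   21.99
```

horses dominate the occupied shape space, and the partial disparities
sum exactly to the total variance. The modularity comparison recovers
the generating six-module model with separate within- and
between-module correlations (`six_modules.d`) as the best-supported of
the 17 candidates.

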