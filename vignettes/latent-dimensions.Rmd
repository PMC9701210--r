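---
title: "Validated latent brain-behaviour dimensions: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated latent brain-behaviour dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentcca)
```

# The model

`latentcca` looks for *latent dimensions* linking two views of the same
participants: a brain-structure view **X** (participants x parcels,
concatenating feature blocks such as grey matter volume, cortical thickness
and surface area) and a behavioural view **Y** (participants x questionnaire
and task scores). A latent dimension is a weight pair (**u**, **v**) chosen
so that the scores **Xu** and **Yv** are maximally correlated — their Pearson
correlation is the *canonical correlation*. Because both views have many
correlated features and finite samples, plain CCA overfits badly; the package
therefore uses *regularized* CCA,

maximise u' Cxy v subject to u'[(1-c_x) Cxx + c_x I]u = 1 and
v'[(1-c_y) Cyy + c_y I]v = 1,

where c in [0, 1] interpolates between classical CCA (c = 0) and the PLS
limit (c = 1, weights equal to the leading singular vectors of the
cross-covariance). Covariances use the (n-1) denominator and are centered
within the fitting set only.

**Solver.** Each view is whitened by its regularised covariance via the
economy SVD of the centered data, and the whitened cross-covariance is
resolved by SVD. Weights always lie in the row space of the data, so the
computation is carried out in the participant-space basis and stays exact
and cheap when features far outnumber participants. Singular values below
1e-10 of the largest are treated as zero. Two conventions remove ambiguity:
(u, v) and (-u, -v) are the same model, so every fit is oriented to make the
largest-magnitude behaviour loading positive; and the reported canonical
correlation is always the plain Pearson correlation of the scores, not the
correlation in the regularised metric.

**Loadings** — the Pearson correlation of each original variable with its
view's score — are the interpretable face of a dimension and the quantity
compared across splits and cohorts. Weights are never averaged across
splits; only loadings are.

**Deflation.** After a significant dimension is found, its variance is
removed by *projection deflation* per view: X <- (I - ss'/s's)X with s = Xu,
and likewise for Y. This guarantees that successive scores are orthogonal on
the deflating set. The exact deflation variant used by earlier toolkits is
not uniquely determined; projection deflation was chosen for that
orthogonality guarantee, applied within each outer split with that split's
own optimisation-set model so holdout data never contribute.

# The multiple-holdout framework

The framework guards against overfitting with two nested levels of
family-aware splits (no family is ever divided across a split side, because
relatives have correlated data that would otherwise leak):

* **outer splits** (default 5): optimisation set (80%) vs holdout set (20%);
* **inner splits** (default 5 per outer split): training (80%) vs testing
  (20%) of the optimisation set.

Per outer split the pipeline is: (1) normalise brain features participant-
wise by the block totals (GMV by the TIV-analogue, CT by mean CT, SA by
total SA) — a per-row operation with no leakage; (2) regress age and gender
(optionally site dummies and other confounds) out of both views with
coefficients estimated on the training data only and applied unchanged to
test and holdout data; (3) grid-search (c_x, c_y) on the inner splits;
(4) refit on the full optimisation set and project the holdout set.

**Hyperparameter selection.** Each grid cell is scored by the mean inner-test
canonical correlation and by stability — the mean pairwise sign-aligned
Pearson similarity of the weight vectors across inner splits, averaged over
u and v. The published description requires "the highest test canonical
correlation and stability" without a combination rule; this package ranks
cells on each criterion separately, selects the best average rank, and breaks
ties toward larger c_x + c_y (more regularised, more conservative). The rule
is deliberately free of an arbitrary weighting constant and is configurable.
The default grid {0, 0.3, 0.6, 0.9, 0.99, 1} is log-dense near 1 where
high-dimensional views need shrinkage.

**Scores for downstream genetics.** Published analyses of this kind feed
"scores averaged over the splits" to later stages without a precise recipe.
The package records both variants: the full cohort projected onto each
split's model and averaged (every participant covered), and holdout-only
scores averaged over the splits in which a participant was actually held out
(NA if never held out). The genetics stage reports both as a sensitivity
pair, since within-sample scores can inflate heritability estimates.

# Permutation inference and the omnibus decision

Significance per outer split comes from a permutation test with frozen
hyperparameters: in each of 1000 iterations the rows of Y are shuffled
independently within the optimisation and within the holdout set, the model
is refitted with the already-selected (c_x, c_y) — never re-selected — and
the permuted holdout correlation is recorded. Shuffling respects the family
structure through exchangeability blocks: whole families swap only with
families of identical composition (the multiset of MZ/DZ/singleton member
types) and members permute only within their type. For an all-singleton
cohort this reduces to a uniform permutation.

p = #(null > observed)/n_perm, floored at 1/n_perm; ties do not count
against the observed statistic. Bonferroni correction multiplies by the
number of outer splits (5), so the smallest reportable corrected p at 1000
permutations is 0.005. The omnibus null of "no effect in any split" is
rejected when any corrected p is *strictly* below alpha; a corrected p
exactly equal to alpha is not significant (documented boundary convention).
A `(count+1)/(n+1)` estimator is available as a config option; it matters
when the permutation count is small: with 100 permutations the strict rule's
floor makes the minimum corrected p exactly 5 x 0.01 = 0.05, which the
strict "<" omnibus can never reject, so type-I-error studies at reduced
permutation counts use the plus-one estimator (the package's calibration
test measures a rejection rate statistically indistinguishable from 0.05
over 200 null cohorts this way).

# Replicability and the spherical spin test

Dimensions are compared across cohorts on their split-averaged loadings:
behavioural loadings by Pearson correlation with its analytic p-value;
surface loadings (CT, SA) by the spin test, which preserves spatial
autocorrelation in the null; volumetric loadings (GMV, subcortex,
cerebellum) are excluded from spatial testing. A full family of a x b
dimensions x 3 loading families is Bonferroni-corrected by a x b x 3 (3 x 2
dimensions gives the familiar factor 18).

The spin test draws a Haar-uniform 3D rotation, applies it to the left
hemisphere's parcel centroids and its mirror image to the right hemisphere
(preserving hemispheric symmetry), and reassigns each rotated centroid the
nearest original parcel (great-circle distance, ties to the lowest index).
Each hemisphere lives on its own full unit sphere, as in surface-registration
coordinates. Duplicate assignments are allowed — the standard behaviour of
centroid-level spin tests — so a null map is value-containing but not an
exact permutation. The loading map is rotated; any reference map stays
fixed. Because the quoted one-sided rule ("null higher than observed") cannot
produce the significant *negative* map correlations such analyses report, the
default p-value compares magnitudes, p = #(|r_null| > |r_obs|)/n, which is
invariant to global sign flips of either map; the literal one-sided rule
remains available.

Under Haar rotations the rotated centroid of any parcel is uniform on the
sphere, so every source parcel shares a single image distribution (each
target parcel's spherical Voronoi share). The package's calibration tests
verify this measure-preserving property, that the spin test rejects at the
nominal 5% on independent smooth null maps, and that a naive exchangeable
permutation test on the same maps is anti-conservative.

# Twin-based variance decomposition

Latent scores are decomposed with an AE model: y ~ Normal(W beta,
2 Phi sigmaA^2 + I sigmaE^2), where 2 Phi is the kinship matrix (MZ co-twins
1, DZ co-twins and full siblings 0.5, unrelated 0) and h2 =
sigmaA^2/(sigmaA^2 + sigmaE^2) is narrow-sense heritability. A
shared-environment (C) component is deliberately out of scope — the AE model
matches the narrow-sense definition. Because the covariance is
sigma^2 [h2 K + (1-h2) I] and K is block-diagonal by family, each family
block is eigendecomposed once; the eigenvectors do not depend on the
parameters, so every likelihood evaluation reduces to weighted least squares
after one orthogonal transform. Fixed effects are profiled out by GLS, the
total variance by its closed form, and the 1-D profile likelihood is
optimised over h2 in [0, 1] to tolerance 1e-9. The test of sigmaA^2 = 0 uses
the boundary-corrected 50:50 mixture of a point mass at zero and
chi-square(1). When the likelihood is flat in h2 (no related pairs), the
parsimonious boundary h2 = 0 is reported with p = 1.

The bivariate fit stacks two traits with cross-covariance blocks
2 Phi rhoG sigmaAx sigmaAy + I rhoE sigmaEx sigmaEy; after the same family
transform the observations decouple into independent 2-vectors with 2 x 2
covariances lambda_i A + E, optimised over log-variances and Fisher-z
correlations from multiple starts (BFGS, relative tolerance 1e-12), with
1-df likelihood-ratio tests for rhoG = 0 and rhoE = 0. The likelihood is
unbounded when the traits are numerically identical (rho -> 1 makes the 2x2
covariance singular); a large finite penalty keeps the optimiser at the
boundary, where estimates are reported as > 0.99 rather than exactly 1. The
extended-covariate sensitivity fit uses TIV, age, age squared, gender and
both age-by-gender interactions as fixed effects.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every stage is validated, since the real restricted cohorts
cannot be redistributed. It emulates:

* two views sharing k planted dimensions: unit-variance latent variate pairs
  with the requested correlation rho; successive planted loading patterns
  are orthonormalised so planted variates are uncorrelated in expectation;
* additive-genetic structure: each latent variate is sqrt(h2) x genetic +
  sqrt(1-h2) x environmental, the genetic part drawn per family from the
  kinship Cholesky, so latent-score heritability equals `h2Target` and the
  genetic and environmental cross-view correlations both equal rho;
* observed features = pattern x variate + linear age/gender effects +
  independent Gaussian noise (default sd 0.25 per feature against unit-norm
  patterns — strong enough that recovery is non-trivial, weak enough that
  holdout correlations track the planted rho with attenuation below 0.05);
* per-participant global size factors, log-normal with coefficient of
  variation 0.1, multiplying each brain block (the TIV / mean-CT / total-SA
  analogues that the normalisation stage must undo);
* family blocks: the default twin-cohort template draws families of 3-6
  members with exactly one twin pair (MZ with probability 0.475, the
  approximate MZ:DZ mix of large twin cohorts); an all-singleton template
  mirrors an unrelated replication cohort. Ages default to the 22-37 range
  (36-100 for the older-cohort template argument), gender is Bernoulli(0.5);
* surface geometry: each hemisphere is a full unit sphere with mirrored
  random centroids; smooth loading patterns are drawn from a Gaussian field
  with exponential great-circle kernel (length-scale 0.5 rad), so spin-test
  validation faces realistic spatial autocorrelation;
* rho = 1 with a nonzero noise floor is rejected as infeasible;
  an optional switch discretises behavioural variables into ordinal levels
  to probe robustness to non-Gaussian scores.

What it does **not** emulate: mixed-type behavioural distributions (beyond
the ordinal switch), realistic atlas geometry, site batch effects beyond a
categorical label, nonlinear brain-behaviour relationships, and measurement
artefacts. Passing tests therefore demonstrate correctness of the machinery
under the stated generative model, not performance guarantees on real data.

One master seed drives everything: sub-streams (participants, patterns,
latents, noise, splits, permutations, rotations) are derived
deterministically from it, so identical seeds give bitwise-identical runs.
The atlas can be pinned separately (`atlasSeed`) so a discovery and a
replication cohort share parcellation geometry.

# Worked example

```{r example}
spec <- cohortSpec(
  familyBlocks = c(hcpYaFamilyBlocks(60, seed = 2), singletonFamilyBlocks(40)),
  nBehaviour = 8, brainBlocks = c(GMV = 12, CT = 10, SA = 10),
  planted = list(plantedDimension(0.6)), h2Target = 0.5, seed = 11)
cohort <- generateCohort(spec)
cohort

config <- frameworkConfig(cGrid = c(0.3, 1), nInner = 3, nPerm = 100,
                          maxDimensions = 2, seed = 5)
results <- runFramework(cohort, config)
splitSummary(results[[1]])

rep <- heritabilityOfDimension(results[[1]], cohort)
rep$averaged$brain
rep$averaged$bivariate
```

# Numerical choices and problem sizes

Tolerances: singular values below 1e-10 of the largest are zero; deflation
orthogonality holds to 1e-10; the univariate profile likelihood is optimised
to 1e-9; equality with the classical CCA oracle is asserted to 1e-8. Tie
breaks: grid cells toward larger c_x + c_y; nearest-centroid ties toward the
lowest parcel index. Degenerate inputs (zero-variance views, constant maps,
zero weight vectors, rank-deficient confound designs) raise explicit errors
rather than propagating silently; a zero-variance variable's loading is NA,
never a silent 0.

The validation suite exercises the pipeline at deliberately modest problem
sizes chosen to keep full runs reproducible on a single CPU: oracle
equivalence on dozens of random small instances; recovery on 20 cohorts of
n = 800 with 70 brain and 12 behaviour features over a reduced 3-value grid;
type-I error on 200 null cohorts of ~100 participants with 100 permutations;
spin calibration on 500 map pairs with 150 rotations; heritability recovery
on 100 samples of 600 twin pairs. These sizes are statements about the test
design, and the binomial/Monte-Carlo tolerances in the tests are computed
for exactly these sizes.

# Known limitations

* Two views only; sparse (L1), kernel and multi-view variants are out of
  scope.
* AE decomposition only ({self, MZ, DZ/sibling, unrelated} relationship
  classes); no dominance, household or SNP-based components.
* The spin test operates at parcel-centroid level; vertex-level spins and
  variogram-matched surrogates are not implemented.
* Permutation p-values are raw rank statistics; no tail approximation, so
  resolution is limited by the permutation count.
* The selection rule for (c_x, c_y) and the deflation variant are principled
  choices among several defensible options; both are configurable and
  recorded per split in the outputs.
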