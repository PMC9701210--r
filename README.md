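# latentcca

Brain-behaviour association studies ask whether interindividual variability
in behaviour (cognition, emotion, alertness) lines up with interindividual
variability in brain structure (grey matter volume, cortical thickness,
surface area, summarised over atlas parcels). Naive canonical correlation
analysis on such data overfits and fails to replicate. `latentcca` is an R
package for researchers who want the whole validated workflow:

* **Regularized CCA.** Weight pairs (**u**, **v**) maximise u&prime;C<sub>xy</sub>v
  subject to u&prime;[(1&minus;c<sub>x</sub>)C<sub>xx</sub> + c<sub>x</sub>I]u = 1 (likewise for v), with
  c &isin; [0, 1] interpolating between classical CCA (c = 0) and the PLS limit
  (c = 1). Scores are **Xu**, **Yv**; the canonical correlation is their
  Pearson correlation; loadings are the correlations of original variables
  with the scores; successive dimensions are extracted by projection
  deflation.
* **Multiple-holdout validation.** Five outer splits (optimisation 80% /
  holdout 20%) times five inner splits (train 80% / test 20%), all splits
  respecting family structure; participant-wise brain-size normalisation and
  leakage-free confound regression; (c<sub>x</sub>, c<sub>y</sub>) selected on the inner splits
  by joint test-correlation + weight-stability ranking.
* **Family-restricted permutation inference.** Y rows shuffled within
  exchangeability blocks (families of identical composition), hyperparameters
  frozen, 1000 iterations per outer split, p floored at 1/n<sub>perm</sub>, Bonferroni
  over the five splits, omnibus rejection when any corrected p < &alpha;.
* **Replicability tools.** Split-averaged loadings with stability flags;
  cross-cohort comparison by Pearson correlation (behaviour) and
  hemisphere-symmetric spherical spin tests (surface maps), volumetric maps
  excluded from spatial testing.
* **Twin-based genetics.** AE maximum-likelihood variance decomposition
  against the kinship matrix 2&Phi; (MZ 1, DZ/sibling 0.5): narrow-sense
  heritability h&sup2; with boundary-corrected LRT, and bivariate genetic /
  environmental correlations (&rho;<sub>g</sub>, &rho;<sub>e</sub>) between the brain and behaviour
  scores.
* **A synthetic-cohort generator** with planted latent dimensions, twin
  families carrying additive-genetic signal, age/gender confound effects,
  global-size scaling and spatially smooth spherical loading patterns, so the
  full pipeline is testable against known ground truth without restricted
  data.

## Worked example

```r
library(latentcca)

spec <- cohortSpec(
  familyBlocks = c(hcpYaFamilyBlocks(60, seed = 2), singletonFamilyBlocks(40)),
  nBehaviour = 8, brainBlocks = c(GMV = 12, CT = 10, SA = 10),
  planted = list(plantedDimension(0.6)), h2Target = 0.5, seed = 11)
cohort <- generateCohort(spec)
cohort
#> Cohort: 295 participants, 32 brain features ( CT:10, GMV:12, SA:10 ), 8 behavioural variables
#>   families: 100 | zygosity: DZ=54 MZ=66 S=175
#>   synthetic cohort with 1 planted dimension(s)

config <- frameworkConfig(cGrid = c(0.3, 1), nInner = 3, nPerm = 100,
                          maxDimensions = 2, seed = 5)
results <- runFramework(cohort, config)
splitSummary(results[[1]])
#>   split cx  cy holdoutCor    p pCorrected
#> 1     1  1 1.0  0.5571834 0.01       0.05
#> 2     2  1 1.0  0.4064511 0.01       0.05
#> 3     3  1 1.0  0.5702615 0.01       0.05
#> 4     4  1 0.3  0.4982261 0.01       0.05
#> 5     5  1 1.0  0.6158891 0.01       0.05
```

One latent dimension was planted with cross-view correlation 0.6 and the
holdout correlations across the five outer splits track it (0.41-0.62; the
spread reflects the 59-participant holdout sets). Each split's p-value sits
at the 1/100 floor of this short demonstration run; with the default 1000
permutations the floor is 0.001 (corrected 0.005). The selected
regularisation leans to c = 1, as expected when features are many and noisy.

```r
rep <- heritabilityOfDimension(results[[1]], cohort)
rep$averaged$brain
#> AE fit: h2 = 0.431 (sigmaA2=0.43, sigmaE2=0.567), LRT p = 2.956e-06
rep$averaged$bivariate
#> Bivariate AE fit: h2 = (0.440, 0.537); rhoG = 0.710 (p=6.339e-05), rhoE = 0.481 (p=1.211e-05)
```

The planted latent heritability was 0.5; the brain-score estimate lands near
it, and the bivariate fit shows the shared genetic influence between the
brain and behaviour scores that the generator planted. Writing a cohort or a
result set to disk (`writeCohort`, `writeDimensionResults`) produces plain
TSV/JSON files plus a manifest whose seed reproduces the run bitwise.

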