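makePed <- function(...) {
  tw <- generateTwinSample(...)
  tw
}

test_that("kinship coefficients match the standard coefficients of relationship", {
  ped <- data.frame(
    id = c("m1", "m2", "d1", "d2", "s1", "x1"),
    family_id = c("A", "A", "A", "A", "A", "B"),
    pair_id = c("A_MZ", "A_MZ", "A_DZ", "A_DZ", NA, NA),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "S", "S"))
  K <- buildKinship(ped)
  expect_equal(unname(diag(K)), rep(1, 6))
  expect_equal(K["m1", "m2"], 1)      # MZ co-twins
  expect_equal(K["d1", "d2"], 0.5)    # DZ co-twins
  expect_equal(K["m1", "s1"], 0.5)    # full siblings
  expect_equal(K["m1", "x1"], 0)      # different families
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # contradictory links are rejected
  bad <- ped; bad$pair_id[1] <- NA
  expect_error(buildKinship(bad), "contradictory")
  bad2 <- ped; bad2$pair_id[5] <- "A_MZ"; bad2$zygosity[5] <- "MZ"
  expect_error(buildKinship(bad2), "contradictory")
})

test_that("per-family likelihood factorisation equals the joint likelihood", {
  tw <- generateTwinSample(20, 20, 10, h2 = 0.5, seed = 3)
  fit <- fitAeUnivariate(tw$phenotype, NULL, tw$pedigree)
  K <- buildKinship(tw$pedigree)
  s2 <- fit@sigmaA + fit@sigmaE
  h2 <- fit@h2
  W <- matrix(1, length(tw$phenotype), 1)
  llJoint <- latentcca:::aeLogLikJoint(as.numeric(tw$phenotype), W, K, h2, s2,
                                       fit@beta)
  expect_equal(fit@logLik, llJoint, tolerance = 1e-8)
})

test_that("h2 recovery: mean estimate near truth, Falconer oracle agreement", {
  h2hat <- numeric(40); falconer <- numeric(40)
  for (s in 1:40) {
    tw <- generateTwinSample(300, 300, 0, h2 = 0.7, seed = 100 + s)
    fit <- fitAeUnivariate(tw$phenotype, NULL, tw$pedigree)
    h2hat[s] <- fit@h2
    zyg <- tw$pedigree$zygosity
    mz <- matrix(tw$phenotype[zyg == "MZ"], ncol = 2, byrow = TRUE)
    dz <- matrix(tw$phenotype[zyg == "DZ"], ncol = 2, byrow = TRUE)
    falconer[s] <- 2 * (cor(mz[, 1], mz[, 2]) - cor(dz[, 1], dz[, 2]))
  }
  expect_lt(abs(mean(h2hat) - 0.7), 0.05)
  # independent closed-form oracle agrees within simulation error
  expect_lt(abs(mean(h2hat) - mean(falconer)), 0.05)
})

test_that("null phenotypes give small h2 and a calibrated boundary LRT", {
  rejections <- 0L; h2s <- numeric(60)
  for (s in 1:60) {
    tw <- generateTwinSample(60, 60, 30, h2 = 0, seed = 200 + s)
    fit <- fitAeUnivariate(tw$phenotype, NULL, tw$pedigree)
    h2s[s] <- fit@h2
    if (fit@pH2 < 0.05) rejections <- rejections + 1L
  }
  expect_lt(mean(h2s), 0.15)
  expect_lte(rejections, 9L)  # ~binomial(60, 0.05) upper bound
  # singletons only: likelihood flat in h2, parsimony picks 0, LRT p = 1
  tw0 <- generateTwinSample(0, 0, 80, h2 = 0.5, seed = 5)
  fit0 <- fitAeUnivariate(tw0$phenotype, NULL, tw0$pedigree)
  expect_equal(fit0@h2, 0)
  expect_equal(fit0@pH2, 1)
})

test_that("estimates are invariant to affine rescaling of the phenotype", {
  tw <- generateTwinSample(150, 150, 50, h2 = 0.6, seed = 9)
  f1 <- fitAeUnivariate(tw$phenotype, NULL, tw$pedigree)
  f2 <- fitAeUnivariate(5 * tw$phenotype + 3, NULL, tw$pedigree)
  expect_equal(f1@h2, f2@h2, tolerance = 1e-5)
  expect_equal(25 * f1@sigmaA, f2@sigmaA, tolerance = 1e-4)
  # likelihood nesting: fitted optimum is at least the h2 = 0 value
  yt <- latentcca:::famTransform(latentcca:::famEigen(tw$pedigree),
                                 as.numeric(tw$phenotype))
  expect_gte(f1@logLik,
             latentcca:::aeProfile(0, drop(yt),
                                   latentcca:::famTransform(
                                     latentcca:::famEigen(tw$pedigree),
                                     matrix(1, length(yt), 1)),
                                   latentcca:::famEigen(tw$pedigree)$lambda)$ll)
})

test_that("covariate fixed effects are removed before decomposition", {
  tw <- generateTwinSample(200, 200, 0, h2 = 0.7, seed = 11)
  set.seed(12)
  age <- runif(length(tw$phenotype), 20, 40)
  y <- tw$phenotype + 0.2 * age
  fitNo <- fitAeUnivariate(y, NULL, tw$pedigree)
  fitCov <- fitAeUnivariate(y, data.frame(age = age), tw$pedigree)
  # the age effect inflates the environmental share unless adjusted
  expect_gt(fitCov@h2, fitNo@h2)
  expect_lt(abs(fitCov@h2 - 0.7), 0.12)
  expect_equal(unname(fitCov@beta["age", 1]), 0.2, tolerance = 0.05)
  expect_error(fitAeUnivariate(y, data.frame(a = age, b = 2 * age),
                               tw$pedigree), "rank-deficient|degenerate")
})

test_that("bivariate fit: identical traits hit the correlation boundary", {
  tw <- generateTwinSample(100, 100, 0, h2 = 0.6, seed = 13)
  fit <- fitAeBivariate(tw$phenotype, tw$phenotype, NULL, tw$pedigree)
  expect_gt(fit@rhoG, 0.99)
  expect_gt(fit@rhoE, 0.99)
})

test_that("bivariate recovery of rhoG/rhoE and the decomposition identity", {
  rg <- numeric(15); re <- numeric(15); idGap <- numeric(15)
  for (s in 1:15) {
    n <- 800  # 400 MZ + 400 DZ pairs worth of participants via 200+200 pairs
    tw <- generateTwinSample(200, 200, 0, h2 = 0, seed = 300 + s)
    ped <- tw$pedigree
    # plant a bivariate AE structure directly: h2x=0.8, h2y=0.7, rhoG=0.6, rhoE=0.2
    fe <- latentcca:::famEigen(ped)
    nI <- nrow(ped)
    gx <- latentcca:::withSeed(400 + s, latentcca:::geneticValues(ped))
    gy0 <- latentcca:::withSeed(500 + s, latentcca:::geneticValues(ped))
    gy <- 0.6 * gx + sqrt(1 - 0.36) * gy0
    set.seed(600 + s)
    ex <- rnorm(nI); ey <- 0.2 * ex + sqrt(1 - 0.04) * rnorm(nI)
    x <- sqrt(0.8) * gx + sqrt(0.2) * ex
    y <- sqrt(0.7) * gy + sqrt(0.3) * ey
    fit <- fitAeBivariate(x, y, NULL, ped)
    rg[s] <- fit@rhoG; re[s] <- fit@rhoE
    phenCor <- sqrt(prod(fit@h2)) * fit@rhoG +
      sqrt(prod(1 - fit@h2)) * fit@rhoE
    idGap[s] <- abs(phenCor - cor(x - mean(x), y - mean(y)))
  }
  expect_lt(abs(mean(rg) - 0.6), 0.1)
  expect_lt(abs(mean(re) - 0.2), 0.1)
  expect_lt(mean(idGap), 0.02)   # fitted phenotypic correlation identity
})

test_that("dimension-level heritability recovers the planted latent h2", {
  spec <- cohortSpec(
    c(rep(list(c("MZ", "MZ", "S")), 120), rep(list(c("DZ", "DZ", "S")), 120)),
    nBehaviour = 10, brainBlocks = c(GMV = 20, CT = 10, SA = 10),
    planted = list(plantedDimension(0.7)), h2Target = 0.7,
    noiseSd = 0.15, seed = 71)
  coh <- generateCohort(spec)
  res <- runFramework(coh, quickConfig(seed = 71))[[1]]
  rep <- heritabilityOfDimension(res, coh)
  expect_lt(abs(rep$averaged$brain@h2 - 0.7), 0.15)
  expect_lt(abs(rep$averaged$behaviour@h2 - 0.7), 0.15)
  expect_lt(rep$averaged$brain@pH2, 0.001)
  expect_s4_class(rep$averaged$bivariate, "VarianceComponents")
  expect_gt(rep$averaged$bivariate@rhoG, 0.3)
  # covariate-extended refit moves estimates by little when nothing is planted
  expect_lt(abs(rep$extendedCovariates$brain@h2 - rep$averaged$brain@h2), 0.1)
  # holdout-score sensitivity variant exists and is in range
  expect_false(is.null(rep$holdout))
  expect_true(rep$holdout$brain@h2 >= 0 && rep$holdout$brain@h2 <= 1)
})
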