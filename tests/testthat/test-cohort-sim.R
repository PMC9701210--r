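test_that("planted latent variates carry the requested cross-view correlation", {
  rs <- vapply(1:50, function(s) {
    spec <- cohortSpec(singletonFamilyBlocks(800), nBehaviour = 6,
                       brainBlocks = c(GMV = 10),
                       planted = list(plantedDimension(0.5)), seed = s)
    tr <- cohortTruth(generateCohort(spec))
    cor(tr$latentBrain[, 1], tr$latentBehaviour[, 1])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.02)
  expect_gte(mean(abs(rs - 0.5) <= 0.06), 0.9)
})

test_that("a study-sized spec yields the study's view dimensions", {
  spec <- cohortSpec(hcpYaFamilyBlocks(60, seed = 9), nBehaviour = 32,
                     brainBlocks = c(GMV = 239, CT = 200, SA = 200),
                     planted = list(plantedDimension(0.4)), seed = 9)
  coh <- generateCohort(spec)
  expect_identical(ncol(brainView(coh)), 639L)
  expect_identical(ncol(behaviourView(coh)), 32L)
  expect_identical(sort(unique(parcelTable(coh)$block)), c("CT", "GMV", "SA"))
})

test_that("cohorts are structurally valid and deterministic in the seed", {
  c1 <- smallCohort(seed = 3)
  c2 <- smallCohort(seed = 3)
  expect_identical(brainView(c1), brainView(c2))
  expect_identical(participantInfo(c1), participantInfo(c2))
  expect_true(validObject(c1))
  # every participant belongs to exactly one family
  meta <- participantInfo(c1)
  expect_false(anyNA(meta$family_id))
  # a different seed changes the data
  expect_false(identical(brainView(c1), brainView(smallCohort(seed = 4))))
})

test_that("infeasible and invalid specs are rejected", {
  expect_error(cohortSpec(singletonFamilyBlocks(10), nBehaviour = 4,
                          brainBlocks = c(GMV = 5),
                          planted = list(plantedDimension(1))),
               "infeasible")
  expect_error(plantedDimension(1.2), "\\[0, 1\\]")
  expect_error(cohortSpec(singletonFamilyBlocks(10), nBehaviour = 4,
                          brainBlocks = c(GMV = 5), h2Target = 1.5),
               "h2Target")
  expect_error(cohortSpec(list(c("MZ")), nBehaviour = 4,
                          brainBlocks = c(GMV = 5)),
               "pairs")
  expect_error(cohortSpec(singletonFamilyBlocks(10), nBehaviour = 4,
                          brainBlocks = c(CT = 7)),
               "even")
})

test_that("sphere parcellation is unit-norm, mirrored and spin-identity-consistent", {
  atlas <- generateSphereParcellation(100, seed = 2)
  expect_identical(nrow(atlas), 200L)
  norms <- sqrt(atlas$x^2 + atlas$y^2 + atlas$z^2)
  expect_lt(max(abs(norms - 1)), 1e-12)
  L <- atlas[atlas$hemisphere == "L", ]; R <- atlas[atlas$hemisphere == "R", ]
  expect_equal(L$x, -R$x, tolerance = 0)
  expect_equal(L$y, R$y, tolerance = 0)
  expect_equal(L$z, R$z, tolerance = 0)
  expect_error(generateSphereParcellation(3), "at least 4")
})

test_that("planted loading patterns are recoverable at moderate noise", {
  ok <- 0L
  for (s in 1:20) {
    spec <- cohortSpec(singletonFamilyBlocks(800), nBehaviour = 12,
                       brainBlocks = c(GMV = 40, CT = 20, SA = 20),
                       planted = list(plantedDimension(0.5)), seed = 400 + s)
    coh <- generateCohort(spec)
    X <- scale(brainView(coh), scale = FALSE)
    Y <- scale(behaviourView(coh), scale = FALSE)
    m <- fitRcca(X, Y, 0.5, 0.5)
    lo <- computeLoadings(X, Y, projectScores(m, X, Y))
    tr <- cohortTruth(coh)
    cb <- abs(sum(lo$brain * tr$brainPatterns[, 1])) /
      sqrt(sum(lo$brain^2) * sum(tr$brainPatterns[, 1]^2))
    cv <- abs(sum(lo$behaviour * tr$behaviourPatterns[, 1])) /
      sqrt(sum(lo$behaviour^2) * sum(tr$behaviourPatterns[, 1]^2))
    if (cb > 0.9 && cv > 0.9) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("latent-score heritability in generated data matches the target", {
  # Falconer-style check on the planted latent variate itself
  h2hat <- vapply(1:20, function(s) {
    spec <- cohortSpec(c(rep(list(c("MZ", "MZ")), 150),
                         rep(list(c("DZ", "DZ")), 150)),
                       nBehaviour = 4, brainBlocks = c(GMV = 5),
                       planted = list(plantedDimension(0.5)),
                       h2Target = 0.6, seed = 500 + s)
    coh <- generateCohort(spec)
    z <- cohortTruth(coh)$latentBrain[, 1]
    meta <- participantInfo(coh)
    pairCor <- function(zy) {
      idx <- which(meta$zygosity == zy)
      m <- matrix(z[idx], ncol = 2, byrow = TRUE)
      cor(m[, 1], m[, 2])
    }
    2 * (pairCor("MZ") - pairCor("DZ"))
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.6), 0.07)
})

test_that("twin samples realise the AE covariance structure", {
  # limits: h2 = 1 gives MZ within-pair correlation ~1; h2 = 0 gives ~0
  tw1 <- generateTwinSample(400, 0, 0, h2 = 1, seed = 1)
  m1 <- matrix(tw1$phenotype, ncol = 2, byrow = TRUE)
  expect_gt(cor(m1[, 1], m1[, 2]), 0.999)
  tw0 <- generateTwinSample(400, 400, 0, h2 = 0, seed = 2)
  zyg <- tw0$pedigree$zygosity
  mz <- matrix(tw0$phenotype[zyg == "MZ"], ncol = 2, byrow = TRUE)
  dz <- matrix(tw0$phenotype[zyg == "DZ"], ncol = 2, byrow = TRUE)
  expect_lt(abs(cor(mz[, 1], mz[, 2])), 0.12)
  expect_lt(abs(cor(dz[, 1], dz[, 2])), 0.12)
  # Falconer estimate recovers h2 = 0.7 on average
  f <- vapply(1:30, function(s) {
    tw <- generateTwinSample(300, 300, 0, h2 = 0.7, seed = 10 + s)
    zyg <- tw$pedigree$zygosity
    mz <- matrix(tw$phenotype[zyg == "MZ"], ncol = 2, byrow = TRUE)
    dz <- matrix(tw$phenotype[zyg == "DZ"], ncol = 2, byrow = TRUE)
    2 * (cor(mz[, 1], mz[, 2]) - cor(dz[, 1], dz[, 2]))
  }, numeric(1))
  expect_lt(abs(mean(f) - 0.7), 0.05)
})

test_that("zero confounds and zero size noise leave preprocessing a no-op up to centering", {
  spec <- smallSpec(seed = 6, confoundEffects = list(age = 0, gender = 0),
                    globalSizeNoise = 0)
  coh <- generateCohort(spec)
  expect_true(all(sizeTotals(coh) == 1))
  X <- brainView(coh)
  Xn <- normaliseBrain(X, sizeTotals(coh), parcelTable(coh)$block)
  expect_identical(Xn, X)
  meta <- participantInfo(coh)
  ps <- fitPreprocess(X, meta[, c("age", "gender")])
  res <- applyPreprocess(ps, X, meta[, c("age", "gender")])
  # residuals equal the centered originals up to the finite-sample (by-chance)
  # association between the noise and the confounds
  ctr <- scale(X, scale = FALSE)
  expect_lt(sqrt(sum((res - ctr)^2) / sum(ctr^2)), 0.15)
  expect_gt(min(diag(cor(res, ctr))), 0.98)
})

test_that("ordinal discretisation produces the requested number of levels", {
  spec <- smallSpec(seed = 12, ordinalLevels = 5)
  coh <- generateCohort(spec)
  lv <- apply(behaviourView(coh), 2, function(x) length(unique(x)))
  expect_true(all(lv <= 5))
  expect_true(all(behaviourView(coh) %in% 1:5))
})
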