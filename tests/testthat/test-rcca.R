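test_that("a duplicated column yields canonical correlation 1", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  Y <- X[, 1, drop = FALSE]
  m <- fitRcca(X, Y, 0, 0)
  expect_equal(canonicalCorrelation(m), 1, tolerance = 1e-8)
})

test_that("c = 0 matches independent CCA oracles on random small instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(30:60, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    Y <- matrix(rnorm(n * 3), n, 3) + 0.5 * X
    m <- fitRcca(X, Y, 0, 0)
    expect_equal(canonicalCorrelation(m), oracleCca(X, Y), tolerance = 1e-8)
    # second, fully independent oracle from base R
    expect_equal(canonicalCorrelation(m), stats::cancor(X, Y)$cor[1],
                 tolerance = 1e-8)
  }
})

test_that("c = 1 matches the cross-covariance SVD (PLS limit)", {
  for (s in 1:25) {
    set.seed(100 + s)
    X <- matrix(rnorm(20 * 4), 20, 4)
    Y <- matrix(rnorm(20 * 3), 20, 3) + 0.3 * X[, 1:3]
    m <- fitRcca(X, Y, 1, 1)
    Cxy <- crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)) / 19
    sv <- svd(Cxy)
    expect_equal(abs(cosineSim <- sum(brainWeights(m) * sv$u[, 1]) /
                       sqrt(sum(brainWeights(m)^2))), 1, tolerance = 1e-6)
    expect_equal(abs(sum(behaviourWeights(m) * sv$v[, 1]) /
                       sqrt(sum(behaviourWeights(m)^2))), 1, tolerance = 1e-6)
    # constraint at c = 1 is unit Euclidean norm
    expect_equal(sum(brainWeights(m)^2), 1, tolerance = 1e-8)
  }
})

test_that("fitted models satisfy the regularised unit-variance constraints", {
  set.seed(7)
  X <- matrix(rnorm(60 * 10), 60, 10)
  Y <- matrix(rnorm(60 * 5), 60, 5) + 0.4 * X[, 1:5]
  for (cc in list(c(0, 0), c(0.5, 0.2), c(0.9, 0.9))) {
    m <- fitRcca(X, Y, cc[1], cc[2])
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    Cxx <- crossprod(Xc) / 59; Cyy <- crossprod(Yc) / 59
    u <- brainWeights(m); v <- behaviourWeights(m)
    expect_equal(drop(t(u) %*% ((1 - cc[1]) * Cxx + cc[1] * diag(10)) %*% u),
                 1, tolerance = 1e-8)
    expect_equal(drop(t(v) %*% ((1 - cc[2]) * Cyy + cc[2] * diag(5)) %*% v),
                 1, tolerance = 1e-8)
  }
})

test_that("solution is invariant (up to sign) to feature order", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rnorm(40 * 4), 40, 4) + 0.5 * X[, 1:4]
  m1 <- fitRcca(X, Y, 0.5, 0.5)
  perm <- sample(6)
  m2 <- fitRcca(X[, perm], Y, 0.5, 0.5)
  expect_equal(canonicalCorrelation(m1), canonicalCorrelation(m2),
               tolerance = 1e-10)
  expect_equal(abs(cor(brainWeights(m1)[perm], brainWeights(m2))), 1,
               tolerance = 1e-8)
})

test_that("projection reproduces the training correlation and flags degenerate scores", {
  set.seed(4)
  X <- matrix(rnorm(50 * 5), 50, 5); Y <- matrix(rnorm(50 * 3), 50, 3)
  m <- fitRcca(X, Y, 0.3, 0.3)
  pr <- projectScores(m, X, Y)
  expect_equal(pr$cor, canonicalCorrelation(m), tolerance = 1e-12)
  m0 <- m
  m0@u <- rep(0, 5)
  expect_error(projectScores(m0, X, Y), "constant scores|degenerate")
  expect_error(projectScores(m, X[, 1:3], Y), "feature counts")
})

test_that("loadings are Pearson correlations with NA for zero variance", {
  set.seed(5)
  X <- matrix(rnorm(1000 * 4), 1000, 4)
  Y <- matrix(rnorm(1000 * 2), 1000, 2) + 0.4 * X[, 1:2]
  m <- fitRcca(X, Y, 0.5, 0.5)
  pr <- projectScores(m, X, Y)
  # a variable identical to its own score has loading 1
  X2 <- cbind(X, pr$xu)
  lo <- computeLoadings(X2, Y, pr)
  expect_equal(lo$brain[5], 1, tolerance = 1e-12)
  # zero-variance variable is an explicit undefined marker, not a silent 0
  X3 <- cbind(X, 1)
  lo3 <- computeLoadings(X3, Y, pr)
  expect_true(is.na(lo3$brain[5]))
  # independent noise variable at large n has near-zero loading
  set.seed(6)
  X4 <- cbind(X, rnorm(1000))
  lo4 <- computeLoadings(X4, Y, pr)
  expect_lt(abs(lo4$brain[5]), 0.08)
})

test_that("projection deflation orthogonalises the deflating set and obeys Pythagoras", {
  set.seed(8)
  X <- scale(matrix(rnorm(60 * 8), 60, 8), scale = FALSE)
  Y <- scale(matrix(rnorm(60 * 4), 60, 4), scale = FALSE)
  m <- fitRcca(X, Y, 0.4, 0.4)
  d <- deflateViews(X, Y, m)
  expect_lt(max(abs(d$X %*% brainWeights(m))), 1e-10)
  expect_lt(max(abs(d$Y %*% behaviourWeights(m))), 1e-10)
  # Frobenius norm shrinks by exactly the removed rank-one component
  sx <- drop(X %*% brainWeights(m))
  removed <- sx %*% crossprod(sx, X) / sum(sx^2)
  expect_equal(sum(X^2), sum(d$X^2) + sum(removed^2), tolerance = 1e-8)
  expect_lte(sum(d$X^2), sum(X^2))
})

test_that("two planted orthogonal dimensions are recovered in sequence after deflation", {
  ok <- 0L
  for (s in 1:5) {
    spec <- cohortSpec(singletonFamilyBlocks(500), nBehaviour = 10,
                       brainBlocks = c(GMV = 30),
                       planted = list(plantedDimension(0.7),
                                      plantedDimension(0.5)),
                       confoundEffects = list(age = 0, gender = 0),
                       globalSizeNoise = 0, seed = 300 + s)
    coh <- generateCohort(spec)
    X <- scale(brainView(coh), scale = FALSE)
    Y <- scale(behaviourView(coh), scale = FALSE)
    tr <- cohortTruth(coh)
    m1 <- fitRcca(X, Y, 0.5, 0.5)
    l1 <- computeLoadings(X, Y, projectScores(m1, X, Y))
    d <- deflateViews(X, Y, m1)
    m2 <- fitRcca(d$X, d$Y, 0.5, 0.5)
    l2 <- computeLoadings(X, Y, projectScores(m2, d$X, d$Y))
    c1 <- abs(sum(l1$brain * tr$brainPatterns[, 1])) /
      sqrt(sum(l1$brain^2) * sum(tr$brainPatterns[, 1]^2))
    c2 <- abs(sum(l2$brain * tr$brainPatterns[, 2])) /
      sqrt(sum(l2$brain^2) * sum(tr$brainPatterns[, 2]^2))
    if (c1 > 0.85 && c2 > 0.85) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("degenerate inputs are rejected with explicit errors", {
  X <- matrix(0, 10, 3); Y <- matrix(rnorm(20), 10, 2)
  expect_error(fitRcca(X, Y, 0, 0), "zero variance")
  expect_error(fitRcca(matrix(1, 2, 2), matrix(1, 2, 2), 0, 0), "at least 3")
  expect_error(fitRcca(matrix(rnorm(30), 10, 3), Y, -0.1, 0), "\\[0, 1\\]")
})

test_that("training correlation exceeds holdout correlation on null data (overfitting direction)", {
  set.seed(42)
  diffs <- replicate(30, {
    X <- matrix(rnorm(40 * 6), 40, 6); Y <- matrix(rnorm(40 * 4), 40, 4)
    m <- fitRcca(X[1:30, ], Y[1:30, ], 0.5, 0.5)
    canonicalCorrelation(m) - projectScores(m, X[31:40, ], Y[31:40, ])$cor
  })
  expect_gt(mean(diffs), 0)
})
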