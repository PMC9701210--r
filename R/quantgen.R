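#' Kinship matrix (2 Phi) from a twin/sibling pedigree
#'
#' Coefficients of relationship for the pedigree universe handled here:
#' self 1, MZ co-twin 1, DZ co-twin or full sibling (same family) 0.5,
#' members of different families 0. Block-diagonal by family and positive
#' semidefinite.
#'
#' @param pedigree data.frame with columns \code{id}, \code{family_id},
#'   \code{pair_id} (shared by the two members of a twin pair, NA otherwise)
#'   and \code{zygosity} (\code{"MZ"}, \code{"DZ"} or \code{"S"}).
#' @return symmetric numeric matrix with dimnames = ids.
#' @export
buildKinship <- function(pedigree) {
  checkPedigree(pedigree)
  n <- nrow(pedigree)
  K <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (fam in split(seq_len(n), pedigree$family_id)) {
    K[fam, fam] <- kinshipBlock(pedigree$zygosity[fam], pedigree$pair_id[fam])
  }
  K
}

checkPedigree <- function(pedigree) {
  req <- c("id", "family_id", "pair_id", "zygosity")
  miss <- setdiff(req, colnames(pedigree))
  if (length(miss))
    stop("pedigree missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(pedigree$id)) stop("pedigree ids must be unique")
  twins <- pedigree[pedigree$zygosity %in% c("MZ", "DZ"), ]
  if (anyNA(twins$pair_id))
    stop("contradictory links: twin members must carry a pair_id")
  if (nrow(twins)) {
    bad <- names(which(table(twins$pair_id) != 2))
    if (length(bad))
      stop("contradictory links: pair(s) without exactly two members: ",
           paste(bad, collapse = ", "))
    for (p in unique(twins$pair_id)) {
      sub <- twins[twins$pair_id == p, ]
      if (length(unique(sub$family_id)) != 1 ||
          length(unique(sub$zygosity)) != 1)
        stop("contradictory links in pair ", p)
    }
  }
  invisible(TRUE)
}

## Per-family eigendecomposition of the kinship blocks. Because the AE
## covariance is sigma2 * (h2 * K + (1 - h2) * I), the eigenvectors do not
## depend on (h2, sigma2): transforming y and W once by the block-diagonal U'
## turns every likelihood evaluation into weighted least squares.
famEigen <- function(pedigree) {
  n <- nrow(pedigree)
  fams <- split(seq_len(n), pedigree$family_id)
  lambda <- numeric(n)
  rot <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    idx <- fams[[fi]]
    K <- kinshipBlock(pedigree$zygosity[idx], pedigree$pair_id[idx])
    e <- eigen(K, symmetric = TRUE)
    rot[[fi]] <- list(idx = idx, U = e$vectors)
    lambda[idx] <- e$values
  }
  list(rot = rot, lambda = lambda)
}

famTransform <- function(fe, M) {
  M <- as.matrix(M)
  out <- M
  for (r in fe$rot) out[r$idx, ] <- crossprod(r$U, M[r$idx, , drop = FALSE])
  out
}

## Profile log-likelihood of the univariate AE model at heritability h2:
## beta by GLS, total variance by its ML closed form.
aeProfile <- function(h2, yt, Wt, lambda) {
  n <- length(yt)
  d <- h2 * lambda + (1 - h2)
  if (any(d <= 0)) return(list(ll = -Inf))
  wy <- yt / d
  beta <- solve(crossprod(Wt, Wt / d), crossprod(Wt, wy))
  res <- yt - drop(Wt %*% beta)
  s2 <- sum(res^2 / d) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
  list(ll = ll, beta = beta, s2 = s2)
}

#' Univariate AE variance decomposition by maximum likelihood
#'
#' Fits y ~ Normal(W beta, 2 Phi sigmaA^2 + I sigmaE^2) by profiling the
#' fixed effects (GLS) and the total variance out of the likelihood and
#' optimising over h2 = sigmaA^2/(sigmaA^2 + sigmaE^2) in [0, 1]. The test of
#' sigmaA^2 = 0 uses the likelihood ratio against the h2 = 0 (OLS) null with
#' the boundary-corrected 50:50 mixture of a point mass at zero and
#' chi-square(1). When the likelihood is flat in h2 (e.g. no related pairs),
#' the estimate is taken at the parsimonious boundary h2 = 0.
#'
#' @param phenotype numeric vector.
#' @param covariates data.frame/matrix of fixed-effect covariates (an
#'   intercept is added; NULL for intercept only).
#' @param pedigree pedigree data.frame as in [buildKinship()], row-aligned
#'   with the phenotype.
#' @return a [VarianceComponents-class].
#' @export
fitAeUnivariate <- function(phenotype, covariates = NULL, pedigree) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (nrow(pedigree) != n) stop("pedigree must align with the phenotype")
  if (anyNA(y)) stop("phenotype must not contain missing values")
  W <- fixedDesign(covariates, n)
  fe <- famEigen(pedigree)
  yt <- drop(famTransform(fe, y))
  Wt <- famTransform(fe, W)
  obj <- function(h2) aeProfile(h2, yt, Wt, fe$lambda)$ll
  opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-9)
  ll0 <- obj(0)
  h2 <- opt$maximum
  ll1 <- opt$objective
  ## boundary candidates: optimize() never lands exactly on 0 or 1
  if (obj(1) >= ll1) { h2 <- 1; ll1 <- obj(1) }
  if (ll0 >= ll1 - 1e-8) { h2 <- 0; ll1 <- ll0 }
  at <- aeProfile(h2, yt, Wt, fe$lambda)
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- if (lrt <= 1e-12) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  methods::new("VarianceComponents",
    type = "univariate",
    sigmaA = h2 * at$s2, sigmaE = (1 - h2) * at$s2,
    h2 = h2, pH2 = p,
    rhoG = NA_real_, rhoE = NA_real_, pRhoG = NA_real_, pRhoE = NA_real_,
    beta = matrix(at$beta, ncol = 1,
                  dimnames = list(colnames(Wt), "trait")),
    logLik = ll1)
}

fixedDesign <- function(covariates, n) {
  if (is.null(covariates)) {
    W <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
    return(W)
  }
  W <- confoundDesign(as.data.frame(covariates))
  attr(W, "template") <- NULL
  if (qr(W)$rank < ncol(W)) stop("degenerate (rank-deficient) covariate design")
  W
}

## Negative log-likelihood of the bivariate AE model after the family
## eigen-transform: observation i has 2-vector (y1t_i, y2t_i) with covariance
## lambda_i * A + E, A/E the genetic/environmental 2x2 covariance matrices.
## Fixed effects are profiled out by GLS inside.
bivarNegLL <- function(theta, y1t, y2t, Wt, lambda, fixRhoG = NULL,
                       fixRhoE = NULL, value = FALSE) {
  a1 <- exp(theta[1]); a2 <- exp(theta[2])
  e1 <- exp(theta[3]); e2 <- exp(theta[4])
  i <- 5L
  rg <- if (is.null(fixRhoG)) { z <- theta[i]; i <- i + 1L; tanh(z) } else fixRhoG
  re <- if (is.null(fixRhoE)) tanh(theta[i]) else fixRhoE
  n <- length(y1t)
  o11 <- lambda * a1 + e1
  o22 <- lambda * a2 + e2
  o12 <- lambda * rg * sqrt(a1 * a2) + re * sqrt(e1 * e2)
  det2 <- o11 * o22 - o12^2
  bad <- !all(is.finite(det2)) || any(det2 <= 0) || any(o11 <= 0)
  ## large finite penalty keeps optim() away from the singular boundary
  ## (identical traits drive rho -> 1 where the likelihood is unbounded)
  if (bad) return(if (value) list(nll = 1e10) else 1e10)
  w11 <- o22 / det2; w22 <- o11 / det2; w12 <- -o12 / det2
  ## GLS for (beta1, beta2) with shared design Wt
  A11 <- crossprod(Wt, Wt * w11); A22 <- crossprod(Wt, Wt * w22)
  A12 <- crossprod(Wt, Wt * w12)
  r1 <- crossprod(Wt, w11 * y1t + w12 * y2t)
  r2 <- crossprod(Wt, w12 * y1t + w22 * y2t)
  p <- ncol(Wt)
  Amat <- rbind(cbind(A11, A12), cbind(A12, A22))
  beta <- tryCatch(solve(Amat, rbind(r1, r2)),
                   error = function(e) NULL)
  if (is.null(beta)) return(if (value) list(nll = 1e10) else 1e10)
  res1 <- y1t - drop(Wt %*% beta[seq_len(p), , drop = FALSE])
  res2 <- y2t - drop(Wt %*% beta[p + seq_len(p), , drop = FALSE])
  quad <- sum(w11 * res1^2 + 2 * w12 * res1 * res2 + w22 * res2^2)
  nll <- 0.5 * (2 * n * log(2 * pi) + sum(log(det2)) + quad)
  if (!is.finite(nll)) nll <- 1e10
  if (value)
    list(nll = nll, beta = matrix(beta, ncol = 2), a = c(a1, a2),
         e = c(e1, e2), rg = rg, re = re)
  else nll
}

bivarFit <- function(y1t, y2t, Wt, lambda, fixRhoG = NULL, fixRhoE = NULL) {
  v1 <- stats::var(y1t); v2 <- stats::var(y2t)
  base <- c(log(v1 / 2), log(v2 / 2), log(v1 / 2), log(v2 / 2))
  nRho <- is.null(fixRhoG) + is.null(fixRhoE)
  starts <- list(c(base, rep(0, nRho)),
                 c(base + c(0.5, 0.5, -0.5, -0.5), rep(0.3, nRho)),
                 c(base + c(-0.5, -0.5, 0.5, 0.5), rep(-0.3, nRho)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, bivarNegLL, y1t = y1t, y2t = y2t, Wt = Wt,
                   lambda = lambda, fixRhoG = fixRhoG, fixRhoE = fixRhoE,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("bivariate AE optimisation failed")
  out <- bivarNegLL(best$par, y1t, y2t, Wt, lambda, fixRhoG, fixRhoE,
                    value = TRUE)
  out$logLik <- -best$value
  out
}

#' Bivariate AE decomposition: genetic and environmental correlation
#'
#' Maximum-likelihood fit of the stacked two-trait AE model whose cross-trait
#' covariance blocks are 2 Phi rhoG sigmaAx sigmaAy + I rhoE sigmaEx sigmaEy.
#' Likelihood-ratio tests (chi-square, 1 df) are reported for rhoG = 0 and
#' rhoE = 0.
#'
#' @param phenotypeX,phenotypeY numeric vectors observed on the same
#'   participants.
#' @inheritParams fitAeUnivariate
#' @return a [VarianceComponents-class] with per-trait h2 and the correlation
#'   estimates.
#' @export
fitAeBivariate <- function(phenotypeX, phenotypeY, covariates = NULL,
                           pedigree) {
  y1 <- as.numeric(phenotypeX); y2 <- as.numeric(phenotypeY)
  n <- length(y1)
  if (length(y2) != n || nrow(pedigree) != n)
    stop("both phenotypes and the pedigree must align")
  if (anyNA(y1) || anyNA(y2)) stop("phenotypes must not contain missing values")
  W <- fixedDesign(covariates, n)
  fe <- famEigen(pedigree)
  y1t <- drop(famTransform(fe, y1)); y2t <- drop(famTransform(fe, y2))
  Wt <- famTransform(fe, W)
  full <- bivarFit(y1t, y2t, Wt, fe$lambda)
  noG <- bivarFit(y1t, y2t, Wt, fe$lambda, fixRhoG = 0)
  noE <- bivarFit(y1t, y2t, Wt, fe$lambda, fixRhoE = 0)
  lrtG <- max(0, 2 * (full$logLik - noG$logLik))
  lrtE <- max(0, 2 * (full$logLik - noE$logLik))
  methods::new("VarianceComponents",
    type = "bivariate",
    sigmaA = full$a, sigmaE = full$e,
    h2 = full$a / (full$a + full$e),
    pH2 = c(NA_real_, NA_real_),
    rhoG = full$rg, rhoE = full$re,
    pRhoG = stats::pchisq(lrtG, 1, lower.tail = FALSE),
    pRhoE = stats::pchisq(lrtE, 1, lower.tail = FALSE),
    beta = full$beta, logLik = full$logLik)
}

#' Heritability report for one latent dimension
#'
#' Univariate h2 for the brain and behaviour scores and their bivariate
#' genetic/environmental correlation, fitted (a) on the split-averaged scores
#' with the basic covariates and (b) as two sensitivity variants: the
#' out-of-sample (holdout-only) scores, and the extended fixed-effect set
#' TIV, age, age^2, gender, age*gender and age^2*gender.
#'
#' @param result a [DimensionResult-class].
#' @param cohort the [Cohort-class] the result was computed on.
#' @param covariates character columns of \code{participantInfo(cohort)} used
#'   as basic fixed effects (default age and gender).
#' @return list with elements \code{averaged}, \code{holdout} and
#'   \code{extendedCovariates}, each a list of \code{brain}, \code{behaviour}
#'   ([VarianceComponents-class], univariate) and \code{bivariate}.
#' @export
heritabilityOfDimension <- function(result, cohort,
                                    covariates = c("age", "gender")) {
  meta <- participantInfo(cohort)
  ped <- meta[, c("id", "family_id", "pair_id", "zygosity")]
  sc <- dimensionScores(result)
  stopifnot(identical(sc$id, meta$id))
  basic <- meta[, covariates, drop = FALSE]
  fitSet <- function(brain, behaviour, covs, rows = NULL) {
    if (is.null(rows)) rows <- seq_len(nrow(meta))
    list(
      brain = fitAeUnivariate(brain[rows], covs[rows, , drop = FALSE],
                              ped[rows, , drop = FALSE]),
      behaviour = fitAeUnivariate(behaviour[rows], covs[rows, , drop = FALSE],
                                  ped[rows, , drop = FALSE]),
      bivariate = fitAeBivariate(brain[rows], behaviour[rows],
                                 covs[rows, , drop = FALSE],
                                 ped[rows, , drop = FALSE]))
  }
  averaged <- fitSet(sc$brainScore, sc$behaviourScore, basic)
  heldRows <- which(is.finite(sc$brainScoreHoldout) &
                      is.finite(sc$behaviourScoreHoldout))
  holdout <- if (length(heldRows) >= 30)
    fitSet(sc$brainScoreHoldout, sc$behaviourScoreHoldout, basic, heldRows)
  else NULL
  tiv <- sizeTotals(cohort)
  tivCol <- if ("GMV" %in% colnames(tiv)) tiv[, "GMV"] else tiv[, 1]
  ext <- data.frame(
    tiv = tivCol, age = meta$age, age2 = meta$age^2, gender = meta$gender,
    ageXgender = meta$age * meta$gender,
    age2Xgender = meta$age^2 * meta$gender)
  extended <- fitSet(sc$brainScore, sc$behaviourScore, ext)
  list(averaged = averaged, holdout = holdout, extendedCovariates = extended)
}

## Direct joint-likelihood evaluation against the full (block-diagonal)
## kinship matrix; retained as an independent cross-check of the per-family
## factorisation used by the fitters.
aeLogLikJoint <- function(y, W, K, h2, s2, beta) {
  n <- length(y)
  V <- s2 * (h2 * K + (1 - h2) * diag(n))
  res <- y - drop(W %*% beta)
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, res, transpose = TRUE)^2))
}
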