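#' Specify a synthetic cohort with planted latent structure
#'
#' Builds and validates the specification consumed by [generateCohort()]. The
#' generated data emulate the layout the analysis assumes: a brain view made
#' of feature blocks (volumetric GMV; surface CT and SA with unit-sphere
#' parcel centroids), a behavioural view, linear age/gender confound effects,
#' per-participant global-size scaling of brain features, family blocks
#' containing MZ/DZ twins and singletons carrying additive-genetic signal on
#' the planted latent variates, and spatially smooth surface loading patterns.
#'
#' @param familyBlocks list of character vectors, one per family, giving the
#'   zygosity of each member: \code{"MZ"} and \code{"DZ"} members must come in
#'   pairs within a family; \code{"S"} marks singletons/non-twin siblings.
#'   See [hcpYaFamilyBlocks()] and [singletonFamilyBlocks()].
#' @param nBehaviour number of behavioural variables.
#' @param brainBlocks named integer vector of parcels per block, e.g.
#'   \code{c(GMV = 239, CT = 200, SA = 200)}. CT and SA are surface blocks
#'   (even parcel counts, mirrored hemispheres); GMV is volumetric.
#' @param planted list of planted dimensions from [plantedDimension()].
#' @param confoundEffects list with \code{age} and \code{gender}: standard
#'   deviations of the per-feature linear confound coefficients (0 disables).
#' @param globalSizeNoise coefficient of variation of the per-participant
#'   global size factors (TIV / mean-CT / total-SA analogues).
#' @param h2Target fraction in [0, 1] of latent-score variance that is
#'   additive-genetic (shared fully by MZ co-twins, half by DZ/siblings).
#' @param noiseSd per-feature independent Gaussian noise standard deviation
#'   (the planted latent variates have unit variance and unit-norm loadings).
#' @param ageRange,genderP age uniform range (years) and P(gender = 1).
#' @param nSites number of acquisition sites (assigned round-robin by family).
#' @param lengthScale great-circle length-scale (radians) of the exponential
#'   kernel from which smooth surface loading patterns are drawn.
#' @param ordinalLevels optional integer: discretise behavioural variables
#'   into this many ordinal levels (robustness switch); NULL keeps them
#'   continuous.
#' @param seed master seed; every sub-stream is derived from it.
#' @param atlasSeed optional separate seed for the parcel atlas geometry, so
#'   two cohorts (e.g. a discovery and a replication sample) can share the
#'   same parcellation while differing in participants; defaults to the
#'   master seed.
#' @return a validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(familyBlocks,
                       nBehaviour,
                       brainBlocks,
                       planted = list(),
                       confoundEffects = list(age = 0.01, gender = 0.1),
                       globalSizeNoise = 0.1,
                       h2Target = 0.5,
                       noiseSd = 0.25,
                       ageRange = c(22, 37),
                       genderP = 0.5,
                       nSites = 1L,
                       lengthScale = 0.5,
                       ordinalLevels = NULL,
                       seed = 1L,
                       atlasSeed = NULL) {
  stopifnot(is.list(familyBlocks), length(familyBlocks) >= 1)
  for (f in familyBlocks) {
    if (!all(f %in% c("MZ", "DZ", "S")))
      stop("family member types must be 'MZ', 'DZ' or 'S'")
    if (sum(f == "MZ") %% 2 != 0 || sum(f == "DZ") %% 2 != 0)
      stop("MZ and DZ members must come in pairs within a family")
  }
  if (nBehaviour < 1) stop("nBehaviour must be positive")
  if (is.null(names(brainBlocks)) || any(!nzchar(names(brainBlocks))))
    stop("brainBlocks must be a named vector")
  if (any(brainBlocks < 1)) stop("brain block parcel counts must be positive")
  surface <- names(brainBlocks) %in% c("CT", "SA")
  if (any(surface & brainBlocks %% 2 != 0))
    stop("surface blocks (CT, SA) need an even parcel count (mirrored hemispheres)")
  if (h2Target < 0 || h2Target > 1) stop("h2Target must lie in [0, 1]")
  for (p in planted) {
    if (!inherits(p, "PlantedDimension"))
      stop("planted must be a list of plantedDimension() objects")
    if (p$rho > 1 - 1e-12 && noiseSd > 0)
      stop("infeasible spec: rho = 1 cannot be realised with a nonzero noise floor")
  }
  if (noiseSd < 0 || globalSizeNoise < 0) stop("noise levels must be nonnegative")
  spec <- list(
    familyBlocks = familyBlocks, nBehaviour = as.integer(nBehaviour),
    brainBlocks = brainBlocks, planted = planted,
    confoundEffects = confoundEffects, globalSizeNoise = globalSizeNoise,
    h2Target = h2Target, noiseSd = noiseSd, ageRange = ageRange,
    genderP = genderP, nSites = as.integer(nSites),
    lengthScale = lengthScale, ordinalLevels = ordinalLevels,
    seed = as.integer(seed),
    atlasSeed = if (is.null(atlasSeed)) NULL else as.integer(atlasSeed))
  class(spec) <- "CohortSpec"
  spec
}

#' Declare a planted latent dimension
#'
#' @param rho target canonical correlation in [0, 1] between the planted brain
#'   and behaviour latent variates.
#' @param brainPattern,behaviourPattern optional explicit loading patterns
#'   (unit-normalised internally); when NULL, [generateCohort()] draws smooth
#'   surface patterns and iid volumetric/behavioural patterns, orthogonalised
#'   across successive dimensions.
#' @return a list of class \code{"PlantedDimension"}.
#' @export
plantedDimension <- function(rho, brainPattern = NULL, behaviourPattern = NULL) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  structure(list(rho = rho, brainPattern = brainPattern,
                 behaviourPattern = behaviourPattern),
            class = "PlantedDimension")
}

#' Family block templates
#'
#' \code{hcpYaFamilyBlocks} draws families of 3 to 6 members each containing
#' exactly one twin pair (MZ with probability \code{pMZ}, reflecting the
#' roughly even MZ/DZ mix of large twin cohorts); remaining members are
#' non-twin siblings. \code{singletonFamilyBlocks} returns n one-member
#' families (an all-unrelated cohort).
#'
#' @param nFamilies,n number of families / singletons.
#' @param pMZ probability a family's twin pair is monozygotic.
#' @param seed integer seed.
#' @return list of character vectors usable as \code{familyBlocks}.
#' @export
hcpYaFamilyBlocks <- function(nFamilies, pMZ = 0.475, seed = 1L) {
  withSeed(seed, {
    lapply(seq_len(nFamilies), function(i) {
      size <- sample(3:6, 1L)
      pair <- if (stats::runif(1) < pMZ) "MZ" else "DZ"
      c(rep(pair, 2L), rep("S", size - 2L))
    })
  })
}

#' @rdname hcpYaFamilyBlocks
#' @export
singletonFamilyBlocks <- function(n) {
  lapply(seq_len(n), function(i) "S")
}

#' Random parcellation of a mirrored spherical surface
#'
#' Draws approximately uniform parcel centroids on the left hemisphere's unit
#' sphere (each hemisphere has its own full sphere, as in surface-registration
#' coordinates) and mirrors them to the right hemisphere, so left (x, y, z)
#' maps exactly to right (-x, y, z). This is the geometric fixture the
#' spherical spin test rotates.
#'
#' @param nPerHemisphere parcels per hemisphere (>= 4).
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{hemisphere}, \code{x},
#'   \code{y}, \code{z}; 2 * nPerHemisphere rows, unit-norm centroids.
#' @export
generateSphereParcellation <- function(nPerHemisphere, seed = 1L) {
  if (nPerHemisphere < 4) stop("need at least 4 parcels per hemisphere")
  left <- withSeed(seed, {
    m <- matrix(stats::rnorm(3 * nPerHemisphere), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  right <- left
  right[, 1] <- -right[, 1]
  data.frame(
    id = c(sprintf("L%03d", seq_len(nPerHemisphere)),
           sprintf("R%03d", seq_len(nPerHemisphere))),
    hemisphere = rep(c("L", "R"), each = nPerHemisphere),
    x = c(left[, 1], right[, 1]),
    y = c(left[, 2], right[, 2]),
    z = c(left[, 3], right[, 3]),
    stringsAsFactors = FALSE)
}

## Smooth Gaussian field on sphere centroids: exponential kernel in
## great-circle distance. Used for planted surface loading patterns so the
## spin test faces realistic spatial autocorrelation.
smoothSphereField <- function(centroids, lengthScale, n = 1L) {
  C <- as.matrix(centroids)
  G <- tcrossprod(C)
  G[G > 1] <- 1; G[G < -1] <- -1
  K <- exp(-acos(G) / lengthScale)
  L <- chol(K + diag(1e-8, nrow(K)))
  t(L) %*% matrix(stats::rnorm(nrow(K) * n), nrow(K), n)
}

## Additive-genetic values with Cov = 2*Phi: exact via per-family Cholesky of
## the kinship block (MZ co-twins 1, DZ/sibs 0.5).
geneticValues <- function(participants) {
  n <- nrow(participants)
  g <- numeric(n)
  for (fam in split(seq_len(n), participants$family_id)) {
    K <- kinshipBlock(participants$zygosity[fam], participants$pair_id[fam])
    L <- chol(K + diag(1e-10, length(fam)))
    g[fam] <- t(L) %*% stats::rnorm(length(fam))
  }
  g
}

## Kinship block for one family given member zygosities and twin pair ids.
kinshipBlock <- function(zygosity, pairId) {
  m <- length(zygosity)
  K <- matrix(0.5, m, m)
  diag(K) <- 1
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (zygosity[i] == "MZ" && zygosity[j] == "MZ" &&
          !is.na(pairId[i]) && identical(pairId[i], pairId[j]))
        K[i, j] <- K[j, i] <- 1
    }
  }
  K
}

buildParticipants <- function(spec) {
  fams <- spec$familyBlocks
  sizes <- lengths(fams)
  n <- sum(sizes)
  familyId <- rep(sprintf("F%04d", seq_along(fams)), sizes)
  zyg <- unlist(fams, use.names = FALSE)
  ## pair ids: within a family, MZ members pair up in order, likewise DZ
  pairId <- rep(NA_character_, n)
  off <- 0L
  for (fi in seq_along(fams)) {
    for (type in c("MZ", "DZ")) {
      idx <- off + which(fams[[fi]] == type)
      if (length(idx))
        pairId[idx] <- sprintf("%s_%s%d", familyId[idx][1], type,
                               ceiling(seq_along(idx) / 2))
    }
    off <- off + sizes[fi]
  }
  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = stats::runif(n, spec$ageRange[1], spec$ageRange[2]),
    gender = stats::rbinom(n, 1L, spec$genderP),
    site = sprintf("site%d", (match(familyId, unique(familyId)) - 1L) %%
                     spec$nSites + 1L),
    family_id = familyId,
    zygosity = zyg,
    pair_id = pairId,
    stringsAsFactors = FALSE)
}

buildParcelAtlas <- function(spec, seed) {
  seed <- spec$atlasSeed %||% seed
  out <- list()
  surfaceCache <- list()
  for (b in names(spec$brainBlocks)) {
    np <- spec$brainBlocks[[b]]
    if (b %in% c("CT", "SA")) {
      key <- as.character(np)
      if (is.null(surfaceCache[[key]]))
        surfaceCache[[key]] <- generateSphereParcellation(
          np %/% 2L, seed = deriveSeed(seed, 11L, np))
      sp <- surfaceCache[[key]]
      out[[b]] <- data.frame(
        id = paste0(b, "_", sp$id), block = b, hemisphere = sp$hemisphere,
        x = sp$x, y = sp$y, z = sp$z, volumetric = FALSE,
        stringsAsFactors = FALSE)
    } else {
      out[[b]] <- data.frame(
        id = sprintf("%s_%03d", b, seq_len(np)), block = b,
        hemisphere = "none", x = NA_real_, y = NA_real_, z = NA_real_,
        volumetric = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## Draw (or take) loading patterns for the planted dimensions and
## orthonormalise successive patterns within each view.
plantedPatterns <- function(spec, parcels) {
  k <- length(spec$planted)
  pBrain <- nrow(parcels); pBeh <- spec$nBehaviour
  B <- matrix(0, pBrain, max(k, 1L))
  V <- matrix(0, pBeh, max(k, 1L))
  if (k == 0) return(list(brain = B[, 0, drop = FALSE],
                          behaviour = V[, 0, drop = FALSE]))
  surf <- !parcels$volumetric
  for (j in seq_len(k)) {
    bp <- spec$planted[[j]]$brainPattern
    if (is.null(bp)) {
      bp <- numeric(pBrain)
      ## smooth field per block and hemisphere: each hemisphere is its own
      ## sphere, so fields are sampled independently within each
      if (any(surf)) {
        grp <- paste(parcels$block, parcels$hemisphere)[surf]
        for (g in split(which(surf), grp))
          bp[g] <- smoothSphereField(parcels[g, c("x", "y", "z")],
                                     spec$lengthScale)
      }
      if (any(!surf)) bp[!surf] <- stats::rnorm(sum(!surf))
    }
    vp <- spec$planted[[j]]$behaviourPattern
    if (is.null(vp)) vp <- stats::rnorm(pBeh)
    B[, j] <- bp; V[, j] <- vp
  }
  ## Gram-Schmidt so successive planted variate directions are uncorrelated
  orth <- function(M) {
    for (j in seq_len(ncol(M))) {
      if (j > 1) {
        prev <- M[, seq_len(j - 1), drop = FALSE]
        M[, j] <- M[, j] - prev %*% crossprod(prev, M[, j])
      }
      nrm <- sqrt(sum(M[, j]^2))
      if (nrm < 1e-12) stop("degenerate planted loading pattern")
      M[, j] <- M[, j] / nrm
    }
    M
  }
  list(brain = orth(B[, seq_len(k), drop = FALSE]),
       behaviour = orth(V[, seq_len(k), drop = FALSE]))
}

#' Generate a synthetic cohort with planted latent structure
#'
#' For each planted dimension, unit-variance brain and behaviour latent
#' variates are drawn with the requested cross-view correlation \code{rho};
#' family members share an additive-genetic component of each variate scaled
#' so the latent-score heritability equals \code{h2Target} (MZ co-twins share
#' it fully, DZ co-twins and siblings half). Observed features are
#' loading-pattern x latent-variate plus linear age/gender confound effects
#' plus independent Gaussian noise; brain features are then multiplied by the
#' participant's per-block global size factor. All ground truth (patterns,
#' latent variates, confound coefficients, size factors) is retained in the
#' cohort's \code{truth} slot.
#'
#' @param spec a [cohortSpec()].
#' @return a [Cohort-class].
#' @examples
#' spec <- cohortSpec(singletonFamilyBlocks(60), nBehaviour = 6,
#'                    brainBlocks = c(GMV = 10, CT = 8),
#'                    planted = list(plantedDimension(0.6)), seed = 7)
#' coh <- generateCohort(spec)
#' coh
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec")) stop("spec must come from cohortSpec()")
  seed <- spec$seed
  participants <- withSeed(deriveSeed(seed, 1L), buildParticipants(spec))
  n <- nrow(participants)
  parcels <- buildParcelAtlas(spec, seed)
  pat <- withSeed(deriveSeed(seed, 2L), plantedPatterns(spec, parcels))
  k <- length(spec$planted)
  h2 <- spec$h2Target
  Zx <- matrix(0, n, k); Zy <- matrix(0, n, k)
  if (k > 0) {
    for (j in seq_len(k)) {
      rho <- spec$planted[[j]]$rho
      zj <- withSeed(deriveSeed(seed, 3L, j), {
        gx <- geneticValues(participants)
        gy <- rho * gx + sqrt(max(0, 1 - rho^2)) * geneticValues(participants)
        ex <- stats::rnorm(n)
        ey <- rho * ex + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
        cbind(sqrt(h2) * gx + sqrt(1 - h2) * ex,
              sqrt(h2) * gy + sqrt(1 - h2) * ey)
      })
      Zx[, j] <- zj[, 1]; Zy[, j] <- zj[, 2]
    }
  }
  pBrain <- nrow(parcels); pBeh <- spec$nBehaviour
  noise <- withSeed(deriveSeed(seed, 4L), list(
    X = matrix(stats::rnorm(n * pBrain, sd = spec$noiseSd), n, pBrain),
    Y = matrix(stats::rnorm(n * pBeh, sd = spec$noiseSd), n, pBeh)))
  X <- noise$X; Y <- noise$Y
  if (k > 0) {
    X <- X + Zx %*% t(pat$brain)
    Y <- Y + Zy %*% t(pat$behaviour)
  }
  ## linear confound effects
  conf <- withSeed(deriveSeed(seed, 5L), list(
    ageX = stats::rnorm(pBrain, sd = spec$confoundEffects$age),
    ageY = stats::rnorm(pBeh, sd = spec$confoundEffects$age),
    genderX = stats::rnorm(pBrain, sd = spec$confoundEffects$gender),
    genderY = stats::rnorm(pBeh, sd = spec$confoundEffects$gender)))
  ageC <- participants$age - mean(participants$age)
  X <- X + outer(ageC, conf$ageX) + outer(participants$gender, conf$genderX)
  Y <- Y + outer(ageC, conf$ageY) + outer(participants$gender, conf$genderY)
  ## per-participant global size scaling of brain features
  blocks <- names(spec$brainBlocks)
  sizeTotals <- withSeed(deriveSeed(seed, 6L), {
    m <- exp(matrix(stats::rnorm(n * length(blocks), sd = spec$globalSizeNoise),
                    n, length(blocks)))
    colnames(m) <- blocks
    m
  })
  for (b in blocks) {
    idx <- which(parcels$block == b)
    X[, idx] <- X[, idx] * sizeTotals[, b]
  }
  if (!is.null(spec$ordinalLevels)) {
    L <- as.integer(spec$ordinalLevels)
    Y <- apply(Y, 2L, function(col)
      as.numeric(cut(col, breaks = stats::quantile(col, probs = seq(0, 1, length.out = L + 1)),
                     labels = FALSE, include.lowest = TRUE)))
  }
  rownames(X) <- rownames(Y) <- rownames(sizeTotals) <- participants$id
  colnames(X) <- parcels$id
  colnames(Y) <- sprintf("beh%02d", seq_len(pBeh))
  methods::new("Cohort",
    brain = X, behaviour = Y, participants = participants,
    sizeTotals = sizeTotals, parcels = parcels,
    truth = list(
      spec = spec,
      planted = spec$planted,
      brainPatterns = pat$brain, behaviourPatterns = pat$behaviour,
      latentBrain = Zx, latentBehaviour = Zy,
      confoundCoefs = conf))
}

#' Simulate twin-pair phenotypes under the AE model
#'
#' Phenotypes are multivariate normal with covariance
#' 2*Phi*sigmaA^2 + I*sigmaE^2 where sigmaA^2/(sigmaA^2 + sigmaE^2) =
#' \code{h2} and total variance 1: MZ co-twins correlate \code{h2}, DZ
#' co-twins \code{h2}/2, unrelated participants 0.
#'
#' @param nMZ,nDZ,nSingletons numbers of MZ pairs, DZ pairs and singletons.
#' @param h2 true narrow-sense heritability in [0, 1].
#' @param seed integer seed.
#' @return list with \code{phenotype} (numeric vector) and \code{pedigree}
#'   (data.frame: id, family_id, pair_id, zygosity).
#' @export
generateTwinSample <- function(nMZ, nDZ, nSingletons, h2, seed = 1L) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  fams <- c(rep(list(c("MZ", "MZ")), nMZ), rep(list(c("DZ", "DZ")), nDZ),
            rep(list("S"), nSingletons))
  spec <- list(familyBlocks = fams)
  participants <- local({
    sizes <- lengths(fams)
    familyId <- rep(sprintf("F%04d", seq_along(fams)), sizes)
    zyg <- unlist(fams, use.names = FALSE)
    pairId <- ifelse(zyg %in% c("MZ", "DZ"), paste0(familyId, "_T1"),
                     NA_character_)
    data.frame(id = sprintf("P%05d", seq_along(zyg)), family_id = familyId,
               pair_id = pairId, zygosity = zyg, stringsAsFactors = FALSE)
  })
  phen <- withSeed(seed, {
    g <- geneticValues(participants)
    sqrt(h2) * g + sqrt(1 - h2) * stats::rnorm(nrow(participants))
  })
  list(phenotype = stats::setNames(phen, participants$id),
       pedigree = participants)
}
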