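#' Average loadings over outer splits
#'
#' Computes, per variable, the mean and (sample) standard deviation of the
#' loading across splits, plus an \code{unstable} flag for variables whose
#' mean absolute loading is below 0.2 and whose one-sd band crosses zero --
#' the interpretation rule used to discount variables with no consistent
#' association.
#'
#' @param loadingList list of numeric vectors (one per split, sign-aligned
#'   models assumed) or a matrix with one column per split.
#' @param variable optional variable names (recycled from the first element's
#'   names when absent).
#' @return data.frame with columns \code{variable}, \code{mean}, \code{sd},
#'   \code{unstable}.
#' @export
averageLoadings <- function(loadingList, variable = NULL) {
  if (is.matrix(loadingList))
    loadingList <- lapply(seq_len(ncol(loadingList)),
                          function(j) loadingList[, j])
  lens <- lengths(loadingList)
  if (length(unique(lens)) != 1)
    stop("mismatched variable sets across splits (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  M <- do.call(cbind, loadingList)
  if (is.null(variable))
    variable <- names(loadingList[[1]]) %||% sprintf("v%03d", seq_len(nrow(M)))
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  data.frame(variable = variable, mean = mu, sd = sdv,
             unstable = abs(mu) < 0.2 & abs(mu) < sdv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hemisphere-symmetric random spherical rotation of a parcellation
#'
#' Draws a uniform (Haar) random 3D rotation, applies it to the
#' left-hemisphere parcel centroids and its mirror image to the
#' right-hemisphere centroids (preserving hemispheric symmetry), then
#' reassigns each rotated centroid the parcel whose original centroid is
#' nearest in great-circle distance (ties broken toward the lowest parcel
#' index; duplicates allowed).
#'
#' @param atlas data.frame of surface parcels with columns \code{hemisphere}
#'   (\code{"L"}/\code{"R"}) and unit-sphere centroids \code{x}, \code{y},
#'   \code{z}.
#' @param seed integer seed.
#' @return integer index map \code{idx} of length \code{nrow(atlas)}: the
#'   rotated (null) map is \code{map[idx]}.
#' @export
spinRotation <- function(atlas, seed = 1L) {
  if (anyNA(atlas[, c("x", "y", "z")]))
    stop("surface parcels must all have centroids")
  R <- withSeed(seed, randomRotation())
  mirror <- diag(c(-1, 1, 1))
  Rright <- mirror %*% R %*% mirror
  idx <- integer(nrow(atlas))
  for (h in c("L", "R")) {
    rows <- which(atlas$hemisphere == h)
    if (!length(rows)) next
    C <- as.matrix(atlas[rows, c("x", "y", "z")])
    rot <- C %*% t(if (h == "L") R else Rright)
    ## nearest original centroid = max inner product on the unit sphere
    sim <- rot %*% t(C)
    idx[rows] <- rows[max.col(sim, ties.method = "first")]
  }
  idx
}

## Haar-uniform rotation via QR of a Gaussian matrix, determinant forced to +1.
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin test for the similarity of two parcellated surface maps
#'
#' The observed statistic is the Pearson correlation of the two maps. Null
#' maps are generated by rotating \code{mapA} on the sphere with
#' hemisphere-symmetric random rotations ([spinRotation()]); \code{mapB}
#' stays fixed. Because the null maps are permutations of \code{mapA}, they
#' preserve its value multiset and spatial autocorrelation. By default the
#' p-value compares magnitudes, p = #(|r_null| > |r_obs|)/n (two-sided on the
#' magnitude and invariant under global sign flips of either map), floored at
#' 1/n_rotations; \code{alternative = "greater"} applies the literal
#' one-sided "null higher than observed" rule.
#'
#' @param mapA,mapB numeric vectors over the same surface parcels (mapA is
#'   rotated; use the loading map here and a fixed reference map as mapB).
#' @param atlas surface parcel table as in [spinRotation()], aligned with the
#'   maps.
#' @param nRotations number of random rotations (default 1000).
#' @param seed integer seed.
#' @param alternative \code{"two.sided"} (magnitude rule, default) or
#'   \code{"greater"}.
#' @return list with \code{r}, \code{p}, \code{nRotations} and the null
#'   correlations \code{nulls}.
#' @export
spinTest <- function(mapA, mapB, atlas, nRotations = 1000L, seed = 1L,
                     alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(mapA) != nrow(atlas) || length(mapB) != nrow(atlas))
    stop("maps must have one value per atlas parcel")
  if (anyNA(mapA) || anyNA(mapB)) stop("maps must be finite")
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0)
    stop("constant map: correlation undefined")
  robs <- stats::cor(mapA, mapB)
  nulls <- vapply(seq_len(nRotations), function(i) {
    idx <- spinRotation(atlas, seed = deriveSeed(seed, 17L, i))
    stats::cor(mapA[idx], mapB)
  }, numeric(1))
  exceed <- if (alternative == "two.sided") sum(abs(nulls) > abs(robs))
            else sum(nulls > robs)
  p <- max(exceed / nRotations, 1 / nRotations)
  list(r = robs, p = p, nRotations = as.integer(nRotations), nulls = nulls)
}

#' Compare the loadings of two latent dimensions across cohorts
#'
#' Behavioural loadings are compared with Pearson's correlation (analytic
#' p-value); CT and SA surface loadings are compared with the spin test
#' ([spinTest()]); volumetric blocks (GMV, subcortex, cerebellum) are
#' excluded from spatial comparison. The Bonferroni factor defaults to the
#' number of comparisons made here, but for a cross-cohort family of
#' dimensions it should be n_dims_a x n_dims_b x 3 loading families (e.g. 3 x
#' 2 x 3 = 18).
#'
#' @param resultA,resultB [DimensionResult-class] objects with shared
#'   behavioural variables and shared surface parcels.
#' @param atlas the parcel table ([parcelTable()]) the results were computed
#'   on (surface rows are matched by parcel id).
#' @param nRotations rotations for the spin tests.
#' @param seed integer seed.
#' @param bonferroni correction factor applied to all p-values (default: the
#'   number of rows returned).
#' @return data.frame with one row per comparison: \code{family}, \code{r},
#'   \code{p}, \code{pCorrected}, \code{method}.
#' @export
compareDimensions <- function(resultA, resultB, atlas, nRotations = 1000L,
                              seed = 1L, bonferroni = NULL) {
  behA <- resultA@behaviourLoadings; behB <- resultB@behaviourLoadings
  if (!identical(behA$variable, behB$variable))
    stop("behavioural variable sets differ: ",
         paste(union(setdiff(behA$variable, behB$variable),
                     setdiff(behB$variable, behA$variable)), collapse = ", "))
  ct <- stats::cor.test(behA$mean, behB$mean)
  rows <- list(data.frame(family = "behaviour", r = unname(ct$estimate),
                          p = ct$p.value, method = "pearson",
                          stringsAsFactors = FALSE))
  for (b in c("CT", "SA")) {
    inBlock <- resultA@brainLoadings$block == b
    if (!any(inBlock)) next
    ids <- resultA@brainLoadings$variable[inBlock]
    sub <- atlas[match(ids, atlas$id), , drop = FALSE]
    if (any(sub$volumetric)) next
    st <- spinTest(resultA@brainLoadings$mean[inBlock],
                   resultB@brainLoadings$mean[match(ids, resultB@brainLoadings$variable)],
                   sub, nRotations = nRotations,
                   seed = deriveSeed(seed, 23L, match(b, c("CT", "SA"))))
    rows <- c(rows, list(data.frame(family = b, r = st$r, p = st$p,
                                    method = "spin", stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  k <- if (is.null(bonferroni)) nrow(out) else bonferroni
  out$pCorrected <- pmin(1, k * out$p)
  out[, c("family", "r", "p", "pCorrected", "method")]
}
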