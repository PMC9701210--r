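#' @import methods
NULL

#' Cohort: two aligned data views with participant and parcel metadata
#'
#' A \code{Cohort} holds a brain-structure view (participants x parcels,
#' possibly concatenating several feature blocks such as grey matter volume,
#' cortical thickness and surface area), a behavioural view (participants x
#' variables), per-participant metadata (age, gender, site, family id,
#' zygosity), per-participant global size totals used for brain-size
#' normalisation, and a parcel table with block membership, hemisphere and
#' unit-sphere centroids for surface parcels. When generated synthetically,
#' the \code{truth} slot retains the generating specification and the planted
#' latent variates.
#'
#' @slot brain numeric matrix, participants x brain features; column names are
#'   parcel ids matching \code{parcels$id}.
#' @slot behaviour numeric matrix, participants x behavioural variables.
#' @slot participants data.frame with columns \code{id}, \code{age},
#'   \code{gender} (0/1), \code{site}, \code{family_id}, \code{zygosity}
#'   (\code{"MZ"}, \code{"DZ"} or \code{"S"} for singleton/non-twin).
#' @slot sizeTotals numeric matrix, participants x blocks, of positive global
#'   size factors (TIV-analogue for GMV, mean-CT-analogue for CT, total-SA
#'   analogue for SA).
#' @slot parcels data.frame with columns \code{id}, \code{block},
#'   \code{hemisphere} (\code{"L"}, \code{"R"} or \code{"none"}), \code{x},
#'   \code{y}, \code{z} (unit-sphere centroid; NA for volumetric parcels) and
#'   \code{volumetric} (logical).
#' @slot truth list; ground-truth bookkeeping for synthetic cohorts (empty for
#'   cohorts read from disk without a truth file).
#'
#' @seealso [generateCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("Cohort",
  slots = c(
    brain = "matrix",
    behaviour = "matrix",
    participants = "data.frame",
    sizeTotals = "matrix",
    parcels = "data.frame",
    truth = "list"
  )
)

setValidity("Cohort", function(object) {
  msg <- character()
  n <- nrow(object@participants)
  req <- c("id", "age", "gender", "site", "family_id", "zygosity")
  miss <- setdiff(req, colnames(object@participants))
  if (length(miss))
    msg <- c(msg, paste("participants missing columns:",
                        paste(miss, collapse = ", ")))
  if (nrow(object@brain) != n || nrow(object@behaviour) != n ||
      nrow(object@sizeTotals) != n)
    msg <- c(msg, "brain, behaviour and sizeTotals must have one row per participant")
  if (length(msg) == 0L) {
    if (anyDuplicated(object@participants$id))
      msg <- c(msg, "participant ids must be unique")
    if (anyNA(object@brain) || anyNA(object@behaviour))
      msg <- c(msg, "data views must not contain missing values")
    if (anyNA(object@participants$family_id))
      msg <- c(msg, "every participant must have a family_id")
    if (!is.null(rownames(object@brain)) &&
        !identical(rownames(object@brain), as.character(object@participants$id)))
      msg <- c(msg, "brain rownames must match participant ids")
    preq <- c("id", "block", "hemisphere", "x", "y", "z", "volumetric")
    pmiss <- setdiff(preq, colnames(object@parcels))
    if (length(pmiss))
      msg <- c(msg, paste("parcels missing columns:",
                          paste(pmiss, collapse = ", ")))
    else if (!identical(as.character(object@parcels$id), colnames(object@brain)))
      msg <- c(msg, "parcels$id must match brain column names in order")
  }
  if (length(msg)) msg else TRUE
})

#' Regularized CCA model: one weight pair with its regularisation
#'
#' Weight vectors \code{u} (brain) and \code{v} (behaviour) maximising the
#' cross-view covariance objective under the regularised unit-variance
#' constraints u'[(1-c_x) Cxx + c_x I]u = 1 and v'[(1-c_y) Cyy + c_y I]v = 1,
#' where Cxx, Cyy are (n-1)-denominator covariance estimates on the fitting
#' set. \code{trainCor} is the plain Pearson correlation of the training
#' scores Xu and Yv.
#'
#' @slot u numeric vector of brain weights.
#' @slot v numeric vector of behaviour weights.
#' @slot cx,cy regularisation parameters in [0, 1].
#' @slot trainCor training canonical correlation.
#' @slot xMeans,yMeans column means of the fitting set (applied before
#'   projection so holdout scores use training centering only).
#' @slot n number of fitting participants.
#' @export
setClass("RccaModel",
  slots = c(
    u = "numeric", v = "numeric",
    cx = "numeric", cy = "numeric",
    trainCor = "numeric",
    xMeans = "numeric", yMeans = "numeric",
    n = "integer"
  )
)

setValidity("RccaModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
    msg <- c(msg, "weights must be finite")
  if (object@cx < 0 || object@cx > 1 || object@cy < 0 || object@cy > 1)
    msg <- c(msg, "regularisation parameters must lie in [0, 1]")
  if (length(object@trainCor) == 1L &&
      (object@trainCor < -1 - 1e-8 || object@trainCor > 1 + 1e-8))
    msg <- c(msg, "training correlation must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Nested family-aware split scheme
#'
#' Outer splits partition participants into optimisation and holdout sets;
#' within each outer split, inner splits partition the optimisation set into
#' training and testing sets. No family is ever divided across the two sides
#' of any split.
#'
#' @slot outer list of length \code{nOuter}; each element a list with integer
#'   index vectors \code{optimisation} and \code{holdout}.
#' @slot inner list of length \code{nOuter}; each element a list of
#'   \code{nInner} lists with index vectors \code{train} and \code{test}
#'   (indices into the full cohort).
#' @slot nOuter,nInner split counts.
#' @slot fractions named numeric: \code{optimisation} and \code{train}
#'   fractions (holdout/test are the complements).
#' @slot seed integer seed the scheme was drawn with.
#' @export
setClass("SplitScheme",
  slots = c(
    outer = "list", inner = "list",
    nOuter = "integer", nInner = "integer",
    fractions = "numeric", seed = "integer"
  )
)

setValidity("SplitScheme", function(object) {
  msg <- character()
  if (length(object@outer) != object@nOuter)
    msg <- c(msg, "outer list length must equal nOuter")
  if (length(object@inner) != object@nOuter)
    msg <- c(msg, "inner list length must equal nOuter")
  for (o in object@outer) {
    if (length(intersect(o$optimisation, o$holdout)))
      msg <- c(msg, "optimisation and holdout sets overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Result for one latent dimension across outer splits
#'
#' @slot dimension 1-based index of the latent dimension.
#' @slot splits data.frame with one row per outer split: selected \code{cx},
#'   \code{cy}, \code{holdoutCor}, permutation \code{p} and Bonferroni
#'   \code{pCorrected}.
#' @slot models list of fitted [RccaModel-class] objects, one per outer split.
#' @slot brainLoadings,behaviourLoadings data.frames with per-variable split
#'   mean, sd and an \code{unstable} flag (|mean| < 0.2 and the one-sd band
#'   crosses zero).
#' @slot scores data.frame keyed by participant id with split-averaged scores
#'   (all splits) and holdout-only scores (NA when a participant was never
#'   held out).
#' @slot significant omnibus verdict: TRUE when any split's corrected p is
#'   strictly below alpha.
#' @slot alpha significance level used for the omnibus decision.
#' @export
setClass("DimensionResult",
  slots = c(
    dimension = "integer",
    splits = "data.frame",
    models = "list",
    brainLoadings = "data.frame",
    behaviourLoadings = "data.frame",
    scores = "data.frame",
    significant = "logical",
    alpha = "numeric"
  )
)

#' AE variance decomposition of one or two phenotypes
#'
#' Maximum-likelihood fit of y ~ Normal(W beta, 2*Phi*sigmaA^2 + I*sigmaE^2)
#' (univariate) or the stacked bivariate model with cross-trait blocks
#' 2*Phi*rhoG*sigmaAx*sigmaAy + I*rhoE*sigmaEx*sigmaEy.
#'
#' @slot type "univariate" or "bivariate".
#' @slot sigmaA,sigmaE additive-genetic and environmental variances (length 1
#'   or 2).
#' @slot h2 narrow-sense heritability per trait.
#' @slot pH2 boundary LRT p-value(s) against sigmaA^2 = 0 (50:50 mixture of a
#'   point mass at 0 and chi-square(1)).
#' @slot rhoG,rhoE genetic/environmental correlations (bivariate only, else NA).
#' @slot pRhoG,pRhoE LRT p-values for rhoG = 0 and rhoE = 0.
#' @slot beta fixed-effect coefficients (matrix, one column per trait).
#' @slot logLik maximised log-likelihood.
#' @export
setClass("VarianceComponents",
  slots = c(
    type = "character",
    sigmaA = "numeric", sigmaE = "numeric",
    h2 = "numeric", pH2 = "numeric",
    rhoG = "numeric", rhoE = "numeric",
    pRhoG = "numeric", pRhoE = "numeric",
    beta = "matrix",
    logLik = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (any(object@sigmaA < -1e-8) || any(object@sigmaE < -1e-8))
    msg <- c(msg, "variance components must be nonnegative")
  if (any(object@h2 < -1e-8 | object@h2 > 1 + 1e-8))
    msg <- c(msg, "h2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
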