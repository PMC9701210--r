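#' @include AllClasses.R
NULL

#' Accessors for Cohort objects
#'
#' @param object a [Cohort-class].
#' @return \code{brainView}/\code{behaviourView}: numeric matrices;
#'   \code{participantInfo}, \code{parcelTable}: data.frames;
#'   \code{sizeTotals}: matrix; \code{cohortTruth}: list.
#' @name cohort-accessors
#' @aliases brainView behaviourView participantInfo parcelTable sizeTotals
#'   cohortTruth
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("brainView", function(object) standardGeneric("brainView"))
#' @rdname cohort-accessors
#' @export
setGeneric("behaviourView", function(object) standardGeneric("behaviourView"))
#' @rdname cohort-accessors
#' @export
setGeneric("participantInfo", function(object) standardGeneric("participantInfo"))
#' @rdname cohort-accessors
#' @export
setGeneric("parcelTable", function(object) standardGeneric("parcelTable"))
#' @rdname cohort-accessors
#' @export
setGeneric("sizeTotals", function(object) standardGeneric("sizeTotals"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
setMethod("brainView", "Cohort", function(object) object@brain)
#' @rdname cohort-accessors
setMethod("behaviourView", "Cohort", function(object) object@behaviour)
#' @rdname cohort-accessors
setMethod("participantInfo", "Cohort", function(object) object@participants)
#' @rdname cohort-accessors
setMethod("parcelTable", "Cohort", function(object) object@parcels)
#' @rdname cohort-accessors
setMethod("sizeTotals", "Cohort", function(object) object@sizeTotals)
#' @rdname cohort-accessors
setMethod("cohortTruth", "Cohort", function(object) object@truth)

setMethod("show", "Cohort", function(object) {
  blocks <- table(object@parcels$block)
  cat("Cohort:", nrow(object@participants), "participants,",
      ncol(object@brain), "brain features (",
      paste(sprintf("%s:%d", names(blocks), as.integer(blocks)),
            collapse = ", "),
      "),", ncol(object@behaviour), "behavioural variables\n")
  cat("  families:", length(unique(object@participants$family_id)),
      "| zygosity:",
      paste(sprintf("%s=%d", names(table(object@participants$zygosity)),
                    as.integer(table(object@participants$zygosity))),
            collapse = " "), "\n")
  if (length(object@truth))
    cat("  synthetic cohort with",
        length(object@truth$planted %||% list()), "planted dimension(s)\n")
})

#' Accessors for RccaModel objects
#'
#' @param object an [RccaModel-class].
#' @name rcca-accessors
#' @aliases brainWeights behaviourWeights regParams canonicalCorrelation
NULL

#' @rdname rcca-accessors
#' @export
setGeneric("brainWeights", function(object) standardGeneric("brainWeights"))
#' @rdname rcca-accessors
#' @export
setGeneric("behaviourWeights", function(object) standardGeneric("behaviourWeights"))
#' @rdname rcca-accessors
#' @export
setGeneric("regParams", function(object) standardGeneric("regParams"))
#' @rdname rcca-accessors
#' @export
setGeneric("canonicalCorrelation",
           function(object) standardGeneric("canonicalCorrelation"))

#' @rdname rcca-accessors
setMethod("brainWeights", "RccaModel", function(object) object@u)
#' @rdname rcca-accessors
setMethod("behaviourWeights", "RccaModel", function(object) object@v)
#' @rdname rcca-accessors
setMethod("regParams", "RccaModel",
          function(object) c(cx = object@cx, cy = object@cy))
#' @rdname rcca-accessors
setMethod("canonicalCorrelation", "RccaModel", function(object) object@trainCor)

setMethod("show", "RccaModel", function(object) {
  cat(sprintf(
    "RccaModel: %d brain x %d behaviour weights, c_x=%.3g, c_y=%.3g, r=%.4f (n=%d)\n",
    length(object@u), length(object@v), object@cx, object@cy,
    object@trainCor, object@n))
})

setMethod("show", "SplitScheme", function(object) {
  cat(sprintf(
    "SplitScheme: %d outer x %d inner family-aware splits (opt %.0f%%/train %.0f%%), seed %d\n",
    object@nOuter, object@nInner, 100 * object@fractions[["optimisation"]],
    100 * object@fractions[["train"]], object@seed))
})

#' Accessors for DimensionResult objects
#'
#' @param object a [DimensionResult-class].
#' @name dimension-accessors
#' @aliases splitSummary dimensionLoadings dimensionScores isSignificant
NULL

#' @rdname dimension-accessors
#' @export
setGeneric("splitSummary", function(object) standardGeneric("splitSummary"))
#' @rdname dimension-accessors
#' @export
setGeneric("dimensionLoadings", function(object) standardGeneric("dimensionLoadings"))
#' @rdname dimension-accessors
#' @export
setGeneric("dimensionScores", function(object) standardGeneric("dimensionScores"))
#' @rdname dimension-accessors
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname dimension-accessors
setMethod("splitSummary", "DimensionResult", function(object) object@splits)
#' @rdname dimension-accessors
setMethod("dimensionLoadings", "DimensionResult", function(object)
  list(brain = object@brainLoadings, behaviour = object@behaviourLoadings))
#' @rdname dimension-accessors
setMethod("dimensionScores", "DimensionResult", function(object) object@scores)
#' @rdname dimension-accessors
setMethod("isSignificant", "DimensionResult", function(object) object@significant)

setMethod("show", "DimensionResult", function(object) {
  rng <- range(object@splits$holdoutCor)
  cat(sprintf("DimensionResult %d: holdout r in [%.3f, %.3f]",
              object@dimension, rng[1], rng[2]))
  if (all(is.finite(object@splits$pCorrected)))
    cat(sprintf(", corrected p in [%.4g, %.4g]",
                min(object@splits$pCorrected), max(object@splits$pCorrected)))
  cat(sprintf(" -> %s (alpha=%.3g)\n",
              if (isTRUE(object@significant)) "significant" else "not significant",
              object@alpha))
})

setMethod("show", "VarianceComponents", function(object) {
  if (object@type == "univariate") {
    cat(sprintf("AE fit: h2 = %.3f (sigmaA2=%.3g, sigmaE2=%.3g), LRT p = %.4g\n",
                object@h2, object@sigmaA, object@sigmaE, object@pH2))
  } else {
    cat(sprintf("Bivariate AE fit: h2 = (%.3f, %.3f); rhoG = %.3f (p=%.4g), rhoE = %.3f (p=%.4g)\n",
                object@h2[1], object@h2[2], object@rhoG, object@pRhoG,
                object@rhoE, object@pRhoE))
  }
})
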