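#' Configuration for the multiple-holdout framework
#'
#' Defaults mirror the study design: five outer and five inner family-aware
#' splits with 80/20 fractions, a regularisation grid spanning CCA (c = 0) to
#' the PLS limit (c = 1) with log-dense coverage near 1, 1000 permutations per
#' outer split, Bonferroni correction over the outer splits and an omnibus
#' alpha of 0.05.
#'
#' @param cGrid numeric values used for both c_x and c_y (full Cartesian
#'   grid).
#' @param nOuter,nInner outer/inner split counts.
#' @param fractions named numeric: optimisation and train fractions.
#' @param nPerm permutations per outer split; 0 skips inference (p-values NA;
#'   extraction then runs to \code{maxDimensions}).
#' @param alpha omnibus significance level.
#' @param maxDimensions most latent dimensions to extract; extraction also
#'   stops after the first non-significant dimension.
#' @param confounds columns of \code{participantInfo(cohort)} regressed out of
#'   both views (leakage-free); character/factor columns become k-1 dummies.
#' @param signFlip optional named numeric multipliers applied to behaviour
#'   columns before analysis (e.g. flipping a reaction time so that larger
#'   means better).
#' @param estimator permutation p-value estimator, see [permutationPvalue()].
#' @param seed master seed; all sub-streams derive from it.
#' @return a validated list of class \code{"FrameworkConfig"}.
#' @export
frameworkConfig <- function(cGrid = c(0, 0.3, 0.6, 0.9, 0.99, 1),
                            nOuter = 5L, nInner = 5L,
                            fractions = c(optimisation = 0.8, train = 0.8),
                            nPerm = 1000L, alpha = 0.05,
                            maxDimensions = 3L,
                            confounds = c("age", "gender"),
                            signFlip = NULL,
                            estimator = "strict",
                            seed = 1L) {
  if (any(cGrid < 0 | cGrid > 1)) stop("grid values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(
    grid = expand.grid(cx = cGrid, cy = cGrid, KEEP.OUT.ATTRS = FALSE),
    nOuter = as.integer(nOuter), nInner = as.integer(nInner),
    fractions = fractions, nPerm = as.integer(nPerm), alpha = alpha,
    maxDimensions = as.integer(maxDimensions), confounds = confounds,
    signFlip = signFlip, estimator = estimator, seed = as.integer(seed)),
    class = "FrameworkConfig")
}

#' Run the full multiple-holdout RCCA framework on a cohort
#'
#' For each latent dimension and each outer split: brain features are
#' size-normalised (per participant), confounds are regressed out with
#' coefficients estimated on the optimisation set only, hyperparameters are
#' selected on the inner splits by joint correlation + stability ranking, the
#' selected model is refitted on the full optimisation set, the holdout set is
#' projected onto its weights, and a family-restricted permutation test
#' (hyperparameters frozen) yields the split's p-value, Bonferroni-corrected
#' over the outer splits. The omnibus decision rejects when any split's
#' corrected p is below alpha. Before seeking the next dimension, each split's
#' data are deflated with that split's own optimisation-set model (no
#' leakage); extraction stops after the first non-significant dimension (which
#' is still reported) or at \code{maxDimensions}.
#'
#' Loadings are computed per split on the optimisation set by correlating the
#' preprocessed (residualised, un-deflated) variables with that split's
#' scores, then averaged across splits with their standard deviation.
#' Participant scores are recorded two ways: projecting the full cohort onto
#' each split's model and averaging (everyone covered; feeds the genetics
#' stage), and averaging only over splits in which the participant was held
#' out (out-of-sample; NA for participants never held out).
#'
#' @param cohort a [Cohort-class].
#' @param config a [frameworkConfig()].
#' @return list of [DimensionResult-class], one per extracted dimension.
#' @export
runFramework <- function(cohort, config) {
  if (!inherits(config, "FrameworkConfig"))
    stop("config must come from frameworkConfig()")
  meta <- participantInfo(cohort)
  n <- nrow(meta)
  Xn <- normaliseBrain(brainView(cohort), sizeTotals(cohort),
                       parcelTable(cohort)$block)
  Y <- behaviourView(cohort)
  if (!is.null(config$signFlip)) {
    bad <- setdiff(names(config$signFlip), colnames(Y))
    if (length(bad)) stop("signFlip names not in behaviour view: ",
                          paste(bad, collapse = ", "))
    Y[, names(config$signFlip)] <-
      sweep(Y[, names(config$signFlip), drop = FALSE], 2L,
            config$signFlip, "*")
  }
  confounds <- meta[, config$confounds, drop = FALSE]
  scheme <- makeSplitScheme(meta, config$nOuter, config$nInner,
                            config$fractions, deriveSeed(config$seed, 7L))
  ## per-split immutable state: preprocess fitted on the optimisation set
  splitState <- lapply(seq_len(config$nOuter), function(o) {
    opt <- scheme@outer[[o]]$optimisation
    hold <- scheme@outer[[o]]$holdout
    psX <- fitPreprocess(Xn[opt, , drop = FALSE], confounds[opt, , drop = FALSE])
    psY <- fitPreprocess(Y[opt, , drop = FALSE], confounds[opt, , drop = FALSE])
    list(
      opt = opt, hold = hold,
      Xopt = applyPreprocess(psX, Xn[opt, , drop = FALSE], confounds[opt, , drop = FALSE]),
      Yopt = applyPreprocess(psY, Y[opt, , drop = FALSE], confounds[opt, , drop = FALSE]),
      Xhold = applyPreprocess(psX, Xn[hold, , drop = FALSE], confounds[hold, , drop = FALSE]),
      Yhold = applyPreprocess(psY, Y[hold, , drop = FALSE], confounds[hold, , drop = FALSE]),
      Xfull = applyPreprocess(psX, Xn, confounds),
      Yfull = applyPreprocess(psY, Y, confounds),
      models = list())
  })
  results <- list()
  for (d in seq_len(config$maxDimensions)) {
    perSplit <- vector("list", config$nOuter)
    for (o in seq_len(config$nOuter)) {
      st <- splitState[[o]]
      gs <- tryCatch(
        gridSearch(Xn, Y, confounds, scheme@inner[[o]], config$grid,
                   priorModels = st$models),
        error = function(e) stop("dimension ", d, ", split ", o,
                                 ": grid search failed: ",
                                 conditionMessage(e)))
      mod <- fitRcca(st$Xopt, st$Yopt, gs$cx, gs$cy)
      holdProj <- projectScores(mod, st$Xhold, st$Yhold)
      perm <- if (config$nPerm > 0) {
        runPermutationTest(
          st$Xopt, st$Yopt, st$Xhold, st$Yhold,
          meta[st$opt, , drop = FALSE], meta[st$hold, , drop = FALSE],
          gs$cx, gs$cy, observed = holdProj$cor,
          nPerm = config$nPerm, nOuter = config$nOuter,
          seed = deriveSeed(config$seed, 31L, d, o),
          estimator = config$estimator)
      } else list(p = NA_real_, pCorrected = NA_real_)
      optProj <- projectScores(mod, st$Xopt, st$Yopt)
      load <- computeLoadings(st$Xopt, st$Yopt, optProj)
      fullProj <- projectScores(mod, st$Xfull, st$Yfull)
      perSplit[[o]] <- list(
        cx = gs$cx, cy = gs$cy, holdoutCor = holdProj$cor,
        p = perm$p, pCorrected = perm$pCorrected, model = mod,
        brainLoad = load$brain, behaviourLoad = load$behaviour,
        fullXu = fullProj$xu, fullYv = fullProj$yv)
      ## deflate this split's data with its own optimisation-set model
      st$models <- c(st$models, list(mod))
      dOpt <- deflateViews(st$Xopt, st$Yopt, mod)
      st$Xopt <- dOpt$X; st$Yopt <- dOpt$Y
      dHold <- deflateViews(st$Xhold, st$Yhold, mod)
      st$Xhold <- dHold$X; st$Yhold <- dHold$Y
      dFull <- deflateViews(st$Xfull, st$Yfull, mod)
      st$Xfull <- dFull$X; st$Yfull <- dFull$Y
      splitState[[o]] <- st
    }
    results[[d]] <- assembleDimensionResult(d, perSplit, splitState, meta,
                                            parcelTable(cohort), colnames(Y),
                                            config)
    if (config$nPerm > 0 && !isSignificant(results[[d]])) break
  }
  results
}

assembleDimensionResult <- function(d, perSplit, splitState, meta, parcels,
                                    behNames, config) {
  nOuter <- length(perSplit)
  splits <- data.frame(
    split = seq_len(nOuter),
    cx = vapply(perSplit, `[[`, numeric(1), "cx"),
    cy = vapply(perSplit, `[[`, numeric(1), "cy"),
    holdoutCor = vapply(perSplit, `[[`, numeric(1), "holdoutCor"),
    p = vapply(perSplit, `[[`, numeric(1), "p"),
    pCorrected = vapply(perSplit, `[[`, numeric(1), "pCorrected"))
  brainL <- averageLoadings(lapply(perSplit, `[[`, "brainLoad"),
                            variable = parcels$id)
  brainL$block <- parcels$block
  behL <- averageLoadings(lapply(perSplit, `[[`, "behaviourLoad"),
                          variable = behNames)
  n <- nrow(meta)
  fullXu <- sapply(perSplit, `[[`, "fullXu")
  fullYv <- sapply(perSplit, `[[`, "fullYv")
  heldMask <- matrix(FALSE, n, nOuter)
  for (o in seq_len(nOuter)) heldMask[splitState[[o]]$hold, o] <- TRUE
  holdXu <- fullXu; holdXu[!heldMask] <- NA
  holdYv <- fullYv; holdYv[!heldMask] <- NA
  std <- function(x) {
    x[is.nan(x)] <- NA_real_  # participants never held out
    s <- stats::sd(x, na.rm = TRUE)
    if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s else x
  }
  scores <- data.frame(
    id = meta$id,
    brainScore = std(rowMeans(fullXu)),
    behaviourScore = std(rowMeans(fullYv)),
    brainScoreHoldout = std(rowMeans(holdXu, na.rm = TRUE)),
    behaviourScoreHoldout = std(rowMeans(holdYv, na.rm = TRUE)))
  sig <- if (config$nPerm > 0)
    omnibusDecision(splits$pCorrected, config$alpha)$significant else NA
  methods::new("DimensionResult",
    dimension = as.integer(d), splits = splits,
    models = lapply(perSplit, `[[`, "model"),
    brainLoadings = brainL, behaviourLoadings = behL,
    scores = scores, significant = sig, alpha = config$alpha)
}
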