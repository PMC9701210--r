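#' Hyperparameter grid search with joint correlation + stability selection
#'
#' For every (c_x, c_y) cell, a model is fitted on each inner training set
#' (deconfounding estimated on that training set only and applied to its test
#' set; prior dimensions deflated with the supplied models) and evaluated by
#' the Pearson correlation of the projected inner-test scores. Stability per
#' cell is the mean pairwise sign-aligned Pearson similarity of the weight
#' vectors across inner splits, averaged over u and v. Cells are ranked
#' separately by mean test correlation and by stability; the cell with the
#' best average rank is selected, ties broken toward larger c_x + c_y (more
#' regularised).
#'
#' @param X,Y full-cohort feature matrices (brain already size-normalised;
#'   behaviour sign-mapped); rows indexed by the inner split indices.
#' @param confounds data.frame of confound columns for the full cohort.
#' @param innerSplits list of lists with integer vectors \code{train} and
#'   \code{test} (absolute row indices), e.g. \code{scheme@inner[[o]]}.
#' @param grid data.frame with columns \code{cx} and \code{cy}.
#' @param priorModels list of [RccaModel-class] objects for already-extracted
#'   dimensions (deflation applied, in order, after residualisation).
#' @return list with \code{grid} (the input plus \code{meanTestCor},
#'   \code{stability}, \code{rankScore}), \code{selected} (row index) and
#'   \code{cx}, \code{cy} of the selected cell.
#' @export
gridSearch <- function(X, Y, confounds, innerSplits, grid,
                       priorModels = list()) {
  if (length(innerSplits) < 2)
    stop("need at least 2 inner splits for stability to be defined")
  if (!all(c("cx", "cy") %in% colnames(grid))) stop("grid needs cx and cy")
  nCell <- nrow(grid)
  testCor <- matrix(NA_real_, nCell, length(innerSplits))
  uw <- vector("list", nCell); vw <- vector("list", nCell)
  for (s in seq_along(innerSplits)) {
    tr <- innerSplits[[s]]$train; te <- innerSplits[[s]]$test
    psX <- fitPreprocess(X[tr, , drop = FALSE], confounds[tr, , drop = FALSE])
    psY <- fitPreprocess(Y[tr, , drop = FALSE], confounds[tr, , drop = FALSE])
    Xtr <- applyPreprocess(psX, X[tr, , drop = FALSE], confounds[tr, , drop = FALSE])
    Ytr <- applyPreprocess(psY, Y[tr, , drop = FALSE], confounds[tr, , drop = FALSE])
    Xte <- applyPreprocess(psX, X[te, , drop = FALSE], confounds[te, , drop = FALSE])
    Yte <- applyPreprocess(psY, Y[te, , drop = FALSE], confounds[te, , drop = FALSE])
    for (m in priorModels) {
      dtr <- deflateViews(Xtr, Ytr, m); Xtr <- dtr$X; Ytr <- dtr$Y
      dte <- deflateViews(Xte, Yte, m); Xte <- dte$X; Yte <- dte$Y
    }
    for (g in seq_len(nCell)) {
      fit <- tryCatch(fitRcca(Xtr, Ytr, grid$cx[g], grid$cy[g]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      testCor[g, s] <- tryCatch(projectScores(fit, Xte, Yte)$cor,
                                error = function(e) NA_real_)
      uw[[g]] <- c(uw[[g]], list(fit@u)); vw[[g]] <- c(vw[[g]], list(fit@v))
    }
  }
  meanTestCor <- rowMeans(testCor, na.rm = TRUE)
  stability <- vapply(seq_len(nCell), function(g) {
    wpairStability(uw[[g]], vw[[g]])
  }, numeric(1))
  ok <- is.finite(meanTestCor) & is.finite(stability)
  if (!any(ok)) stop("all grid cells degenerate")
  rankScore <- rep(NA_real_, nCell)
  rankScore[ok] <- (rank(-meanTestCor[ok]) + rank(-stability[ok])) / 2
  cand <- which(ok & rankScore == min(rankScore[ok]))
  selected <- cand[which.max(grid$cx[cand] + grid$cy[cand])]
  out <- grid
  out$meanTestCor <- meanTestCor
  out$stability <- stability
  out$rankScore <- rankScore
  list(grid = out, selected = selected,
       cx = grid$cx[selected], cy = grid$cy[selected])
}

## Mean pairwise sign-aligned Pearson similarity of weight vectors across
## inner splits, averaged over the u and v families. Signs are aligned to the
## first split's model by the dot product.
wpairStability <- function(us, vs) {
  if (length(us) < 2) return(NA_real_)
  us <- lapply(us, alignSign, ref = us[[1]])
  vs <- lapply(vs, alignSign, ref = vs[[1]])
  pair <- function(ws) {
    k <- length(ws); acc <- c()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- safeCor(ws[[i]], ws[[j]])
      acc <- c(acc, r)
    }
    mean(acc, na.rm = TRUE)
  }
  mean(c(pair(us), pair(vs)), na.rm = TRUE)  # length-1 weight vectors have no defined similarity
}
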