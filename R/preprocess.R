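#' Leakage-free confound regression
#'
#' \code{fitPreprocess} estimates, per feature, an ordinary least-squares
#' regression on an intercept plus the confound columns, on training data
#' only. \code{applyPreprocess} residualises any slice with the stored
#' training coefficients, so validation and holdout data never influence the
#' deconfounding (train residuals are exactly orthogonal to each confound;
#' non-train residuals generally are not, by design).
#'
#' @param features numeric matrix, participants x features (training slice).
#' @param confounds data.frame/matrix of confound columns for the same rows
#'   (e.g. age, gender, site dummies). Factors/characters are expanded into
#'   k-1 dummy columns.
#' @return \code{fitPreprocess}: a \code{PreprocessState} list with the
#'   coefficient matrix and confound column template;
#'   \code{applyPreprocess}: the residualised feature matrix.
#' @export
fitPreprocess <- function(features, confounds) {
  features <- as.matrix(features)
  W <- confoundDesign(confounds)
  if (nrow(W) != nrow(features))
    stop("confounds must cover all participants in the slice")
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    drop <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("rank-deficient confound design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrW, features)
  structure(list(beta = beta, columns = colnames(W),
                 template = attr(W, "template"), nTrain = nrow(features)),
            class = "PreprocessState")
}

#' @rdname fitPreprocess
#' @param state a \code{PreprocessState} from [fitPreprocess()].
#' @export
applyPreprocess <- function(state, features, confounds) {
  features <- as.matrix(features)
  W <- confoundDesign(confounds, template = state$template)
  if (!identical(colnames(W), state$columns))
    stop("confound columns do not match the fitted state")
  features - W %*% state$beta
}

## Intercept + numeric confounds + k-1 dummies for factors/characters.
## `template` pins factor levels so train-fitted dummies apply consistently.
confoundDesign <- function(confounds, template = NULL) {
  confounds <- as.data.frame(confounds)
  cols <- list(`(intercept)` = rep(1, nrow(confounds)))
  tmpl <- list()
  for (nm in colnames(confounds)) {
    v <- confounds[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
      tmpl[[nm]] <- NULL
    } else {
      lev <- if (!is.null(template) && !is.null(template[[nm]]))
        template[[nm]] else sort(unique(as.character(v)))
      tmpl[[nm]] <- lev
      for (l in lev[-1]) cols[[paste0(nm, "=", l)]] <- as.numeric(v == l)
    }
  }
  W <- do.call(cbind, cols)
  colnames(W) <- names(cols)
  attr(W, "template") <- tmpl
  W
}

#' Brain-size normalisation
#'
#' Divides each participant's features in every block by that participant's
#' global size total for the block (GMV by the TIV-analogue, CT by the
#' mean-CT-analogue, SA by the total-SA-analogue), so features reflect the
#' relative structural profile of a parcel. Purely per-row arithmetic: no
#' cross-participant statistics, hence no leakage; the pipeline applies it
#' before deconfounding.
#'
#' @param features participants x brain-features matrix.
#' @param totals participants x blocks matrix of positive size totals.
#' @param blockMap character vector, length ncol(features), naming each
#'   feature's block (must match \code{colnames(totals)}).
#' @return the normalised feature matrix.
#' @export
normaliseBrain <- function(features, totals, blockMap) {
  features <- as.matrix(features); totals <- as.matrix(totals)
  if (length(blockMap) != ncol(features))
    stop("blockMap must name a block for every feature column")
  if (!all(blockMap %in% colnames(totals)))
    stop("blocks missing from totals: ",
         paste(setdiff(blockMap, colnames(totals)), collapse = ", "))
  if (any(totals <= 0)) stop("size totals must be positive")
  out <- features
  for (b in unique(blockMap)) {
    idx <- which(blockMap == b)
    out[, idx] <- features[, idx, drop = FALSE] / totals[, b]
  }
  out
}
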