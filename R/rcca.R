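#' Fit a regularized CCA model
#'
#' Finds weight vectors u (brain) and v (behaviour) maximising the cross-view
#' objective u' Cxy v subject to u'[(1-c_x) Cxx + c_x I]u = 1 and
#' v'[(1-c_y) Cyy + c_y I]v = 1, where covariances use the (n-1) denominator
#' and centering is done within the fitting set. c = 0 recovers classical CCA;
#' c = 1 the PLS limit (weights proportional to the leading singular vectors
#' of the cross-covariance). The solver whitens each view with the regularised
#' covariance in the participant-space basis (economy SVD of the centered
#' data), so it is exact and tractable when features far outnumber
#' participants: weights always lie in the row space of the data.
#'
#' The fitted model is sign-oriented so that the behaviour loading of largest
#' magnitude is positive, removing the (u, v) vs (-u, -v) indeterminacy across
#' splits and cohorts. The stored training canonical correlation is the plain
#' Pearson correlation of the training scores Xu and Yv.
#'
#' @param X,Y numeric matrices, row-aligned participants x features; no
#'   missing values; at least 3 rows.
#' @param cx,cy regularisation parameters in [0, 1].
#' @return an [RccaModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4); Y <- X[, 1, drop = FALSE]
#' fitRcca(X, Y, 0, 0)  # training correlation 1 by construction
#' @export
fitRcca <- function(X, Y, cx, cy) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 participants to fit")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed")
  if (cx < 0 || cx > 1 || cy < 0 || cy > 1)
    stop("regularisation parameters must lie in [0, 1]")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm, "-"); Yc <- sweep(Y, 2L, ym, "-")
  if (all(abs(Xc) < 1e-14) || all(abs(Yc) < 1e-14))
    stop("degenerate input: a view has zero variance")
  sx <- svd(Xc); sy <- svd(Yc)
  tolx <- 1e-10 * max(sx$d); toly <- 1e-10 * max(sy$d)
  rx <- sum(sx$d > tolx); ry <- sum(sy$d > toly)
  if (rx == 0 || ry == 0) stop("degenerate input: a view has zero variance")
  dx <- sx$d[seq_len(rx)]; dy <- sy$d[seq_len(ry)]
  ## regularised variances along each view's principal axes
  gx <- (1 - cx) * dx^2 / (n - 1) + cx
  gy <- (1 - cy) * dy^2 / (n - 1) + cy
  ## whitened cross-covariance in the (Qx, Qy) bases:
  ## M = Gx^{-1/2} Dx Px'Py Dy Gy^{-1/2} / (n-1)
  M <- crossprod(sx$u[, seq_len(rx), drop = FALSE],
                 sy$u[, seq_len(ry), drop = FALSE])
  M <- (dx / sqrt(gx)) * M * rep(dy / sqrt(gy), each = rx)
  M <- M / (n - 1)
  sm <- svd(M, nu = 1L, nv = 1L)
  a <- sm$u[, 1L] / sqrt(gx)
  b <- sm$v[, 1L] / sqrt(gy)
  u <- sx$v[, seq_len(rx), drop = FALSE] %*% a
  v <- sy$v[, seq_len(ry), drop = FALSE] %*% b
  xu <- drop(Xc %*% u); yv <- drop(Yc %*% v)
  if (stats::sd(xu) == 0 || stats::sd(yv) == 0)
    stop("degenerate fit: constant scores")
  ## sign convention: largest-magnitude behaviour loading positive
  bl <- suppressWarnings(stats::cor(Yc, yv))
  bl[is.na(bl)] <- 0
  if (bl[which.max(abs(bl))] < 0) { u <- -u; v <- -v; xu <- -xu; yv <- -yv }
  methods::new("RccaModel",
    u = as.numeric(u), v = as.numeric(v), cx = cx, cy = cy,
    trainCor = stats::cor(xu, yv), xMeans = xm, yMeans = ym, n = n)
}

#' Project data onto a fitted model's weights
#'
#' Returns the score pair (Xu, Yv) using the model's training-set centering.
#' Applying to the training set reproduces the stored training canonical
#' correlation exactly.
#'
#' @param model an [RccaModel-class].
#' @param X,Y matrices with the model's feature counts.
#' @return list with numeric vectors \code{xu}, \code{yv} and their Pearson
#'   correlation \code{cor}.
#' @export
projectScores <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != length(model@u) || ncol(Y) != length(model@v))
    stop("feature counts do not match the model")
  xu <- drop(sweep(X, 2L, model@xMeans, "-") %*% model@u)
  yv <- drop(sweep(Y, 2L, model@yMeans, "-") %*% model@v)
  if (stats::sd(xu) == 0 || stats::sd(yv) == 0)
    stop("degenerate projection: constant scores (zero weight vector or constant data)")
  list(xu = xu, yv = yv, cor = stats::cor(xu, yv))
}

#' Loadings: correlations of original variables with the scores
#'
#' @param X,Y the original (unprojected) variables, row-aligned with the
#'   scores.
#' @param scores a score pair from [projectScores()].
#' @return list of numeric vectors \code{brain} and \code{behaviour}; a
#'   zero-variance variable yields NA (an explicit undefined marker, never a
#'   silent 0).
#' @export
computeLoadings <- function(X, Y, scores) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != length(scores$xu) || nrow(Y) != length(scores$yv))
    stop("rows of X/Y must align with the scores")
  list(
    brain = vapply(seq_len(ncol(X)), function(j) safeCor(X[, j], scores$xu),
                   numeric(1)),
    behaviour = vapply(seq_len(ncol(Y)), function(j) safeCor(Y[, j], scores$yv),
                       numeric(1)))
}

#' Projection deflation of both views
#'
#' Removes from each view the rank-one component along its own score vector:
#' X <- (I - s s'/s's) X with s = Xu, and likewise for Y with Yv. The deflated
#' X satisfies X_deflated u = 0 on the deflating set, so successive fitted
#' scores are orthogonal there.
#'
#' @param X,Y centered (or residualised) matrices to deflate.
#' @param model the fitted [RccaModel-class] supplying u and v (scores are
#'   recomputed on X and Y themselves, so holdout data can be deflated with an
#'   optimisation-set model without leakage).
#' @return list with matrices \code{X} and \code{Y}.
#' @export
deflateViews <- function(X, Y, model) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != length(model@u) || ncol(Y) != length(model@v))
    stop("feature counts do not match the model")
  sx <- drop(X %*% model@u); sy <- drop(Y %*% model@v)
  nx <- sum(sx^2); ny <- sum(sy^2)
  if (nx < 1e-24 || ny < 1e-24) stop("zero-norm score: cannot deflate")
  list(X = X - sx %*% crossprod(sx, X) / nx,
       Y = Y - sy %*% crossprod(sy, Y) / ny)
}
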