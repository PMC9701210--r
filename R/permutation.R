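#' Family-restricted permutation of participants
#'
#' Draws a random permutation that respects the family (exchangeability
#' block) structure: whole families are permuted only among families with an
#' identical composition signature (the multiset of member zygosity types),
#' and members within a family are permuted only among members of the same
#' type (MZ and DZ twins are distinct types; \code{"S"} covers singletons and
#' non-twin siblings). For an all-singleton sample this reduces to a uniform
#' random permutation. The identity permutation is always a member of the
#' valid set.
#'
#' @param metadata data.frame with columns \code{family_id} and
#'   \code{zygosity} for the participants being permuted, in row order.
#' @param seed integer seed.
#' @return integer vector \code{perm} of length \code{nrow(metadata)}: row i
#'   of the permuted data is row \code{perm[i]} of the original.
#' @export
permuteWithinBlocks <- function(metadata, seed = 1L) {
  if (!all(c("family_id", "zygosity") %in% colnames(metadata)))
    stop("metadata needs 'family_id' and 'zygosity' columns")
  n <- nrow(metadata)
  famIdx <- split(seq_len(n), metadata$family_id)
  sig <- vapply(famIdx, function(ix) {
    tab <- table(metadata$zygosity[ix])
    paste(names(tab), as.integer(tab), sep = ":", collapse = "|")
  }, character(1))
  perm <- integer(n)
  withSeed(seed, {
    for (group in split(seq_along(famIdx), sig)) {
      sigma <- if (length(group) > 1) sample(group) else group
      for (gi in seq_along(group)) {
        tgtFam <- famIdx[[group[gi]]]
        srcFam <- famIdx[[sigma[gi]]]
        tgtTypes <- metadata$zygosity[tgtFam]
        srcTypes <- metadata$zygosity[srcFam]
        for (t in unique(tgtTypes)) {
          tgt <- tgtFam[tgtTypes == t]
          src <- srcFam[srcTypes == t]
          perm[tgt] <- if (length(src) > 1) sample(src) else src
        }
      }
    }
  })
  perm
}

#' Permutation p-value with Bonferroni correction over outer splits
#'
#' p is the fraction of null statistics strictly exceeding the observed one
#' (ties do not count against the observed value), floored at 1/n_perm so the
#' minimum reportable uncorrected p at 1000 permutations is 0.001; the
#' corrected value is min(1, nOuter * p).
#'
#' @param observed observed statistic (holdout canonical correlation).
#' @param nulls numeric vector of permutation-null statistics.
#' @param nOuter Bonferroni factor (number of outer splits, default 5).
#' @param estimator \code{"strict"} (the default count/n rule) or
#'   \code{"plus-one"} for the (count+1)/(n+1) variant.
#' @return list with \code{p} and \code{pCorrected}.
#' @export
permutationPvalue <- function(observed, nulls, nOuter = 5L,
                              estimator = c("strict", "plus-one")) {
  estimator <- match.arg(estimator)
  if (length(nulls) < 1) stop("empty null distribution")
  nPerm <- length(nulls)
  p <- if (estimator == "strict") {
    max(sum(nulls > observed) / nPerm, 1 / nPerm)
  } else {
    (sum(nulls > observed) + 1) / (nPerm + 1)
  }
  list(p = p, pCorrected = min(1, nOuter * p))
}

#' Permutation test for one outer split with frozen hyperparameters
#'
#' Per iteration, the rows of the behaviour view are shuffled separately (and
#' independently) within the optimisation and holdout sets, each respecting
#' the family structure; the model is refitted on the permuted optimisation
#' set with the regularisation parameters selected on the original data
#' (never re-selected under permutation), the permuted holdout set is
#' projected, and the holdout correlation is recorded. A failed fit is
#' retried once with a fresh permutation.
#'
#' @param Xopt,Yopt,Xhold,Yhold preprocessed (and, beyond the first
#'   dimension, deflated) optimisation and holdout views.
#' @param optMeta,holdMeta data.frames with \code{family_id} and
#'   \code{zygosity} for the optimisation and holdout rows.
#' @param cx,cy frozen regularisation parameters.
#' @param observed observed holdout correlation.
#' @param nPerm number of iterations (default 1000).
#' @param nOuter Bonferroni factor for the corrected p.
#' @param seed integer seed; per-iteration seeds are derived from it.
#' @inheritParams permutationPvalue
#' @return list with \code{observed}, \code{nulls}, \code{p},
#'   \code{pCorrected} and \code{nFailed}.
#' @export
runPermutationTest <- function(Xopt, Yopt, Xhold, Yhold, optMeta, holdMeta,
                               cx, cy, observed, nPerm = 1000L, nOuter = 5L,
                               seed = 1L, estimator = "strict") {
  nulls <- numeric(nPerm)
  nFailed <- 0L
  for (i in seq_len(nPerm)) {
    r <- NA_real_
    for (attempt in 1:2) {
      permO <- permuteWithinBlocks(optMeta, deriveSeed(seed, i, attempt, 1L))
      permH <- permuteWithinBlocks(holdMeta, deriveSeed(seed, i, attempt, 2L))
      r <- tryCatch({
        mod <- fitRcca(Xopt, Yopt[permO, , drop = FALSE], cx, cy)
        projectScores(mod, Xhold, Yhold[permH, , drop = FALSE])$cor
      }, error = function(e) NA_real_)
      if (is.finite(r)) break
      nFailed <- nFailed + 1L
    }
    if (!is.finite(r)) stop("permutation iteration ", i, " failed twice")
    nulls[i] <- r
  }
  pv <- permutationPvalue(observed, nulls, nOuter, estimator)
  list(observed = observed, nulls = nulls, p = pv$p,
       pCorrected = pv$pCorrected, nFailed = nFailed)
}

#' Omnibus decision over outer splits
#'
#' The omnibus null hypothesis is "no effect in any outer split"; it is
#' rejected when the smallest Bonferroni-corrected p-value is strictly below
#' alpha (a corrected p exactly equal to alpha is not significant).
#'
#' @param pCorrected numeric vector of corrected p-values, one per outer
#'   split.
#' @param alpha significance level (default 0.05).
#' @return list with logical \code{significant} and \code{minP}.
#' @export
omnibusDecision <- function(pCorrected, alpha = 0.05) {
  if (!length(pCorrected)) stop("need one corrected p per outer split")
  list(significant = any(pCorrected < alpha, na.rm = FALSE),
       minP = min(pCorrected))
}
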