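#' Family-aware nested split scheme
#'
#' Randomly assigns whole families to either side of each split so no family
#' is ever divided, hitting the target participant fractions as closely as the
#' family sizes allow. Outer splits divide the cohort into optimisation and
#' holdout sets; within each outer split, inner splits divide the optimisation
#' set into training and testing sets. Deterministic given \code{seed}.
#'
#' @param metadata data.frame with columns \code{id} and \code{family_id}
#'   (singleton families allowed), e.g. \code{participantInfo(cohort)}.
#' @param nOuter,nInner numbers of outer and inner splits (defaults 5 and 5).
#' @param fractions named numeric with \code{optimisation} (outer) and
#'   \code{train} (inner) fractions; holdout and test are the complements.
#' @param seed integer seed.
#' @return a [SplitScheme-class]; indices refer to rows of \code{metadata}.
#' @export
makeSplitScheme <- function(metadata, nOuter = 5L, nInner = 5L,
                            fractions = c(optimisation = 0.8, train = 0.8),
                            seed = 1L) {
  if (!all(c("id", "family_id") %in% colnames(metadata)))
    stop("metadata needs 'id' and 'family_id' columns")
  if (anyNA(metadata$family_id)) stop("every participant needs a family_id")
  n <- nrow(metadata)
  famIdx <- split(seq_len(n), metadata$family_id)
  holdTarget <- round((1 - fractions[["optimisation"]]) * n)
  if (max(lengths(famIdx)) > max(holdTarget, 1)) {
    stop("a family (", max(lengths(famIdx)), " members) exceeds the holdout ",
         "target (", holdTarget, " participants); enlarge the cohort or the ",
         "holdout fraction")
  }
  outer <- vector("list", nOuter)
  inner <- vector("list", nOuter)
  for (o in seq_len(nOuter)) {
    sides <- withSeed(deriveSeed(seed, 101L, o),
                      splitFamilies(famIdx, 1 - fractions[["optimisation"]]))
    outer[[o]] <- list(optimisation = sides$rest, holdout = sides$taken)
    optFams <- famIdx[vapply(famIdx, function(ix) all(ix %in% sides$rest),
                             logical(1))]
    inner[[o]] <- lapply(seq_len(nInner), function(i) {
      s <- withSeed(deriveSeed(seed, 202L, o, i),
                    splitFamilies(optFams, 1 - fractions[["train"]]))
      list(train = s$rest, test = s$taken)
    })
  }
  methods::new("SplitScheme",
    outer = outer, inner = inner, nOuter = as.integer(nOuter),
    nInner = as.integer(nInner), fractions = fractions,
    seed = as.integer(seed))
}

## Assign whole families at random until the taken side is as close as
## possible to `frac` of the participants: families are shuffled and the
## cumulative-size cut nearest the target is used.
splitFamilies <- function(famIdx, frac) {
  ord <- sample(length(famIdx))
  sizes <- lengths(famIdx)[ord]
  target <- frac * sum(sizes)
  cum <- cumsum(sizes)
  k <- which.min(abs(cum - target))
  if (abs(cum[k] - target) > target) k <- 0L  # empty side strictly closer
  takenFams <- ord[seq_len(k)]
  taken <- sort(unlist(famIdx[takenFams], use.names = FALSE))
  rest <- sort(unlist(famIdx[setdiff(seq_along(famIdx), takenFams)],
                      use.names = FALSE))
  list(taken = taken, rest = rest)
}
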