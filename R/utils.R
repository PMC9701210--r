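# Internal helpers: deterministic seed streams, sign alignment, small numerics.

## All randomness in the package flows from a single master seed; sub-streams
## are derived with a Weyl-style integer hash so that independent stages
## (splits, permutations, rotations) never share a stream.
deriveSeed <- function(master, ...) {
  tags <- c(...)
  s <- as.double(master) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 2654435761 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483647)
}

## Evaluate `expr` under `seed` without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

## Sign-aligned cosine/correlation helpers: (u, v) and (-u, -v) are the same
## model, so comparisons are made after aligning to a reference direction.
alignSign <- function(x, ref) {
  s <- sum(x * ref)
  if (s < 0) -x else x
}

colCenter <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

## Pearson correlation that returns NA (not an error/warning) for
## zero-variance inputs; used for loadings where the spec requires an
## explicit undefined marker.
safeCor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
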