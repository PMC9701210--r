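# Small cohort builders shared across test files.

smallSpec <- function(seed = 1L, rho = 0.6, nFam = 40, nSingle = 40,
                      nBehaviour = 8, brainBlocks = c(GMV = 12, CT = 10, SA = 10),
                      ...) {
  planted <- if (is.null(rho)) list() else list(plantedDimension(rho))
  cohortSpec(
    familyBlocks = c(hcpYaFamilyBlocks(nFam, seed = seed + 1000L),
                     singletonFamilyBlocks(nSingle)),
    nBehaviour = nBehaviour, brainBlocks = brainBlocks,
    planted = planted, seed = seed, ...)
}

# rho = NULL gives a null cohort (no planted structure)
smallCohort <- function(seed = 1L, ...) generateCohort(smallSpec(seed = seed, ...))

quickConfig <- function(seed = 1L, ...) {
  args <- list(cGrid = c(0.3, 1), nInner = 3L, nPerm = 0L,
               maxDimensions = 1L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(frameworkConfig, args)
}

# family blocks (study-like twin families) padded with singletons to exactly
# n participants
familyBlocksForN <- function(n, seed = 1L) {
  fams <- hcpYaFamilyBlocks(ceiling(n / 4.5), seed = seed)
  sizes <- cumsum(lengths(fams))
  keep <- which(sizes <= n - 1)
  fams <- fams[keep]
  c(fams, singletonFamilyBlocks(n - sum(lengths(fams))))
}

# textbook generalised-eigenvalue CCA oracle (first canonical correlation),
# written directly from the definition; independent of the package solver
oracleCca <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(Re(eigen(M, only.values = TRUE)$values)))
}
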