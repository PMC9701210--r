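#' Write a cohort to a directory of TSV/JSON files
#'
#' The on-disk contract (also accepted by [readCohort()]): \code{brain.tsv}
#' and \code{behaviour.tsv} (participants x features, first column \code{id},
#' remaining headers the parcel/variable ids), \code{metadata.tsv} (id, age,
#' gender, site, family_id, zygosity, pair_id), \code{sizes.tsv} (id plus one
#' column of global size totals per block), \code{parcels.tsv} (id, block,
#' hemisphere, x, y, z, volumetric) and, for synthetic cohorts,
#' \code{truth.json} with the generating parameters and planted loading
#' patterns.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  meta <- participantInfo(cohort)
  wtsv(cbind(id = meta$id, as.data.frame(brainView(cohort))), "brain.tsv")
  wtsv(cbind(id = meta$id, as.data.frame(behaviourView(cohort))),
       "behaviour.tsv")
  wtsv(meta, "metadata.tsv")
  wtsv(cbind(id = meta$id, as.data.frame(sizeTotals(cohort))), "sizes.tsv")
  wtsv(parcelTable(cohort), "parcels.tsv")
  truth <- cohortTruth(cohort)
  if (length(truth)) {
    spec <- truth$spec
    tr <- list(
      seed = spec$seed, h2Target = spec$h2Target, noiseSd = spec$noiseSd,
      globalSizeNoise = spec$globalSizeNoise,
      nBehaviour = spec$nBehaviour,
      brainBlocks = as.list(spec$brainBlocks),
      plantedRho = vapply(spec$planted, `[[`, numeric(1), "rho"),
      brainPatterns = truth$brainPatterns,
      behaviourPatterns = truth$behaviourPatterns)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read and validate a cohort directory
#'
#' Performs an itemised validation: all files present, ids shared and aligned
#' across tables (participants present in the features but absent from the
#' metadata are listed), no missing values (the offending row and column are
#' named), parcel table consistent with the brain columns.
#'
#' @param dir directory written by [writeCohort()] (or assembled to the same
#'   contract).
#' @return a [Cohort-class]; the \code{truth} slot is populated from
#'   \code{truth.json} when present.
#' @export
readCohort <- function(dir) {
  rtsv <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing file: ", f)
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  brain <- rtsv("brain.tsv"); beh <- rtsv("behaviour.tsv")
  meta <- rtsv("metadata.tsv"); sizes <- rtsv("sizes.tsv")
  parcels <- rtsv("parcels.tsv")
  problems <- character()
  for (nm in c("brain", "behaviour", "sizes")) {
    tab <- switch(nm, brain = brain, behaviour = beh, sizes = sizes)
    extra <- setdiff(tab$id, meta$id)
    if (length(extra))
      problems <- c(problems, paste0(nm, ".tsv has ids absent from metadata: ",
                                     paste(extra, collapse = ", ")))
    missing <- setdiff(meta$id, tab$id)
    if (length(missing))
      problems <- c(problems, paste0(nm, ".tsv lacks ids: ",
                                     paste(missing, collapse = ", ")))
    na <- which(is.na(as.matrix(tab[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(na))
      problems <- c(problems, paste0(
        nm, ".tsv has missing values, e.g. row id '", tab$id[na[1, 1]],
        "', column '", colnames(tab)[-1][na[1, 2]], "'"))
  }
  if (length(problems))
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  ord <- match(meta$id, brain$id)
  asMat <- function(tab, o) {
    m <- as.matrix(tab[o, -1, drop = FALSE])
    rownames(m) <- tab$id[o]
    m
  }
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
  if (length(truth) && !is.null(truth$brainPatterns))
    truth$brainPatterns <- as.matrix(truth$brainPatterns)
  if (length(truth) && !is.null(truth$behaviourPatterns))
    truth$behaviourPatterns <- as.matrix(truth$behaviourPatterns)
  methods::new("Cohort",
    brain = asMat(brain, ord),
    behaviour = asMat(beh, match(meta$id, beh$id)),
    participants = meta,
    sizeTotals = asMat(sizes, match(meta$id, sizes$id)),
    parcels = parcels,
    truth = if (length(truth)) list(json = truth) else list())
}

#' Export dimension results as TSV tables plus a JSON run manifest
#'
#' Writes, per dimension, \code{dimK_splits.tsv} (selected hyperparameters,
#' holdout correlation, p-values per outer split),
#' \code{dimK_loadings_brain.tsv} / \code{dimK_loadings_behaviour.tsv}
#' (split-averaged loadings with sd and the unstable flag) and
#' \code{dimK_scores.tsv}, and a \code{manifest.json} recording the
#' configuration, master seed and package version -- sufficient to reproduce
#' the run bitwise with [runFramework()].
#'
#' @param results list of [DimensionResult-class] from [runFramework()].
#' @param config the [frameworkConfig()] used.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeDimensionResults <- function(results, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (res in results) {
    k <- res@dimension
    wtsv(splitSummary(res), sprintf("dim%d_splits.tsv", k))
    wtsv(res@brainLoadings, sprintf("dim%d_loadings_brain.tsv", k))
    wtsv(res@behaviourLoadings, sprintf("dim%d_loadings_behaviour.tsv", k))
    wtsv(dimensionScores(res), sprintf("dim%d_scores.tsv", k))
  }
  manifest <- list(
    package = "latentcca",
    version = as.character(utils::packageVersion("latentcca")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = config[setdiff(names(config), "grid")],
    cGrid = sort(unique(config$grid$cx)),
    nDimensions = length(results),
    significant = vapply(results, isSignificant, logical(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
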