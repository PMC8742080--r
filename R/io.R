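# Survey container, CSV round trip, species inclusion filters, and
# posterior persistence.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

.metaCols <- c("towId", "lon", "lat", "year", "season", "stratum")

#' Build a SurveyExperiment from a response matrix and covariate table
#'
#' @param y n x S matrix, tows in rows and species in columns (CPUE kg/tow
#'   or 0/1 presence).
#' @param covariates data.frame with one row per tow: the meta columns
#'   towId, lon, lat, year, season, stratum plus environmental covariates.
#' @param assayName \code{"cpue"} or \code{"pa"}.
#' @return a \linkS4class{SurveyExperiment} (species x tows assay).
#' @export
surveyExperiment <- function(y, covariates, assayName = c("cpue", "pa")) {
  assayName <- match.arg(assayName)
  y <- as.matrix(y)
  if (nrow(covariates) != nrow(y))
    stop("covariates and response disagree on the number of tows")
  if (anyDuplicated(covariates$towId)) stop("tow ids must be unique")
  if (assayName == "cpue" && any(y < 0))
    stop("negative CPUE value(s); CPUE must be nonnegative")
  if (assayName == "pa" && !all(y %in% c(0, 1)))
    stop("presence/absence values must be 0/1")
  a <- t(y)
  colnames(a) <- covariates$towId
  se <- SummarizedExperiment(assays = setNames(list(a), assayName),
                             colData = DataFrame(covariates))
  new("SurveyExperiment", se)
}

#' Tow-by-species response matrix of a SurveyExperiment
#' @param se a \linkS4class{SurveyExperiment}
#' @return n x S matrix (tows in rows)
#' @export
responseMatrix <- function(se) t(SummarizedExperiment::assay(se, 1))

#' Covariate table of a SurveyExperiment
#' @param se a \linkS4class{SurveyExperiment}
#' @return data.frame, one row per tow
#' @export
covariateTable <- function(se) as.data.frame(colData(se))

#' Write a survey table to CSV
#'
#' One row per tow: the meta columns, the covariates, then one column per
#' species prefixed \code{cpue_} (or \code{pa_}).
#'
#' @param se a \linkS4class{SurveyExperiment}
#' @param path output file.
#' @export
writeSurveyCsv <- function(se, path) {
  y <- responseMatrix(se)
  prefix <- if (names(SummarizedExperiment::assays(se))[1] == "cpue")
    "cpue_" else "pa_"
  colnames(y) <- paste0(prefix, colnames(y))
  tab <- cbind(covariateTable(se), as.data.frame(y))
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a survey table from CSV
#'
#' Species columns are identified by the \code{cpue_} / \code{pa_} prefix;
#' everything else apart from the meta columns is treated as a covariate.
#' Rows with missing covariate values are dropped with a message recording
#' the count (also returned as the \code{"droppedRows"} attribute).
#'
#' @param path CSV file written by \code{\link{writeSurveyCsv}} (or matching
#'   its schema).
#' @param requiredCovariates character vector of covariate columns that
#'   must be present.
#' @return a \linkS4class{SurveyExperiment}
#' @export
readSurveyCsv <- function(path, requiredCovariates = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sppCols <- grep("^(cpue|pa)_", names(tab), value = TRUE)
  if (!length(sppCols)) stop("no species columns (cpue_/pa_ prefix) found")
  prefix <- if (startsWith(sppCols[1], "cpue_")) "cpue" else "pa"
  miss <- setdiff(requiredCovariates, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  covCols <- setdiff(names(tab), sppCols)
  bad <- !stats::complete.cases(tab[covCols])
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing covariates")
    tab <- tab[!bad, , drop = FALSE]
  }
  y <- as.matrix(tab[sppCols])
  if (!is.numeric(y)) {
    badRow <- which(apply(tab[sppCols], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))[1]
    stop("non-numeric CPUE at row ", badRow)
  }
  if (anyNA(y)) stop("non-numeric CPUE at row ", which(rowSums(is.na(y)) > 0)[1])
  colnames(y) <- sub("^(cpue|pa)_", "", sppCols)
  se <- surveyExperiment(y, tab[covCols],
                         assayName = if (prefix == "cpue") "cpue" else "pa")
  attr(se, "droppedRows") <- sum(bad)
  se
}

#' Species inclusion filter
#'
#' Keeps species present in at least \code{minPresenceTows} tows and with a
#' CPUE of at least \code{minBiomass} kg/tow in more than
#' \code{minBiomassTows} tows (note the strict inequality on the tow
#' count). Defaults are 400 tows, 0.5 kg/tow, and 100 tows.
#'
#' @param y n x S CPUE matrix (or a \linkS4class{SurveyExperiment}).
#' @param minPresenceTows,minBiomass,minBiomassTows filter thresholds, all
#'   nonnegative.
#' @return list: \code{kept} (species names), \code{report} (per-species
#'   counts and decision).
#' @export
filterSpecies <- function(y, minPresenceTows = 400, minBiomass = 0.5,
                          minBiomassTows = 100) {
  if (is(y, "SurveyExperiment")) y <- responseMatrix(y)
  if (any(c(minPresenceTows, minBiomass, minBiomassTows) < 0))
    stop("filter thresholds must be nonnegative")
  presence <- colSums(y > 0)
  biomass <- colSums(y >= minBiomass)
  keep <- presence >= minPresenceTows & biomass > minBiomassTows
  spp <- colnames(y); if (is.null(spp)) spp <- paste0("sp", seq_len(ncol(y)))
  list(kept = spp[keep],
       report = data.frame(species = spp, presenceTows = presence,
                           biomassTows = biomass, kept = keep,
                           row.names = NULL))
}

#' Persist a fitted posterior as text
#'
#' Writes the draw arrays as a flat CSV (one row per retained draw) plus a
#' JSON sidecar with the chain settings, seed, species, term labels, and
#' standardization parameters needed to reproduce or reload the fit.
#'
#' @param fit a \linkS4class{JsdmFit}
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
savePosterior <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Q <- dim(fit@Bdraws)[1]; S <- dim(fit@Bdraws)[2]; M <- nDraws(fit)
  Bflat <- t(matrix(fit@Bdraws, Q * S, M))
  colnames(Bflat) <- paste0("B.", outer(dimnames(fit@Bdraws)[[1]],
                                        dimnames(fit@Bdraws)[[2]],
                                        paste, sep = "."))
  Sflat <- t(matrix(fit@SigmaDraws, S * S, M))
  colnames(Sflat) <- paste0("Sigma.", outer(dimnames(fit@SigmaDraws)[[1]],
                                            dimnames(fit@SigmaDraws)[[2]],
                                            paste, sep = "."))
  drawsPath <- file.path(dir, "draws.csv")
  utils::write.csv(cbind(draw = seq_len(M), Bflat, Sflat, deviance = fit@deviance),
                   drawsPath, row.names = FALSE)
  meta <- list(kind = fit@kind,
               nIter = fit@nIter, burnin = fit@burnin, thin = fit@thin,
               seed = fit@seed, nu0 = fit@nu0,
               terms = dimnames(fit@Bdraws)[[1]],
               species = dimnames(fit@Bdraws)[[2]],
               standardization = standardizationParams(fit@design))
  metaPath <- file.path(dir, "posterior.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  sumPath <- file.path(dir, "summaries.csv")
  utils::write.csv(fitSummaries(fit), sumPath, row.names = FALSE)
  invisible(c(draws = drawsPath, meta = metaPath, summaries = sumPath))
}

#' Reload posterior draws written by savePosterior
#'
#' @param dir directory written by \code{\link{savePosterior}}.
#' @return list: \code{Bdraws}, \code{SigmaDraws}, \code{deviance},
#'   \code{meta}.
#' @export
loadPosterior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "posterior.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  Q <- length(meta$terms); S <- length(meta$species); M <- nrow(tab)
  B <- array(t(as.matrix(tab[, grep("^B\\.", names(tab))])), c(Q, S, M),
             dimnames = list(meta$terms, meta$species, NULL))
  Sg <- array(t(as.matrix(tab[, grep("^Sigma\\.", names(tab))])), c(S, S, M),
              dimnames = list(meta$species, meta$species, NULL))
  list(Bdraws = B, SigmaDraws = Sg, deviance = tab$deviance, meta = meta)
}
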