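#' @import methods
#' @importFrom stats pnorm qnorm runif rnorm quantile median sd var cov
#'   optimize optim rWishart kmeans cov2cor setNames acf
NULL

#' Model specification for a joint species distribution model
#'
#' Describes the mean structure of the censored latent Gaussian model: an
#' intercept, continuous covariates (standardized by default), factors with a
#' named baseline level, and two-way interactions (continuous x continuous or
#' continuous x factor). The response kind selects the multivariate tobit
#' (\code{"CA"}, continuous abundance such as CPUE in kg/tow with exact
#' zeros) or the multivariate probit (\code{"PA"}, presence/absence).
#'
#' @slot responseKind \code{"CA"} or \code{"PA"}.
#' @slot terms ordered list of term descriptors. Each is a list with a
#'   \code{type} (\code{"intercept"}, \code{"continuous"}, \code{"factor"},
#'   \code{"interaction"}) plus \code{var} (continuous/factor),
#'   \code{levels} (factor; first level is the baseline), or \code{a},
#'   \code{b} (interaction parents, \code{b} may be a factor).
#' @slot standardize center/scale continuous covariates before forming
#'   interaction columns.
#' @export
setClass("JsdmModelSpec",
  representation(responseKind = "character", terms = "list",
                 standardize = "logical"))

#' Design matrix with recorded standardization
#'
#' The n x Q numeric design built from a survey table under a
#' \linkS4class{JsdmModelSpec}. Standardization parameters (per-covariate
#' mean and sd from the training data) are stored so the identical transform
#' can be replayed on new data at prediction time. The originating covariate
#' table is kept for inverse prediction, where interaction columns must be
#' recomputed as functions of the base covariates.
#'
#' @slot values n x Q matrix; column 1 is the intercept.
#' @slot columnTerms integer vector mapping columns to term indices in the spec.
#' @slot standardization named list of c(mean, sd) per continuous covariate.
#' @slot spec the \linkS4class{JsdmModelSpec} used.
#' @slot data the covariate data.frame the matrix was built from.
#' @export
setClass("JsdmDesign",
  representation(values = "matrix", columnTerms = "integer",
                 standardization = "list", spec = "JsdmModelSpec",
                 data = "data.frame"))

#' Trawl-survey container
#'
#' A \linkS4class{SummarizedExperiment} with one assay (\code{"cpue"} for
#' continuous abundance in kg/tow, or \code{"pa"} for presence/absence)
#' holding species in rows and tows in columns, and tow-level covariates
#' (coordinates, year, season, environmental variables, subregion) in
#' \code{colData}.
#'
#' @export
setClass("SurveyExperiment", contains = "SummarizedExperiment")

#' Posterior of a fitted joint species distribution model
#'
#' Post-burn-in Gibbs draws of the coefficient matrix B (Q x S) and residual
#' covariance Sigma (S x S), with the inputs needed to reproduce and extend
#' the fit. For presence/absence fits every stored Sigma draw is a
#' correlation matrix (unit diagonal) and B is rescaled compatibly.
#'
#' @slot kind response kind, \code{"CA"} or \code{"PA"}.
#' @slot Bdraws Q x S x M array of coefficient draws.
#' @slot SigmaDraws S x S x M array of residual covariance draws.
#' @slot deviance length-M complete-data deviance at each retained draw.
#' @slot meanW posterior mean of the latent matrix over retained draws.
#' @slot WSnapshots list of retained latent matrices for invariant checks.
#' @slot y the n x S response matrix the model was fitted to.
#' @slot design the \linkS4class{JsdmDesign} used.
#' @slot nIter,burnin,thin,seed chain settings.
#' @slot nu0,Psi0 inverse-Wishart prior degrees of freedom and scale.
#' @slot summaries per-coefficient data.frame (mean, sd, quantiles,
#'   significance flag, effective sample size).
#' @export
setClass("JsdmFit",
  representation(kind = "character", Bdraws = "array", SigmaDraws = "array",
                 deviance = "numeric", meanW = "matrix", WSnapshots = "list",
                 y = "matrix", design = "JsdmDesign",
                 nIter = "integer", burnin = "integer", thin = "integer",
                 seed = "integer", nu0 = "numeric", Psi0 = "matrix",
                 summaries = "data.frame"))

#' Generating truth for synthetic communities
#'
#' Bundles the model specification, true coefficients and residual
#' covariance, and covariate-generation settings used to simulate a survey,
#' so parameter recovery can be scored against known values.
#'
#' @slot spec the generating \linkS4class{JsdmModelSpec}.
#' @slot B true Q x S coefficient matrix.
#' @slot Sigma true S x S residual covariance (positive definite).
#' @slot covariateStructure list used by \code{\link{generateCovariates}}.
#' @slot seed integer seed the scenario was built from.
#' @export
setClass("JsdmTruth",
  representation(spec = "JsdmModelSpec", B = "matrix", Sigma = "matrix",
                 covariateStructure = "list", seed = "integer"))

setValidity("JsdmModelSpec", function(object) {
  msg <- character()
  if (!object@responseKind %in% c("CA", "PA"))
    msg <- c(msg, "responseKind must be 'CA' or 'PA'")
  types <- vapply(object@terms, function(t) t$type, character(1))
  if (sum(types == "intercept") != 1L)
    msg <- c(msg, "exactly one intercept term required")
  labs <- vapply(object@terms, .termLabel, character(1))
  if (anyDuplicated(labs))
    msg <- c(msg, paste("duplicate terms:", paste(labs[duplicated(labs)], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setValidity("JsdmFit", function(object) {
  d <- dim(object@Bdraws)
  ds <- dim(object@SigmaDraws)
  msg <- character()
  if (length(d) != 3L || length(ds) != 3L || d[3] != ds[3])
    msg <- c(msg, "Bdraws and SigmaDraws must be 3-d arrays over the same draws")
  if (ds[1] != ds[2] || d[2] != ds[1])
    msg <- c(msg, "Sigma draws must be S x S matching ncol(B)")
  if (length(msg)) msg else TRUE
})

setValidity("JsdmTruth", function(object) {
  if (!.isSymmetricPD(object@Sigma)) return("true Sigma must be symmetric positive definite")
  if (ncol(object@B) != ncol(object@Sigma)) return("B and Sigma disagree on species count")
  TRUE
})
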