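# Synthetic trawl-survey generator with known truth.
#
# Emulates the structure of a Northeast US shelf bottom-trawl CPUE survey:
# correlated continuous covariates (bottom/surface temperature and salinity,
# depth), a two-level subregion factor with covariate mean shifts, depth
# interactions, heavy zero inflation with at least one rare species, and
# region-specific coordinate boxes. The generating coefficients and residual
# covariance are returned so parameter recovery can be scored exactly.

#' Default covariate-generation structure
#'
#' Covariates are drawn multivariate normal on realistic scales (depth
#' 10-300 m, temperatures 3-27 degrees C, salinities around 31-35 psu) with
#' negative depth-temperature correlation, and the subregion factor shifts
#' covariate means (the southern region warmer and shallower). The model
#' consumes standardized values, so the scales are cosmetic.
#'
#' @return list understood by \code{\link{generateCovariates}}.
#' @export
defaultCovariateStructure <- function() {
  vars <- c("BT", "SST", "BSAL", "SSAL", "depth")
  corr <- diag(5)
  dimnames(corr) <- list(vars, vars)
  corr["BT", "SST"] <- corr["SST", "BT"] <- 0.6
  corr["BT", "depth"] <- corr["depth", "BT"] <- -0.5
  corr["SST", "depth"] <- corr["depth", "SST"] <- -0.35
  corr["BSAL", "SSAL"] <- corr["SSAL", "BSAL"] <- 0.5
  corr["BSAL", "depth"] <- corr["depth", "BSAL"] <- 0.3
  list(
    vars = vars,
    means = c(BT = 9, SST = 14, BSAL = 33.5, SSAL = 32.5, depth = 120),
    sds = c(BT = 3.5, SST = 5, BSAL = 1.2, SSAL = 1.5, depth = 70),
    corr = corr,
    factorName = "subregion",
    levels = c("GoM", "SNE"),
    proportions = c(0.5, 0.5),
    levelShifts = rbind(GoM = c(BT = -1.5, SST = -2, BSAL = 0.3, SSAL = 0.4, depth = 30),
                        SNE = c(BT = 1.5, SST = 2, BSAL = -0.3, SSAL = -0.4, depth = -30)),
    bbox = list(GoM = c(lonMin = -70.8, lonMax = -66.0, latMin = 42.0, latMax = 44.5),
                SNE = c(lonMin = -74.0, lonMax = -69.5, latMin = 39.0, latMax = 41.8)),
    years = 1998:2020)
}

#' Generate a synthetic covariate table
#'
#' @param n number of tows.
#' @param structure list as returned by
#'   \code{\link{defaultCovariateStructure}}: covariate means, sds, a
#'   positive-definite correlation matrix, factor proportions, per-level
#'   covariate mean shifts, coordinate boxes, and survey years.
#' @param seed integer seed.
#' @param season \code{"fall"} or \code{"spring"} label stamped on all rows.
#' @return data.frame with towId, lon, lat, year, season, stratum, the
#'   continuous covariates, and the subregion factor.
#' @export
generateCovariates <- function(n, structure = defaultCovariateStructure(),
                               seed = 1L, season = "fall") {
  st <- structure
  if (!.isSymmetricPD(st$corr))
    stop("declared covariate correlation matrix is not positive definite")
  set.seed(.deriveSeed(seed, 10L))
  lev <- st$levels
  g <- sample(lev, n, replace = TRUE, prob = st$proportions)
  Sig <- diag(st$sds[st$vars]) %*% st$corr %*% diag(st$sds[st$vars])
  Z <- MASS::mvrnorm(n, mu = rep(0, length(st$vars)), Sigma = Sig)
  colnames(Z) <- st$vars
  X <- sweep(Z, 2, st$means[st$vars], "+")
  for (l in lev) {
    rows <- g == l
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                       st$levelShifts[l, st$vars], "+")
  }
  X[, "depth"] <- pmax(X[, "depth"], 5)
  lon <- lat <- numeric(n)
  for (l in lev) {
    rows <- which(g == l)
    bb <- st$bbox[[l]]
    lon[rows] <- runif(length(rows), bb["lonMin"], bb["lonMax"])
    lat[rows] <- runif(length(rows), bb["latMin"], bb["latMax"])
  }
  data.frame(towId = sprintf("tow%05d", seq_len(n)),
             lon = lon, lat = lat,
             year = sample(st$years, n, replace = TRUE),
             season = season,
             stratum = paste0("str", 1 + (seq_len(n) - 1) %% 40),
             as.data.frame(X),
             subregion = g,
             stringsAsFactors = FALSE)
}

#' Construct a generating truth
#'
#' @param spec the generating \linkS4class{JsdmModelSpec}.
#' @param B true Q x S coefficient matrix (rows in design-column order).
#' @param Sigma true S x S positive-definite residual covariance.
#' @param covariateStructure covariate-generation settings.
#' @param seed integer seed.
#' @return a \linkS4class{JsdmTruth}
#' @export
jsdmTruth <- function(spec, B, Sigma,
                      covariateStructure = defaultCovariateStructure(),
                      seed = 1L) {
  new("JsdmTruth", spec = spec, B = B, Sigma = Sigma,
      covariateStructure = covariateStructure, seed = as.integer(seed))
}

setMethod("show", "JsdmTruth", function(object) {
  cat("JsdmTruth: Q = ", nrow(object@B), ", S = ", ncol(object@B),
      ", seed ", object@seed, "\n", sep = "")
})

#' Generate a synthetic community from a known truth
#'
#' Latent rows are drawn \eqn{w_i \sim MVN(B'x_i, \Sigma)} and censored to
#' the observation scale. Species ending up with no nonzero observation are
#' redrawn (whole community, fresh noise) up to 100 attempts, since such
#' columns carry no information and the fitter rejects them.
#'
#' @param truth a \linkS4class{JsdmTruth}.
#' @param covariates data.frame from \code{\link{generateCovariates}}.
#' @param seed integer seed.
#' @param species optional species names (default sp01..spS).
#' @return list: \code{survey} (a \linkS4class{SurveyExperiment}), \code{y}
#'   (n x S observed matrix), \code{W} (the generating latent matrix),
#'   \code{design} (the \linkS4class{JsdmDesign} used).
#' @export
generateCommunity <- function(truth, covariates, seed = 1L, species = NULL) {
  design <- buildDesign(covariates, truth@spec)
  X <- designMatrix(design)
  if (ncol(X) != nrow(truth@B))
    stop("truth B has ", nrow(truth@B), " rows but the design has ",
         ncol(X), " columns")
  S <- ncol(truth@B)
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(S))
  Mu <- X %*% truth@B
  kind <- truth@spec@responseKind
  for (attempt in seq_len(100)) {
    set.seed(.deriveSeed(seed, 20L + attempt))
    W <- Mu + .rmvnRows(nrow(X), truth@Sigma)
    y <- censorToObserved(W, kind)
    if (all(colSums(y != 0) > 0)) break
    if (attempt == 100) stop("degenerate all-zero species after 100 redraws")
  }
  dimnames(y) <- list(covariates$towId, species)
  dimnames(W) <- dimnames(y)
  se <- surveyExperiment(y, covariates,
                         assayName = if (kind == "CA") "cpue" else "pa")
  list(survey = se, y = y, W = W, design = design)
}

#' Default shelf-scale synthetic scenario
#'
#' A survey of 5,217 tows by 30 species under the final-model mean
#' structure (intercept + BT + depth + BSAL + SST + subregion + depth:BT +
#' depth:BSAL + depth:SST; Q = 9). Species form two clusters with
#' opposite-sign temperature responses (cold-water versus warm-water
#' groups), the residual correlation is block structured (within-cluster
#' 0.4, between -0.15), intercepts spread zero inflation over species, and
#' one rare species has about 10 percent nonzero rows.
#'
#' @param seed integer seed.
#' @param n number of tows (default 5,217).
#' @param S number of species (default 30).
#' @return list: \code{truth}, plus the elements of
#'   \code{\link{generateCommunity}} (\code{survey}, \code{y}, \code{W},
#'   \code{design}, and \code{covariates}).
#' @export
defaultNeusScenario <- function(seed = 1L, n = 5217L, S = 30L) {
  spec <- jsdmModelSpec(
    continuous = c("BT", "depth", "BSAL", "SST"),
    factors = list(subregion = c("GoM", "SNE")),
    interactions = list(c("depth", "BT"), c("depth", "BSAL"), c("depth", "SST")),
    response = "CA")
  set.seed(.deriveSeed(seed, 30L))
  half <- S %/% 2
  cold <- seq_len(half); warm <- (half + 1):S
  B <- matrix(0, 9, S,
              dimnames = list(c("(Intercept)", "BT", "depth", "BSAL", "SST",
                                "subregionSNE", "depth:BT", "depth:BSAL",
                                "depth:SST"), NULL))
  B["(Intercept)", ] <- runif(S, 0.2, 1.2)
  B["BT", cold] <- runif(half, -0.8, -0.3)
  B["BT", warm] <- runif(S - half, 0.3, 0.8)
  B["SST", cold] <- runif(half, -0.6, -0.2)
  B["SST", warm] <- runif(S - half, 0.2, 0.6)
  B["depth", cold] <- runif(half, 0.2, 0.7)
  B["depth", warm] <- runif(S - half, -0.7, -0.2)
  B["BSAL", ] <- runif(S, -0.3, 0.3)
  B["subregionSNE", cold] <- runif(half, -0.8, -0.2)
  B["subregionSNE", warm] <- runif(S - half, 0.2, 0.8)
  B["depth:BT", warm] <- runif(S - half, 0.2, 0.5)
  B["depth:BT", cold] <- runif(half, -0.3, 0.1)
  B["depth:BSAL", ] <- runif(S, -0.2, 0.2)
  B["depth:SST", ] <- runif(S, -0.2, 0.2)
  # a rare, weakly informed species: about 10% nonzero tows
  rare <- S
  B[, rare] <- 0.1 * B[, rare]
  B["(Intercept)", rare] <- qnorm(0.10)
  Rtrue <- matrix(-0.15, S, S)
  Rtrue[cold, cold] <- 0.4
  Rtrue[warm, warm] <- 0.4
  diag(Rtrue) <- 1
  ev <- eigen(Rtrue, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) Rtrue <- Rtrue + diag(abs(min(ev)) + 0.01, S)
  sdS <- runif(S, 0.7, 1.4)
  sdS[rare] <- 1
  Sigma <- diag(sdS) %*% cov2cor(Rtrue) %*% diag(sdS)
  truth <- jsdmTruth(spec, B, .symmetrize(Sigma), seed = seed)
  covs <- generateCovariates(n, seed = seed)
  out <- generateCommunity(truth, covs, seed = seed)
  c(list(truth = truth, covariates = covs,
         clusters = list(cold = cold, warm = warm)), out)
}
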