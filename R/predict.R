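# Marginal and conditional prediction on the observation scale.

.checkPredictionDesign <- function(fit, newDesign) {
  if (is(newDesign, "JsdmDesign")) {
    trained <- standardizationParams(fit@design)
    if (length(trained)) {
      got <- standardizationParams(newDesign)
      for (v in names(trained)) {
        if (is.null(got[[v]]) ||
            max(abs(got[[v]] - trained[[v]])) > 1e-10)
          stop("standardization mismatch for covariate '", v,
               "'; build the prediction design with the training ",
               "standardization parameters")
      }
    }
    designMatrix(newDesign)
  } else {
    as.matrix(newDesign)
  }
}

#' Posterior predictive distribution on the observation scale
#'
#' For each retained draw (optionally subsampled) a latent matrix is drawn
#' from MVN(B'x, Sigma) and censored to the observation scale; pooled means
#' and central 90/95 percent intervals are reported. CA means are
#' nonnegative; PA means are occurrence probabilities in [0, 1].
#'
#' @param fit a \linkS4class{JsdmFit}
#' @param newDesign a \linkS4class{JsdmDesign} built with the training
#'   standardization parameters (checked), or a bare matrix. Defaults to the
#'   training design (in-sample prediction).
#' @param nDrawsUse number of posterior draws to propagate (default up to
#'   500, evenly spaced).
#' @param seed integer seed.
#' @param keepDraws also return the ntilde x S x nDrawsUse predictive array.
#' @return list with \code{mean}, \code{lower90}, \code{upper90},
#'   \code{lower95}, \code{upper95} (ntilde x S matrices) and optionally
#'   \code{draws}.
#' @export
predictJsdm <- function(fit, newDesign = NULL, nDrawsUse = NULL, seed = 1L,
                        keepDraws = FALSE) {
  X <- if (is.null(newDesign)) designMatrix(fit@design)
       else .checkPredictionDesign(fit, newDesign)
  M <- nDraws(fit)
  if (is.null(nDrawsUse)) nDrawsUse <- min(500L, M)
  use <- unique(.roundHalfUp(seq(1, M, length.out = nDrawsUse)))
  n <- nrow(X); S <- dim(fit@Bdraws)[2]
  set.seed(.deriveSeed(seed, 2L))
  draws <- array(NA_real_, c(n, S, length(use)))
  for (j in seq_along(use)) {
    m <- use[j]
    Wt <- X %*% .Bat(fit, m) + .rmvnRows(n, .Sat(fit, m))
    draws[, , j] <- censorToObserved(Wt, fit@kind)
  }
  out <- .summarizePredictive(draws, colnames(fit@y))
  if (keepDraws) out$draws <- draws
  out
}

.summarizePredictive <- function(draws, species) {
  qfun <- function(p) apply(draws, c(1, 2), quantile, probs = p)
  out <- list(mean = apply(draws, c(1, 2), mean),
              lower90 = qfun(0.05), upper90 = qfun(0.95),
              lower95 = qfun(0.025), upper95 = qfun(0.975))
  for (nm in names(out)) colnames(out[[nm]]) <- species
  out
}

#' Conditional moments under the multivariate normal partition
#'
#' Given latent values for a conditioned block C, the targets T follow
#' \eqn{MVN(\mu_T + \Sigma_{TC}\Sigma_{CC}^{-1}(w_C - \mu_C),
#' \Sigma_{TT} - \Sigma_{TC}\Sigma_{CC}^{-1}\Sigma_{CT})}.
#'
#' @param mu length-S mean vector (or n x S matrix of row means).
#' @param Sigma S x S covariance.
#' @param condIdx integer indices of the conditioned block.
#' @param condValues latent values for the conditioned block (vector, or
#'   n x |C| matrix matching \code{mu}).
#' @return list with \code{mean} (targets) and \code{cov}
#'   (|T| x |T| conditional covariance).
#' @export
conditionalMoments <- function(mu, Sigma, condIdx, condValues) {
  S <- ncol(Sigma)
  ti <- setdiff(seq_len(S), condIdx)
  mu <- if (is.matrix(mu)) mu else matrix(mu, 1)
  condValues <- if (is.matrix(condValues)) condValues else matrix(condValues, 1)
  SCC <- Sigma[condIdx, condIdx, drop = FALSE]
  STC <- Sigma[ti, condIdx, drop = FALSE]
  K <- STC %*% solve(SCC)
  m <- mu[, ti, drop = FALSE] +
    (condValues - mu[, condIdx, drop = FALSE]) %*% t(K)
  V <- .symmetrize(Sigma[ti, ti, drop = FALSE] - K %*% t(STC))
  list(mean = m, cov = V)
}

#' Conditional prediction of target species given others
#'
#' Uses the multivariate-normal partition of the latent vector: per draw the
#' conditioned species' latent values are fixed at the observed CPUE when
#' positive and sampled from the censored region otherwise (always sampled
#' for PA), then targets are drawn from the conditional
#' \eqn{MVN(\mu_T + \Sigma_{TC}\Sigma_{CC}^{-1}(w_C - \mu_C),
#' \Sigma_{TT} - \Sigma_{TC}\Sigma_{CC}^{-1}\Sigma_{CT})} and censored to
#' the observation scale. With nothing conditioned on this reduces exactly
#' to \code{\link{predictJsdm}} (same seed path).
#'
#' @param fit a \linkS4class{JsdmFit}
#' @param newDesign prediction design (see \code{\link{predictJsdm}}).
#' @param conditioned named list or ntilde-row matrix/data.frame of observed
#'   values for the conditioning species (names must be fitted species);
#'   scalars are recycled over rows.
#' @param targets character vector of species to predict; defaults to all
#'   non-conditioned species.
#' @param nDrawsUse,seed as in \code{\link{predictJsdm}}.
#' @param sweeps Gibbs sweeps used to draw censored conditioned latents.
#' @param keepDraws also return the predictive array.
#' @return list of summary matrices over the target species.
#' @export
conditionalPredict <- function(fit, newDesign = NULL, conditioned = list(),
                               targets = NULL, nDrawsUse = NULL, seed = 1L,
                               sweeps = 5L, keepDraws = FALSE) {
  species <- colnames(fit@y)
  if (length(conditioned) == 0) {
    out <- predictJsdm(fit, newDesign, nDrawsUse, seed, keepDraws)
    if (!is.null(targets)) {
      unknown <- setdiff(targets, species)
      if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
      out <- lapply(out, function(m)
        if (length(dim(m)) == 2) m[, targets, drop = FALSE] else m)
    }
    return(out)
  }
  condNames <- names(conditioned)
  unknown <- setdiff(condNames, species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (is.null(targets)) targets <- setdiff(species, condNames)
  unknown <- setdiff(targets, species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (length(intersect(targets, condNames)))
    stop("conditioned and target species must be disjoint")

  X <- if (is.null(newDesign)) designMatrix(fit@design)
       else .checkPredictionDesign(fit, newDesign)
  n <- nrow(X)
  yC <- sapply(condNames, function(s) rep_len(as.numeric(conditioned[[s]]), n))
  yC <- matrix(yC, nrow = n, dimnames = list(NULL, condNames))
  if (fit@kind == "CA" && any(yC < 0)) stop("conditioned CPUE must be nonnegative")

  ci <- match(condNames, species)
  ti <- match(targets, species)
  M <- nDraws(fit)
  if (is.null(nDrawsUse)) nDrawsUse <- min(500L, M)
  use <- unique(.roundHalfUp(seq(1, M, length.out = nDrawsUse)))
  set.seed(.deriveSeed(seed, 3L))

  draws <- array(NA_real_, c(n, length(ti), length(use)))
  for (j in seq_along(use)) {
    m <- use[j]
    B <- .Bat(fit, m); Sigma <- .Sat(fit, m)
    Mu <- X %*% B
    SCC <- Sigma[ci, ci, drop = FALSE]
    # latent values for the conditioned block
    wC <- sampleLatent(yC, X, B[, ci, drop = FALSE], SCC, kind = fit@kind,
                       sweeps = sweeps)
    ord <- c(ci, ti)
    cm <- conditionalMoments(Mu[, ord, drop = FALSE],
                             Sigma[ord, ord, drop = FALSE],
                             seq_along(ci), wC)
    condMu <- cm$mean
    condSig <- cm$cov
    ev <- eigen(condSig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12) condSig <- condSig + diag(1e-10, nrow(condSig))
    Wt <- condMu + .rmvnRows(n, condSig)
    draws[, , j] <- censorToObserved(Wt, fit@kind)
  }
  out <- .summarizePredictive(draws, targets)
  if (keepDraws) out$draws <- draws
  out
}
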