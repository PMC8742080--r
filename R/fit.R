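# The Gibbs sampler tying the three conditional updates together.

#' Fit a joint species distribution model by Gibbs sampling
#'
#' Cycles latent draws, the matrix-normal coefficient update, and the
#' inverse-Wishart covariance update. For presence/absence fits each stored
#' draw is identified by parameter expansion: Sigma is rescaled to a
#' correlation matrix and the columns of B divided by the corresponding
#' residual standard deviations.
#'
#' Default chain lengths are 20,000 iterations with 8,000 burn-in, the
#' settings used for a final fit; shorter chains (5,000/800 or 1,000/400)
#' are appropriate for variable-selection stages.
#'
#' @param y n x S response matrix (CPUE in kg/tow for CA, 0/1 for PA).
#'   Species with no nonzero observation carry no information about their
#'   coefficients or covariances and are rejected; see
#'   \code{\link{filterSpecies}}.
#' @param design a \linkS4class{JsdmDesign} (or plain numeric matrix).
#' @param kind response kind; defaults to the spec's when a design is given.
#' @param nIter total Gibbs iterations.
#' @param burnin iterations discarded before storage.
#' @param thin store every \code{thin}-th post-burn-in draw.
#' @param seed integer run seed; per-iteration randomness is drawn from the
#'   stream this seed initializes, so identical inputs reproduce identical
#'   draws.
#' @param nu0,Psi0 inverse-Wishart prior; defaults S + 2 and the identity
#'   (proper, weak, conjugate).
#' @param latentSnapshots how many retained latent matrices to keep for
#'   censoring-invariant checks (spread evenly over retained draws).
#' @param verbose print the running complete-data log-likelihood every 500
#'   iterations.
#' @return a \linkS4class{JsdmFit}
#' @export
fitJsdm <- function(y, design, kind = NULL, nIter = 20000L, burnin = 8000L,
                    thin = 1L, seed = 1L, nu0 = NULL, Psi0 = NULL,
                    latentSnapshots = 5L, verbose = FALSE) {
  if (is(design, "JsdmDesign")) {
    X <- designMatrix(design)
    if (is.null(kind)) kind <- design@spec@responseKind
  } else {
    X <- as.matrix(design)
    design <- .bareDesign(X)
    if (is.null(kind)) stop("kind must be given when design is a bare matrix")
  }
  kind <- match.arg(kind, c("CA", "PA"))
  y <- as.matrix(y)
  n <- nrow(y); S <- ncol(y); Q <- ncol(X)
  if (nrow(X) != n) stop("response and design disagree on n")
  if (!(nIter > burnin) || burnin < 0) stop("need nIter > burnin >= 0")
  if (kind == "CA" && any(y < 0)) stop("CA responses must be nonnegative")
  if (kind == "PA" && !all(y %in% c(0, 1))) stop("PA responses must be 0/1")
  zeroSpp <- colSums(y != 0) == 0
  if (any(zeroSpp))
    stop("all-zero species column(s): ",
         paste(colnames(y)[zeroSpp], collapse = ", "),
         "; remove them first (see filterSpecies)")
  if (is.null(nu0)) nu0 <- S + 2
  if (is.null(Psi0)) Psi0 <- diag(S)
  if (is.null(colnames(y))) colnames(y) <- paste0("sp", seq_len(S))

  XtX <- crossprod(X)
  qrX <- qr(X)
  if (qrX$rank < Q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):Q]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nu0 + n <= S + 1 || n <= S)
    stop("too few observations (n = ", n, ") relative to S = ", S,
         " species for a proper posterior")
  Ux <- chol(XtX)

  set.seed(.deriveSeed(seed, 1L))
  W <- .initLatent(y, kind)
  Sigma <- diag(S)
  B <- backsolve(Ux, forwardsolve(t(Ux), crossprod(X, W)))

  nStore <- (nIter - burnin) %/% thin
  Bdraws <- array(NA_real_, c(Q, S, nStore),
                  dimnames = list(colnames(X), colnames(y), NULL))
  SigmaDraws <- array(NA_real_, c(S, S, nStore),
                      dimnames = list(colnames(y), colnames(y), NULL))
  deviance <- numeric(nStore)
  meanW <- matrix(0, n, S)
  snapAt <- if (latentSnapshots > 0 && nStore > 0)
    unique(pmax(1L, .roundHalfUp(seq(1, nStore, length.out = min(latentSnapshots, nStore)))))
  else integer(0)
  snaps <- list()

  stored <- 0L
  for (it in seq_len(nIter)) {
    Mu <- X %*% B
    W <- .latentSweeps(W, y, Mu, .condParams(Sigma), kind, sweeps = 1L)
    B <- .drawB(W, X, Ux, Sigma)
    Sigma <- .drawSigma(W, X %*% B, nu0, Psi0)
    if (!all(is.finite(B)) || !all(is.finite(Sigma)))
      stop("divergent chain: non-finite state at iteration ", it)
    if (verbose && it %% 500 == 0)
      message("iter ", it, " logLik ",
              signif(.mvnLogLikRows(W, X %*% B, Sigma), 8))
    if (it > burnin && (it - burnin) %% thin == 0L) {
      stored <- stored + 1L
      if (kind == "PA") {
        d <- sqrt(diag(Sigma))
        Bs <- sweep(B, 2, d, "/")
        Ss <- .symmetrize(cov2cor(Sigma))
        Bdraws[, , stored] <- Bs
        SigmaDraws[, , stored] <- Ss
      } else {
        Bdraws[, , stored] <- B
        SigmaDraws[, , stored] <- Sigma
      }
      deviance[stored] <- -2 * .mvnLogLikRows(W, X %*% B, Sigma)
      meanW <- meanW + W
      if (stored %in% snapAt) snaps[[length(snaps) + 1L]] <- W
    }
  }
  meanW <- meanW / max(stored, 1L)

  fit <- new("JsdmFit", kind = kind, Bdraws = Bdraws, SigmaDraws = SigmaDraws,
             deviance = deviance, meanW = meanW, WSnapshots = snaps,
             y = y, design = design, nIter = as.integer(nIter),
             burnin = as.integer(burnin), thin = as.integer(thin),
             seed = as.integer(seed), nu0 = nu0, Psi0 = Psi0,
             summaries = data.frame())
  fit@summaries <- .summarizeFit(fit)
  fit
}

.bareDesign <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  spec <- new("JsdmModelSpec", responseKind = "CA",
              terms = list(.termIntercept()), standardize = FALSE)
  new("JsdmDesign", values = X, columnTerms = rep(1L, ncol(X)),
      standardization = list(), spec = spec, data = data.frame())
}

.summarizeFit <- function(fit, level = 0.95) {
  B <- fit@Bdraws
  Q <- dim(B)[1]; S <- dim(B)[2]
  a <- (1 - level) / 2
  out <- expand.grid(term = dimnames(B)[[1]], species = dimnames(B)[[2]],
                     stringsAsFactors = FALSE)
  flat <- matrix(B, Q * S, dim(B)[3])
  out$mean <- rowMeans(flat)
  out$sd <- apply(flat, 1, sd)
  qs <- apply(flat, 1, quantile, probs = c(a, 1 - a))
  out$q2.5 <- qs[1, ]; out$q97.5 <- qs[2, ]
  out$significant <- out$q2.5 > 0 | out$q97.5 < 0
  out$ess <- apply(flat, 1, .essChain)
  out
}

#' Number of retained posterior draws
#' @param fit a \linkS4class{JsdmFit}
#' @export
nDraws <- function(fit) dim(fit@Bdraws)[3]

#' Coefficient draws accessor
#' @param fit a \linkS4class{JsdmFit}
#' @return Q x S x M array
#' @export
coefficientDraws <- function(fit) fit@Bdraws

#' Residual covariance draws accessor
#' @param fit a \linkS4class{JsdmFit}
#' @return S x S x M array (correlation matrices for PA fits)
#' @export
covarianceDraws <- function(fit) fit@SigmaDraws

#' Posterior means of B and Sigma
#' @param fit a \linkS4class{JsdmFit}
#' @return list with elements \code{B} and \code{Sigma}
#' @export
posteriorMeans <- function(fit) {
  list(B = apply(fit@Bdraws, c(1, 2), mean),
       Sigma = .symmetrize(apply(fit@SigmaDraws, c(1, 2), mean)))
}

#' Per-coefficient posterior summary table
#' @param fit a \linkS4class{JsdmFit}
#' @return data.frame: term, species, mean, sd, 95\% interval, significance
#'   flag (interval excludes zero), effective sample size
#' @export
fitSummaries <- function(fit) fit@summaries

setMethod("show", "JsdmFit", function(object) {
  d <- dim(object@Bdraws)
  cat("JsdmFit (", object@kind, "): ", nrow(object@y), " obs x ", d[2],
      " species, Q = ", d[1], "\n", sep = "")
  cat("  ", object@nIter, " iterations, burn-in ", object@burnin,
      ", ", d[3], " retained draws (thin ", object@thin, ")\n", sep = "")
  cat("  seed ", object@seed, "; mean deviance ",
      signif(mean(object@deviance), 8), "\n", sep = "")
})

#' Deviance information criterion of a fitted model
#'
#' Complete-data (conditional) DIC for the latent-variable model:
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\bar\theta)}, where
#' the deviance is minus twice the multivariate-normal log-likelihood of the
#' latent matrix, averaged over retained (W, B, Sigma) draws, and
#' \eqn{D(\bar\theta)} evaluates it at their posterior means.
#'
#' @param fit a \linkS4class{JsdmFit}
#' @return list with \code{DIC}, \code{meanDeviance}, \code{pD}
#' @export
dic <- function(fit) {
  if (nDraws(fit) < 50)
    stop("too few retained draws (", nDraws(fit), " < 50) for a stable DIC")
  pm <- posteriorMeans(fit)
  X <- designMatrix(fit@design)
  Dbar <- mean(fit@deviance)
  Dhat <- -2 * .mvnLogLikRows(fit@meanW, X %*% pm$B, pm$Sigma)
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, meanDeviance = Dbar, pD = pD)
}

# Slice draw m without losing matrix shape when Q = 1 or S = 1.
.Bat <- function(fit, m) {
  d <- dim(fit@Bdraws)
  matrix(fit@Bdraws[, , m], d[1], d[2], dimnames = dimnames(fit@Bdraws)[1:2])
}
.Sat <- function(fit, m) {
  d <- dim(fit@SigmaDraws)
  matrix(fit@SigmaDraws[, , m], d[1], d[2],
         dimnames = dimnames(fit@SigmaDraws)[1:2])
}
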