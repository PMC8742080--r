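# Gibbs updates for the censored latent multivariate Gaussian model.
#
# The latent row w_i follows MVN(B'x_i, Sigma) restricted by the censoring
# indicators: for continuous abundance (CA) entries with y > 0 the latent is
# observed exactly (w = y) and entries with y = 0 lie in (-Inf, 0]; for
# presence/absence (PA) every entry is latent, with w > 0 iff y = 1.

# Per-species conditional regression parameters given the other species.
.condParams <- function(Sigma) {
  S <- ncol(Sigma)
  k <- vector("list", S); v <- numeric(S)
  for (s in seq_len(S)) {
    if (S == 1) {
      k[[s]] <- numeric(0); v[s] <- Sigma[1, 1]
    } else {
      ks <- solve(Sigma[-s, -s, drop = FALSE], Sigma[-s, s])
      k[[s]] <- ks
      v[s] <- Sigma[s, s] - sum(Sigma[s, -s] * ks)
    }
  }
  list(k = k, var = pmax(v, 1e-12))
}

#' Draw the censored latent matrix given coefficients and covariance
#'
#' One systematic-scan Gibbs sweep over species in fixed column order: for
#' each species the censored entries are drawn from their univariate
#' conditional normal given all other species in the same row, truncated to
#' the region fixed by the observation. CA entries with y > 0 are held at y.
#'
#' @param y n x S observed response matrix.
#' @param X n x Q design matrix (numeric matrix or \linkS4class{JsdmDesign}).
#' @param B Q x S coefficient matrix.
#' @param Sigma S x S residual covariance (positive definite).
#' @param kind \code{"CA"} or \code{"PA"}.
#' @param W optional current latent matrix to update; defaults to the
#'   feasible initialization (y for positive CA entries, -0.5 for censored
#'   CA entries, +/-0.5 by label for PA).
#' @param sweeps number of full sweeps over species.
#' @param seed optional integer seed for reproducible draws.
#' @return n x S latent matrix satisfying the censoring constraints.
#' @export
sampleLatent <- function(y, X, B, Sigma, kind = c("CA", "PA"), W = NULL,
                         sweeps = 1L, seed = NULL) {
  kind <- match.arg(kind)
  if (is(X, "JsdmDesign")) X <- designMatrix(X)
  if (!.isSymmetricPD(Sigma))
    stop("Sigma is not symmetric positive definite")
  .setSeed(seed)
  Mu <- X %*% B
  if (is.null(W)) W <- .initLatent(y, kind)
  W <- .latentSweeps(W, y, Mu, .condParams(Sigma), kind, sweeps)
  dimnames(W) <- dimnames(y)
  W
}

# Hot path shared by sampleLatent and the fit loop: no validation, reuses a
# precomputed conditional-parameter list.
.latentSweeps <- function(W, y, Mu, cp, kind, sweeps = 1L) {
  S <- ncol(y)
  sdv <- sqrt(cp$var)
  for (sw in seq_len(sweeps)) {
    for (s in seq_len(S)) {
      if (kind == "CA") {
        idx <- which(y[, s] == 0)
        if (!length(idx)) next
        m <- Mu[idx, s]
        if (S > 1)
          m <- m + (W[idx, -s, drop = FALSE] - Mu[idx, -s, drop = FALSE]) %*% cp$k[[s]]
        W[idx, s] <- .rtruncUpper(length(idx), as.numeric(m), sdv[s], 0)
      } else {
        m <- Mu[, s]
        if (S > 1)
          m <- m + (W[, -s, drop = FALSE] - Mu[, -s, drop = FALSE]) %*% cp$k[[s]]
        m <- as.numeric(m)
        pos <- y[, s] == 1
        if (any(pos))
          W[pos, s] <- .rtruncLower(sum(pos), m[pos], sdv[s], 0)
        if (any(!pos))
          W[!pos, s] <- .rtruncUpper(sum(!pos), m[!pos], sdv[s], 0)
      }
    }
  }
  W
}

# Matrix-normal coefficient draw given precomputed chol(X'X).
.drawB <- function(W, X, Ux, Sigma) {
  Q <- ncol(X); S <- ncol(W)
  M <- backsolve(Ux, forwardsolve(t(Ux), crossprod(X, W)))
  Us <- chol(Sigma)
  M + backsolve(Ux, matrix(rnorm(Q * S), Q, S)) %*% Us
}

# Inverse-Wishart covariance draw without re-validating inputs.
.drawSigma <- function(W, XB, nu0, Psi0) {
  R <- W - XB
  scale <- .symmetrize(Psi0 + crossprod(R))
  Wd <- rWishart(1, nu0 + nrow(W), chol2inv(chol(scale)))[, , 1]
  .symmetrize(chol2inv(chol(Wd)))
}

.initLatent <- function(y, kind) {
  if (kind == "CA") {
    W <- y
    W[y == 0] <- -0.5
  } else {
    W <- matrix(-0.5, nrow(y), ncol(y))
    W[y == 1] <- 0.5
  }
  dimnames(W) <- dimnames(y)
  W
}

#' Draw the coefficient matrix from its matrix-normal full conditional
#'
#' Under the flat prior on B the full conditional given the latent matrix is
#' matrix normal with mean (X'X)^{-1} X'W, row covariance (X'X)^{-1} and
#' column covariance Sigma.
#'
#' @param W n x S latent matrix.
#' @param X n x Q design matrix (or \linkS4class{JsdmDesign}).
#' @param Sigma S x S residual covariance.
#' @param seed optional integer seed.
#' @return one Q x S draw.
#' @export
sampleCoefficients <- function(W, X, Sigma, seed = NULL) {
  if (is(X, "JsdmDesign")) X <- designMatrix(X)
  .setSeed(seed)
  Q <- ncol(X); S <- ncol(W)
  XtX <- crossprod(X)
  qrX <- qr(X)
  if (qrX$rank < Q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):Q]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (!.isSymmetricPD(Sigma)) stop("Sigma is not symmetric positive definite")
  M <- solve(XtX, crossprod(X, W))
  Ux <- chol(XtX)               # Ux'Ux = X'X
  Us <- chol(Sigma)             # Us'Us = Sigma
  Z <- matrix(rnorm(Q * S), Q, S)
  B <- M + backsolve(Ux, Z) %*% Us
  dimnames(B) <- list(colnames(X), colnames(W))
  B
}

#' Draw the residual covariance from its inverse-Wishart full conditional
#'
#' With prior Sigma ~ IW(nu0, Psi0) the full conditional given latent
#' residuals is IW(nu0 + n, Psi0 + (W - XB)'(W - XB)).
#'
#' @param W n x S latent matrix.
#' @param X n x Q design matrix (or \linkS4class{JsdmDesign}).
#' @param B Q x S coefficient matrix.
#' @param nu0 prior degrees of freedom (default S + 2: proper and weak).
#' @param Psi0 prior scale matrix (default identity).
#' @param seed optional integer seed.
#' @return one symmetric positive-definite S x S draw.
#' @export
sampleCovariance <- function(W, X, B, nu0 = ncol(W) + 2, Psi0 = diag(ncol(W)),
                             seed = NULL) {
  if (is(X, "JsdmDesign")) X <- designMatrix(X)
  .setSeed(seed)
  n <- nrow(W); S <- ncol(W)
  if (nu0 + n <= S + 1)
    stop("too few observations (n = ", n, ") for a proper inverse-Wishart ",
         "posterior with S = ", S, " species")
  R <- W - X %*% B
  scale <- .symmetrize(Psi0 + crossprod(R))
  df <- nu0 + n
  Wdraw <- rWishart(1, df, solve(scale))[, , 1]
  Sigma <- .symmetrize(solve(Wdraw))
  dimnames(Sigma) <- list(colnames(W), colnames(W))
  Sigma
}
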