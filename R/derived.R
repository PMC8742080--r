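# Matrices derived from the fitted parameters: R, f, E, V, variance partition.

#' Residual correlation matrix from a covariance
#'
#' \eqn{R_{ss'} = \Sigma_{ss'} / \sqrt{\Sigma_{ss}\Sigma_{s's'}}}.
#'
#' @param Sigma symmetric positive-definite covariance matrix.
#' @return correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(Sigma) {
  d <- diag(Sigma)
  if (any(d <= 0)) stop("zero or negative diagonal entry in Sigma")
  if (!.isSymmetricPD(Sigma)) stop("Sigma is not symmetric positive definite")
  R <- .symmetrize(cov2cor(Sigma))
  diag(R) <- 1
  R
}

#' Posterior mean residual correlation of a fit
#' @param fit a \linkS4class{JsdmFit}
#' @return S x S matrix, the mean over per-draw correlation matrices
#' @export
residualCorrelation <- function(fit) {
  M <- nDraws(fit)
  acc <- 0
  for (m in seq_len(M)) acc <- acc + correlationMatrix(.Sat(fit, m))
  acc / M
}

#' Whole-community sensitivity to each predictor
#'
#' \eqn{f = \mathrm{diag}(B \Sigma^{-1} B')}: the length-Q vector measuring
#' how strongly each design column drives the full response matrix, with
#' species weighted by the inverse residual covariance. Entries are
#' nonnegative because each is a quadratic form in a positive-definite
#' matrix.
#'
#' @param B Q x S coefficient matrix.
#' @param Sigma S x S positive-definite residual covariance.
#' @return named nonnegative vector of length Q.
#' @export
sensitivity <- function(B, Sigma) {
  if (ncol(B) != ncol(Sigma)) stop("dimension mismatch between B and Sigma")
  if (!.isSymmetricPD(Sigma)) stop("Sigma is not symmetric positive definite")
  U <- chol(Sigma)
  Z <- backsolve(U, t(B), transpose = TRUE)   # U' Z = B' => Z = U'^{-1} B'
  f <- colSums(Z^2)
  names(f) <- rownames(B)
  pmax(f, 0)
}

#' Posterior draws of the sensitivity vector
#' @param fit a \linkS4class{JsdmFit}
#' @return Q x M matrix, one sensitivity vector per retained draw
#' @export
sensitivityDraws <- function(fit) {
  M <- nDraws(fit)
  out <- vapply(seq_len(M), function(m)
    sensitivity(.Bat(fit, m), .Sat(fit, m)),
    numeric(dim(fit@Bdraws)[1]))
  rownames(out) <- dimnames(fit@Bdraws)[[1]]
  out
}

#' Environmental covariance between species
#'
#' \eqn{E = B'VB}: similarity of species induced by shared responses to the
#' environment, weighted by how much the predictors vary. Species with
#' identical columns of B get identical rows and columns of E; predictors
#' with zero variance contribute nothing.
#'
#' @param B Q x S coefficient matrix.
#' @param V Q x Q symmetric positive semi-definite predictor covariance.
#' @return symmetric S x S matrix.
#' @export
environmentalCovariance <- function(B, V) {
  if (nrow(B) != nrow(V) || nrow(V) != ncol(V))
    stop("dimension mismatch between B and V")
  .symmetrize(t(B) %*% V %*% B)
}

#' Predictor covariance from an observed design
#'
#' Sample covariance of the design columns with the intercept row and column
#' zeroed (the intercept does not vary).
#'
#' @param design a \linkS4class{JsdmDesign} or numeric matrix whose first
#'   column is the intercept.
#' @return Q x Q symmetric positive semi-definite matrix.
#' @export
predictorCovariance <- function(design) {
  X <- if (is(design, "JsdmDesign")) designMatrix(design) else as.matrix(design)
  if (nrow(X) < 2) stop("need at least 2 rows")
  V <- cov(X)
  V[1, ] <- 0
  V[, 1] <- 0
  .symmetrize(V)
}

#' Partition response variance into mean-structure and residual parts
#'
#' Per retained draw and species s, the total is the variance over
#' observations of the fitted mean mu_is plus the residual variance
#' Sigma_ss; the reported fraction is the mean-structure share. Posterior
#' means over draws are returned.
#'
#' @param fit a \linkS4class{JsdmFit}
#' @return data.frame: species, totalVariance, fractionFromMean
#' @export
variancePartition <- function(fit) {
  X <- designMatrix(fit@design)
  M <- nDraws(fit)
  S <- dim(fit@Bdraws)[2]
  tot <- frac <- matrix(0, S, M)
  for (m in seq_len(M)) {
    Mu <- X %*% .Bat(fit, m)
    v <- apply(Mu, 2, var)
    t_ <- v + diag(.Sat(fit, m))
    tot[, m] <- t_
    frac[, m] <- v / t_
  }
  data.frame(species = dimnames(fit@Bdraws)[[2]],
             totalVariance = rowMeans(tot),
             fractionFromMean = rowMeans(frac))
}

#' Significance flags from credible intervals
#'
#' A coefficient is flagged significant when its central credible interval
#' excludes zero.
#'
#' @param fit a \linkS4class{JsdmFit}
#' @param level credible level, default 0.95.
#' @return data.frame: term, species, lo, hi, significant
#' @export
significanceTable <- function(fit, level = 0.95) {
  B <- fit@Bdraws
  a <- (1 - level) / 2
  flat <- matrix(B, prod(dim(B)[1:2]), dim(B)[3])
  qs <- apply(flat, 1, quantile, probs = c(a, 1 - a))
  out <- expand.grid(term = dimnames(B)[[1]], species = dimnames(B)[[2]],
                     stringsAsFactors = FALSE)
  out$lo <- qs[1, ]; out$hi <- qs[2, ]
  out$significant <- out$lo > 0 | out$hi < 0
  out
}

#' Elementwise difference of absolute residual correlations
#'
#' \code{|R_pa| - |R_cpue|}, used to see where the presence/absence and
#' abundance models disagree about residual co-dependence.
#'
#' @param Rpa,Rcpue correlation matrices over the same species in the same
#'   order.
#' @return symmetric matrix with zero diagonal, entries in [-1, 1].
#' @export
absCorrelationDifference <- function(Rpa, Rcpue) {
  if (!identical(dim(Rpa), dim(Rcpue)))
    stop("species mismatch: correlation matrices differ in dimension")
  if (!is.null(rownames(Rpa)) && !is.null(rownames(Rcpue)) &&
      !identical(rownames(Rpa), rownames(Rcpue)))
    stop("species mismatch: correlation matrices differ in species order")
  D <- abs(Rpa) - abs(Rcpue)
  diag(D) <- 0
  .symmetrize(D)
}
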