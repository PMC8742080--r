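# internal helpers shared across modules

# Deterministically derive a sub-stream seed from a run seed. Kept below
# 2^31 - 1 so it is always a valid integer seed.
.deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 65011) * 33029 + 101 * (offset %% 9973) + 17) %% 2147483629L
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# Half-up rounding: round(0.5) in base R is banker's rounding, which would
# split 5,935 tows 4154/1781 instead of the intended 4155/1780.
.roundHalfUp <- function(x) floor(x + 0.5)

# One-sided truncated normal draws by inverse CDF, evaluated in log space so
# the quantile stays finite when the untruncated mass in the allowed region
# is tiny (mean many sd away from the bound).
.rtruncUpper <- function(n, mean, sd, upper = 0) {
  lp <- pnorm(upper, mean = mean, sd = sd, log.p = TRUE)
  u <- runif(n)
  z <- qnorm(log(u) + lp, log.p = TRUE)
  out <- mean + sd * z
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- upper[if (length(upper) > 1) bad else 1] - 1e-8
  pmin(out, upper)
}

.rtruncLower <- function(n, mean, sd, lower = 0) {
  lp <- pnorm(lower, mean = mean, sd = sd, lower.tail = FALSE, log.p = TRUE)
  u <- runif(n)
  z <- qnorm(log(u) + lp, log.p = TRUE)
  out <- mean - sd * z
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- lower[if (length(lower) > 1) bad else 1] + 1e-8
  pmax(out, lower + .Machine$double.xmin)
}

.isSymmetricPD <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > tol * max(abs(ev), 1)
}

.symmetrize <- function(M) (M + t(M)) / 2

# Multivariate normal rows: Z %*% chol(Sigma) has row covariance Sigma.
.rmvnRows <- function(n, Sigma) {
  S <- ncol(Sigma)
  U <- chol(Sigma)
  matrix(rnorm(n * S), n, S) %*% U
}

# Log-density of n MVN rows with per-row means, common covariance.
.mvnLogLikRows <- function(W, Mu, Sigma) {
  n <- nrow(W); S <- ncol(W)
  U <- chol(Sigma)
  Z <- forwardsolve(t(U), t(W - Mu))
  logdet <- 2 * sum(log(diag(U)))
  -0.5 * (n * S * log(2 * pi) + n * logdet + sum(Z^2))
}

# Effective sample size from the initial positive sequence of autocorrelations.
.essChain <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}
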