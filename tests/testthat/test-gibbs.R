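# The three conditional updates against independent oracles.

test_that("latent draws respect the censoring regions", {
  sim <- smallCommunity(n = 100, S = 4)
  X <- designMatrix(sim$design)
  W <- sampleLatent(sim$y, X, sim$B, sim$Sigma, "CA", seed = 5)
  pos <- sim$y > 0
  expect_identical(W[pos], sim$y[pos])     # uncensored entries fixed at y
  expect_true(all(W[!pos] <= 0))           # censored entries in (-Inf, 0]
  # PA: sign of latent matches the label
  yPA <- censorToObserved(sim$W, "PA")
  Wpa <- sampleLatent(yPA, X, sim$B, sim$Sigma, "PA", seed = 6, sweeps = 3)
  expect_true(all(Wpa[yPA == 1] > 0))
  expect_true(all(Wpa[yPA == 0] <= 0))
  expect_error(sampleLatent(sim$y, X, sim$B, diag(c(1, -1, 1, 1)), "CA"),
               "positive definite")
})

test_that("censored conditional matches a rejection-sampling oracle", {
  # bivariate Sigma = [[1, .8], [.8, 1]], mu = 0, y = (2, 0): w2 | w1 = 2
  # is N(1.6, 0.36) truncated to (-Inf, 0]
  Sigma <- matrix(c(1, 0.8, 0.8, 1), 2)
  n <- 10000
  y <- cbind(rep(2, n), rep(0, n))
  X <- matrix(1, n, 1)
  B <- matrix(0, 1, 2)
  W <- sampleLatent(y, X, B, Sigma, "CA", seed = 42)
  # rejection-sampling oracle for the truncated mean
  set.seed(99)
  z <- rnorm(2e5, 1.6, 0.6)
  z <- z[z <= 0]
  mOracle <- mean(z)
  se <- sd(z) / sqrt(length(z)) + sd(W[, 2]) / sqrt(n)
  expect_lt(abs(mean(W[, 2]) - mOracle), 3 * se)
})

test_that("coefficient draws center on the least-squares solution", {
  set.seed(31)
  n <- 80; Q <- 3; S <- 4
  X <- cbind(1, matrix(rnorm(n * (Q - 1)), n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  W <- matrix(rnorm(n * S), n, S)
  Sigma <- diag(S) * 0.5
  # orthonormal X, Sigma = I: conditional mean equals X'W
  Xo <- qr.Q(qr(matrix(rnorm(n * Q), n)))
  draws <- sapply(1:2000, function(i) sampleCoefficients(W, Xo, diag(S)))
  m <- matrix(rowMeans(draws), Q, S)
  expect_lt(max(abs(m - crossprod(Xo, W))), 3 * sqrt(1 / 2000) * 4)
  # general X: mean matches the OLS oracle within 3 MC standard errors
  ols <- qr.solve(X, W)
  draws <- array(sapply(1:5000, function(i) sampleCoefficients(W, X, Sigma)),
                 c(Q, S, 5000))
  m <- apply(draws, c(1, 2), mean)
  mcse <- apply(draws, c(1, 2), sd) / sqrt(5000)
  expect_true(all(abs(m - ols) < 3.5 * mcse + 1e-10))
  # seeded draws are bit-identical
  expect_identical(sampleCoefficients(W, X, Sigma, seed = 7),
                   sampleCoefficients(W, X, Sigma, seed = 7))
  # rank deficiency names the collinear column
  Xbad <- cbind(X, dup = X[, 2])
  expect_error(sampleCoefficients(W, Xbad, Sigma), "collinear")
})

test_that("covariance draws match the analytic inverse-Wishart mean", {
  set.seed(17)
  n <- 40; S <- 3
  X <- matrix(1, n, 1)
  B <- matrix(0, 1, S)
  W <- matrix(0, n, S)      # residuals identically zero
  nu0 <- S + 2
  draws <- array(sapply(1:5000, function(i)
    sampleCovariance(W, X, B, nu0 = nu0, Psi0 = diag(S))), c(S, S, 5000))
  m <- apply(draws, c(1, 2), mean)
  # IW mean: Psi / (nu - S - 1) with Psi = I, nu = nu0 + n
  analytic <- diag(S) / (nu0 + n - S - 1)
  mcse <- apply(draws, c(1, 2), sd) / sqrt(5000)
  expect_true(all(abs(m - analytic) < 3.5 * mcse + 1e-12))
  # every draw is PD (Cholesky succeeds)
  ok <- apply(draws[, , 1:200], 3, function(s) !inherits(try(chol(s), silent = TRUE), "try-error"))
  expect_true(all(ok))
  # n too small for a proper posterior
  expect_error(sampleCovariance(matrix(0, 1, 5), matrix(1, 1, 1),
                                matrix(0, 1, 5), nu0 = 0), "too few")
})

test_that("covariance draws recover a known residual covariance", {
  set.seed(23)
  S <- 4; n <- 10000
  A <- matrix(rnorm(S * S), S); SigStar <- crossprod(A) / S + diag(S) * 0.5
  R <- MASS::mvrnorm(n, rep(0, S), SigStar)
  X <- matrix(1, n, 1); B <- matrix(0, 1, S)
  draws <- array(sapply(1:200, function(i) sampleCovariance(R, X, B)),
                 c(S, S, 200))
  m <- apply(draws, c(1, 2), mean)
  relErr <- norm(m - SigStar, "F") / norm(SigStar, "F")
  expect_lt(relErr, 0.05)
})
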