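# Predictive distribution and conditional prediction closed forms.

test_that("predictive summaries live on the observation scale", {
  sim <- smallCommunity(n = 150, S = 4)
  fit <- quickFit(sim)
  pr <- predictJsdm(fit, nDrawsUse = 60, seed = 2)
  expect_true(all(pr$mean >= 0))
  expect_true(all(pr$lower90 <= pr$upper90))
  yPA <- censorToObserved(sim$W, "PA")
  fitPA <- fitJsdm(yPA, sim$design, kind = "PA", nIter = 300, burnin = 100,
                   seed = 3)
  prPA <- predictJsdm(fitPA, nDrawsUse = 60, seed = 2)
  expect_true(all(prPA$mean >= 0 & prPA$mean <= 1))
})

test_that("B = 0 predictive mean matches the half-normal closed form", {
  # with mu = 0 and unit variance the censored mean is E[max(Z,0)] = 1/sqrt(2*pi)
  S <- 3; Q <- 2; M <- 200; n <- 400
  B <- array(0, c(Q, S, M), dimnames = list(c("(Intercept)", "x"),
                                            paste0("sp", 1:S), NULL))
  Sg <- array(diag(S), c(S, S, M))
  fit <- new("JsdmFit", kind = "CA", Bdraws = B, SigmaDraws = Sg,
             deviance = numeric(M), meanW = matrix(0, 1, S),
             WSnapshots = list(),
             y = matrix(1, 1, S, dimnames = list(NULL, paste0("sp", 1:S))),
             design = jsdmTobit:::.bareDesign(matrix(1, 1, Q)),
             nIter = 10L, burnin = 0L, thin = 1L, seed = 1L,
             nu0 = S + 2, Psi0 = diag(S), summaries = data.frame())
  Xnew <- cbind(rep(1, n), rnorm(n))
  pr <- predictJsdm(fit, Xnew, nDrawsUse = M, seed = 4)
  m <- mean(pr$mean)
  se <- sd(pr$mean) / sqrt(length(pr$mean))
  expect_lt(abs(m - 1 / sqrt(2 * pi)), 3 * se + 0.01)
})

test_that("in-sample predictions explain strong-signal synthetic data", {
  # every species gets slopes of magnitude >= 0.8 so the mean structure
  # dominates the unit residual variance
  set.seed(56)
  S <- 5
  spec <- smallSpec()
  B <- rbind(1, runif(S, 0.8, 1.4) * sign(rnorm(S)),
             runif(S, 0.8, 1.4) * sign(rnorm(S)),
             runif(S, -0.5, 0.5), runif(S, -0.5, 0.5))
  Sigma <- (diag(S) * 0.7 + 0.3) * 0.3   # residual sd ~ 0.55 per species
  covs <- smallCovariates(400, seed = 57)
  sim <- generateCommunity(jsdmTruth(spec, B, Sigma), covs, seed = 58)
  fit <- fitJsdm(sim$y, sim$design, nIter = 600, burnin = 200, seed = 5)
  pr <- predictJsdm(fit, nDrawsUse = 100, seed = 6)
  zeroFrac <- colMeans(sim$y == 0)
  common <- which(zeroFrac < 0.5)
  expect_gt(length(common), 0)
  r2 <- vapply(common, function(s) rSquared(pr$mean[, s], sim$y[, s]), 1)
  expect_true(all(r2 > 0.5))
})

test_that("conditional prediction matches bivariate MVN conditioning", {
  rho <- 0.6; c0 <- 2
  S <- 2; Q <- 1; M <- 400; n <- 2000
  Sg <- array(matrix(c(1, rho, rho, 1), 2), c(S, S, M),
              dimnames = list(c("a", "b"), c("a", "b"), NULL))
  B <- array(0, c(Q, S, M), dimnames = list("(Intercept)", c("a", "b"), NULL))
  fit <- new("JsdmFit", kind = "CA", Bdraws = B, SigmaDraws = Sg,
             deviance = numeric(M), meanW = matrix(0, 1, S),
             WSnapshots = list(),
             y = matrix(1, 1, S, dimnames = list(NULL, c("a", "b"))),
             design = jsdmTobit:::.bareDesign(matrix(1, 1, 1)),
             nIter = 10L, burnin = 0L, thin = 1L, seed = 1L,
             nu0 = S + 2, Psi0 = diag(S), summaries = data.frame())
  Xnew <- matrix(1, n, 1)
  cp <- conditionalPredict(fit, Xnew, conditioned = list(a = c0),
                           targets = "b", nDrawsUse = M, seed = 9,
                           keepDraws = TRUE)
  # closed form: latent b | a = c0 is N(rho*c0, 1 - rho^2); the observed
  # value is that normal censored at zero
  mu <- rho * c0; s <- sqrt(1 - rho^2)
  censoredMean <- mu * pnorm(mu / s) + s * dnorm(mu / s)
  got <- mean(cp$draws)
  expect_lt(abs(got - censoredMean), 0.02)
  # latent-scale check through a diagonal-covariance control: conditional
  # equals marginal when the residual covariance is diagonal
  Sg0 <- array(diag(2), c(S, S, M), dimnames = dimnames(Sg))
  fit0 <- fit; fit0@SigmaDraws <- Sg0
  cp0 <- conditionalPredict(fit0, Xnew, conditioned = list(a = 5),
                            targets = "b", nDrawsUse = 100, seed = 11)
  pr0 <- conditionalPredict(fit0, Xnew, conditioned = list(a = 0),
                            targets = "b", nDrawsUse = 100, seed = 11)
  expect_equal(mean(cp0$mean), mean(pr0$mean), tolerance = 0.03)
})

test_that("empty conditioning reduces to marginal prediction", {
  sim <- smallCommunity(n = 100, S = 3)
  fit <- quickFit(sim)
  a <- conditionalPredict(fit, conditioned = list(), nDrawsUse = 40, seed = 8)
  b <- predictJsdm(fit, nDrawsUse = 40, seed = 8)
  expect_identical(a$mean, b$mean)
  expect_error(conditionalPredict(fit, conditioned = list(nosuch = 1)),
               "unknown species")
  expect_error(conditionalPredict(fit, conditioned = list(sp01 = 1),
                                  targets = "sp01"), "disjoint")
})
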