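# Inverse prediction: closed-form agreement, symmetry, and scores.

# Build a deterministic single-draw fit object so the optimizer can be
# compared to the GLS closed form without Monte Carlo noise.
singleDrawFit <- function(B, Sigma, y, design) {
  Q <- nrow(B); S <- ncol(B); M <- 2
  Bd <- array(B, c(Q, S, M),
              dimnames = list(colnames(designMatrix(design)), colnames(y), NULL))
  Sd <- array(Sigma, c(S, S, M),
              dimnames = list(colnames(y), colnames(y), NULL))
  new("JsdmFit", kind = "CA", Bdraws = Bd, SigmaDraws = Sd,
      deviance = numeric(M), meanW = y, WSnapshots = list(), y = y,
      design = design, nIter = 10L, burnin = 0L, thin = 1L, seed = 1L,
      nu0 = S + 2, Psi0 = diag(S), summaries = data.frame())
}

test_that("the numeric optimizer matches the GLS closed form", {
  # no interactions, single free covariate: the MVN likelihood in x is
  # quadratic and maximized at (b Sigma^-1 b')^-1 b Sigma^-1 (w - mu_rest)
  set.seed(3)
  n <- 12; S <- 4
  covs <- data.frame(BT = rnorm(n, 10, 3), depth = rnorm(n, 100, 40))
  spec <- jsdmModelSpec(continuous = c("BT", "depth"))
  design <- buildDesign(covs, spec)
  B <- rbind(1, rnorm(S, 0, 0.8), rnorm(S, 0, 0.8))
  A <- matrix(rnorm(S * S), S); Sigma <- crossprod(A) / S + diag(S) * 0.5
  # strictly positive responses: latent rows equal y exactly
  y <- matrix(abs(MASS::mvrnorm(n, rep(3, S), Sigma)) + 0.5, n, S)
  colnames(y) <- paste0("sp", 1:S)
  fit <- singleDrawFit(B, Sigma, y, design)
  inv <- invertContinuous(fit, "BT", nDrawsUse = 2, seed = 1)
  X <- designMatrix(design)
  SigInv <- solve(Sigma)
  b <- B[2, ]     # row for BT
  p <- standardizationParams(design)$BT
  for (i in seq_len(n)) {
    muRest <- as.numeric(crossprod(B[-2, , drop = FALSE], X[i, -2]))
    xhat <- sum(b * (SigInv %*% (y[i, ] - muRest))) /
      as.numeric(t(b) %*% SigInv %*% b)
    got <- (inv$BT$estimate[i] - p["mean"]) / p["sd"]
    expect_lt(abs(got - xhat), 1e-6)
  }
})

test_that("an uninformative coefficient row gives no inverse signal", {
  set.seed(9)
  n <- 25; S <- 4
  covs <- data.frame(BT = rnorm(n, 10, 3), depth = rnorm(n, 100, 40))
  spec <- jsdmModelSpec(continuous = c("BT", "depth"))
  design <- buildDesign(covs, spec)
  B <- rbind(1, 0, rnorm(S, 0, 0.8))      # BT row all zeros
  Sigma <- diag(S)
  y <- matrix(abs(MASS::mvrnorm(n, rep(3, S), Sigma)) + 0.5, n, S)
  colnames(y) <- paste0("sp", 1:S)
  fit <- singleDrawFit(B, Sigma, y, design)
  inv <- invertContinuous(fit, "BT", nDrawsUse = 2, seed = 1)
  sc <- inversePredictionScores(inv, list(), covs)
  expect_lt(sc$score[1], 0.2)
  expect_error(invertContinuous(fit, "SSAL"), "not continuous main effects")
})

test_that("strong community signal recovers the covariate", {
  sim <- smallCommunity(n = 250, S = 12, bsd = 1.0, intercept = 1.5, seed = 77)
  fit <- fitJsdm(sim$y, sim$design, nIter = 500, burnin = 200, seed = 3)
  rows <- 1:120
  inv <- invertContinuous(fit, "BT", rows = rows, nDrawsUse = 15, seed = 2)
  sc <- inversePredictionScores(inv, list(), sim$covariates)
  expect_gt(sc$score[sc$covariate == "BT"], 0.8)
  # intervals contain their point estimate
  expect_true(all(inv$BT$lo90 <= inv$BT$estimate + 1e-9))
  expect_true(all(inv$BT$hi90 >= inv$BT$estimate - 1e-9))
})

test_that("factor inversion is symmetric, normalized, and accurate", {
  # identical B columns across levels: probabilities are uniform
  set.seed(4)
  n <- 10; S <- 3
  covs <- data.frame(BT = rnorm(n, 10, 2),
                     subregion = rep(c("GoM", "SNE"), length.out = n))
  spec <- jsdmModelSpec(continuous = "BT",
                        factors = list(subregion = c("GoM", "SNE")))
  design <- buildDesign(covs, spec)
  B <- rbind(1, 0.5, 0)    # zero dummy row: levels indistinguishable
  B <- matrix(rep(B, S), 3, S)
  y <- matrix(abs(MASS::mvrnorm(n, rep(3, S), diag(S))) + 0.5, n, S)
  colnames(y) <- paste0("sp", 1:S)
  fit <- singleDrawFit(B, diag(S), y, design)
  fi <- invertFactor(fit, "subregion", nDrawsUse = 2, seed = 1)
  expect_true(all(abs(fi$probabilities - 0.5) < 1e-10))
  expect_true(all(abs(rowSums(fi$probabilities) - 1) < 1e-12))
  # well-separated subregions classify accurately
  sim <- smallCommunity(n = 250, S = 10, bsd = 0.4, seed = 91)
  # strengthen the factor signal
  simB <- sim$B; simB[4, ] <- simB[4, ] + rep(c(-1.5, 1.5), length.out = 10)
  truth <- jsdmTruth(sim$spec, simB, sim$Sigma, seed = 1)
  sim2 <- generateCommunity(truth, sim$covariates, seed = 5)
  fit <- fitJsdm(sim2$y, sim2$design, nIter = 400, burnin = 150, seed = 3)
  fi <- invertFactor(fit, "subregion", rows = 1:100, nDrawsUse = 10, seed = 2)
  acc <- mean(fi$predicted == sim$covariates$subregion[1:100])
  expect_gt(acc, 0.9)
})

test_that("inverse-prediction scores behave at their extremes", {
  d <- data.frame(BT = 1:10)
  inv <- list(BT = data.frame(row = 1:10, estimate = 1:10,
                              lo90 = 1:10 - 1, hi90 = 1:10 + 1))
  class(inv) <- c("jsdmInversion", "list")
  expect_equal(inversePredictionScores(inv, list(), d)$score, 1)
  invC <- list(BT = data.frame(row = 1:10, estimate = rep(5.5, 10),
                               lo90 = rep(0, 10), hi90 = rep(11, 10)))
  class(invC) <- c("jsdmInversion", "list")
  expect_lte(inversePredictionScores(invC, list(), d)$score, 0)
  # random two-level guesses hover near one half
  set.seed(12)
  n <- 2000
  dd <- data.frame(g = sample(c("a", "b"), n, TRUE))
  fi <- list(g = list(predicted = sample(c("a", "b"), n, TRUE), rows = 1:n))
  acc <- inversePredictionScores(NULL, fi, dd)$score
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
})
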