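# Small in-code fixtures shared across tests.

# A compact covariate table with the default structure.
smallCovariates <- function(n = 300, seed = 11) {
  generateCovariates(n, seed = seed)
}

# A simple spec: two continuous covariates, the subregion factor, one
# interaction.
smallSpec <- function(response = "CA") {
  jsdmModelSpec(continuous = c("BT", "depth"),
                factors = list(subregion = c("GoM", "SNE")),
                interactions = list(c("depth", "BT")),
                response = response)
}

# Community simulated from known truth on the small spec (Q = 5).
smallCommunity <- function(n = 300, S = 5, seed = 21, response = "CA",
                           intercept = 0.5, bsd = 0.5, rho = 0.3) {
  spec <- smallSpec(response)
  set.seed(seed)
  B <- matrix(rnorm(5 * S, 0, bsd), 5, S)
  B[1, ] <- intercept
  Sigma <- matrix(rho, S, S); diag(Sigma) <- 1
  truth <- jsdmTruth(spec, B, Sigma, seed = seed)
  covs <- smallCovariates(n, seed = seed + 1)
  sim <- generateCommunity(truth, covs, seed = seed + 2)
  c(sim, list(truth = truth, covariates = covs, B = B, Sigma = Sigma,
              spec = spec))
}

# Quick fit with short chains for structural tests.
quickFit <- function(sim, nIter = 400, burnin = 150, seed = 7, ...) {
  fitJsdm(sim$y, sim$design, nIter = nIter, burnin = burnin, seed = seed, ...)
}

expect_symmetric <- function(M, tol = 1e-8) {
  expect_lt(max(abs(M - t(M))), tol)
}
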