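# Evaluation metrics against brute-force oracles.

test_that("rmspe and rSquared follow their formulas", {
  expect_equal(rmspe(1:5, 1:5), 0)
  expect_equal(rmspe(c(2, 0), c(1, 1)), 1)
  p <- c(1.2, 0.4, 3.3, 2.0, 5.1); o <- c(1, 1, 3, 2, 4)
  expect_equal(rmspe(p, o), sqrt(mean((p - o)^2)))
  expect_error(rmspe(numeric(0), numeric(0)), "empty")
  expect_equal(rSquared(o, o), 1)
  expect_equal(rSquared(rep(mean(o), 5), o), 0)
  worse <- o + c(3, -3, 3, -3, 3)
  expect_equal(rSquared(worse, o), 1 - sum((worse - o)^2) / sum((o - mean(o))^2))
  expect_lt(rSquared(worse, o), 0)
  expect_error(rSquared(1:3, c(2, 2, 2)), "constant")
})

test_that("AUC equals all-pairs counting with ties at one half", {
  aucOracle <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2); l <- c(1, 0, 1, 1, 0, 0)
  expect_equal(auc(s, l), aucOracle(s, l))
  set.seed(2)
  for (i in 1:10) {
    s <- round(runif(20), 1); l <- rbinom(20, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), aucOracle(s, l))
  }
  # independent scores approach one half
  set.seed(3)
  s <- runif(20000); l <- rbinom(20000, 1, 0.3)
  expect_lt(abs(auc(s, l) - 0.5), 0.02)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("mean precision equals threshold enumeration", {
  precOracle <- function(s, l, step = 0.01) {
    vals <- c()
    for (t in seq(0, 1, by = step)) {
      sel <- s >= t
      if (!any(sel)) next
      vals <- c(vals, sum(l[sel] == 1) / sum(sel))
    }
    mean(vals)
  }
  # scores identical to the 0/1 labels: precision = prevalence at
  # thresholds <= 0 boundary, 1 at the rest of the grid
  l <- c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0)
  prev <- mean(l)
  expect_equal(meanPrecision(l, l), (prev + 100) / 101)
  expect_equal(meanPrecision(rep(0.7, 4), rep(1, 4)), 1)
  s <- c(0.95, 0.4, 0.62, 0.05, 0.8); l2 <- c(1, 0, 1, 0, 0)
  expect_equal(meanPrecision(s, l2), precOracle(s, l2))
  set.seed(5)
  for (i in 1:10) {
    s <- runif(15); l3 <- rbinom(15, 1, 0.4)
    if (sum(l3) == 0) next
    expect_equal(meanPrecision(s, l3), precOracle(s, l3))
  }
  expect_error(meanPrecision(runif(5), rep(0, 5)), "no positive")
})

test_that("k-means aggregation preserves weighted grand means", {
  set.seed(7)
  n <- 120
  X <- cbind(1, matrix(rnorm(n * 3), n))
  pred <- matrix(rnorm(n * 2), n); obs <- matrix(rnorm(n * 2), n)
  agg <- aggregateByKmeans(pred, obs, X, k = 8, seed = 2)
  expect_equal(sum(agg$size), n)
  gm <- colSums(agg$pred * agg$size) / n
  expect_lt(max(abs(gm - colMeans(pred))), 1e-10)
  gmo <- colSums(agg$obs * agg$size) / n
  expect_lt(max(abs(gmo - colMeans(obs))), 1e-10)
  # k = 1: single global mean row
  a1 <- aggregateByKmeans(pred, obs, X, k = 1, seed = 2)
  expect_equal(nrow(a1$pred), 1)
  expect_equal(as.numeric(a1$pred), colMeans(pred))
  # k = n: identity aggregation up to row order
  an <- aggregateByKmeans(pred, obs, X, k = n, seed = 2)
  expect_equal(dim(an$pred), dim(pred))
  expect_equal(sort(an$pred[, 1]), sort(pred[, 1]))
  expect_error(aggregateByKmeans(pred, obs, X, k = n + 1), "at most n")
})

test_that("the metrics report pools per-species results", {
  set.seed(11)
  obs <- matrix(rpois(60, 2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  pred <- obs + matrix(rnorm(60, 0, 0.5), 20, 3)
  rep_ <- metricsReport(pred, obs, "CA")
  expect_equal(rep_$perSpecies$rmspe[1], rmspe(pred[, 1], obs[, 1]))
  expect_equal(unname(rep_$pooled["rmspe"]), mean(rep_$perSpecies$rmspe))
  labs <- matrix(rbinom(60, 1, 0.5), 20, 3)
  scores <- labs * 0.6 + matrix(runif(60) * 0.4, 20, 3)
  repPA <- metricsReport(scores, labs, "PA")
  expect_true(all(repPA$perSpecies$auc >= 0 & repPA$perSpecies$auc <= 1,
                  na.rm = TRUE))
})
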