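# Model-grid enumeration, splits, DIC, and the two selection workflows'
# structural behavior (selection power is exercised at scale in the
# acceptance suite).

gridTemplate <- function() {
  jsdmModelSpec(
    continuous = c("BT", "BSAL", "SST", "SSAL", "chla", "depth", "SEDSIZE"),
    factors = list(subregion = c("GoM", "SNE"),
                   position = c("low", "mid", "high")),
    interactions = list(c("depth", "SEDSIZE"), c("depth", "BT"),
                        c("depth", "BSAL"), c("depth", "SST"),
                        c("depth", "SSAL"), c("depth", "chla")))
}

test_that("grid enumeration counts candidates exactly", {
  tpl <- gridTemplate()
  forced <- c("BT", "BSAL", "SST", "SSAL", "chla", "depth")
  optional <- c("SEDSIZE", "subregion", "position",
                "depth:SEDSIZE", "depth:BT", "depth:BSAL", "depth:SST",
                "depth:SSAL", "depth:chla")
  # 6 forced + 10 optional (4 covariates/factors + 6 depth interactions)
  optional10 <- c(optional, "extra")
  tpl10 <- jsdmModelSpec(
    continuous = c("BT", "BSAL", "SST", "SSAL", "chla", "depth", "SEDSIZE",
                   "extra"),
    factors = list(subregion = c("GoM", "SNE"),
                   position = c("low", "mid", "high")),
    interactions = list(c("depth", "SEDSIZE"), c("depth", "BT"),
                        c("depth", "BSAL"), c("depth", "SST"),
                        c("depth", "SSAL"), c("depth", "chla")))
  g <- enumerateModelGrid(tpl10, forced, optional10)
  expect_length(g$candidates, 1024)
  expect_equal(nrow(unique(g$included)), 1024)
  # every candidate contains the forced terms
  expect_true(all(vapply(g$candidates, function(s)
    all(forced %in% termLabels(s)), logical(1))))
  # 0 optional -> the forced model alone; 2 optional -> explicit listing
  g0 <- enumerateModelGrid(tpl, forced, character())
  expect_length(g0$candidates, 1)
  g2 <- enumerateModelGrid(tpl, forced, c("SEDSIZE", "subregion"))
  expect_length(g2$candidates, 4)
  sets <- lapply(g2$candidates, function(s)
    sort(intersect(termLabels(s), c("SEDSIZE", "subregion"))))
  expect_setequal(vapply(sets, paste, collapse = "+", FUN.VALUE = ""),
                  c("", "SEDSIZE", "subregion", "SEDSIZE+subregion"))
  expect_error(enumerateModelGrid(tpl, forced, c("BT", "SEDSIZE")), "overlap")
})

test_that("train/test splits reproduce the printed survey arithmetic", {
  s1 <- trainTestSplit(5217, 0.7, seed = 1)
  expect_length(s1$train, 3652)
  expect_length(s1$test, 1565)
  s2 <- trainTestSplit(5935, 0.7, seed = 1)
  expect_length(s2$train, 4155)
  expect_length(s2$test, 1780)
  s3 <- trainTestSplit(10, 0.5, seed = 4)
  expect_length(s3$train, 5)
  expect_length(intersect(s3$train, s3$test), 0)
  expect_setequal(c(s3$train, s3$test), 1:10)
  expect_identical(trainTestSplit(100, 0.7, seed = 9),
                   trainTestSplit(100, 0.7, seed = 9))
  expect_error(trainTestSplit(10, 1.2), "fraction")
})

test_that("DIC is stable and penalizes fitted complexity", {
  sim <- smallCommunity(n = 200, S = 4, seed = 61)
  fit <- fitJsdm(sim$y, sim$design, nIter = 700, burnin = 200, seed = 3)
  d <- dic(fit)
  expect_gt(d$pD, 0)
  # doubling retained draws moves DIC by well under 1%
  fit2 <- fitJsdm(sim$y, sim$design, nIter = 1200, burnin = 200, seed = 3)
  expect_lt(abs(dic(fit2)$DIC - d$DIC) / abs(d$DIC), 0.01)
  shortFit <- fitJsdm(sim$y, sim$design, nIter = 240, burnin = 200, seed = 3)
  expect_error(dic(shortFit), "too few retained draws")
})

test_that("grid selection returns a coherent report", {
  sim <- smallCommunity(n = 180, S = 4, bsd = 0.8, seed = 71)
  tpl <- sim$spec
  g <- enumerateModelGrid(tpl, c("BT", "depth"), c("subregion", "depth:BT"))
  sel <- selectByGrid(g, sim$covariates, sim$y, kind = "CA",
                      shortlistSize = 2, nIter = 300, burnin = 100, seed = 5)
  expect_length(g$candidates, 4)
  expect_true(sel$chosen %in% sel$shortlist)
  expect_true(all(sel$shortlist %in% seq_len(4)))
  expect_equal(nrow(sel$report), 4)
  # shortlistSize >= |grid|: the whole grid advances
  sel2 <- selectByGrid(g, sim$covariates, sim$y, kind = "CA",
                       shortlistSize = 10, nIter = 300, burnin = 100, seed = 5)
  expect_length(sel2$shortlist, 4)
})

test_that("the pruning loop drops interactions before main effects", {
  # noise covariate: BT has signal, depth none, depth:BT none
  set.seed(81)
  n <- 300; S <- 6
  covs <- smallCovariates(n, seed = 82)
  spec <- smallSpec()
  B <- matrix(0, 5, S)
  B[1, ] <- 1
  B[2, ] <- rnorm(S, 0, 1)      # BT informative
  B[4, ] <- rep(c(-1, 1), 3)    # subregion informative
  truth <- jsdmTruth(spec, B, diag(S) * 0.6 + 0.4, seed = 1)
  sim <- generateCommunity(truth, covs, seed = 2)
  sel <- selectByInversePrediction(covs, sim$y, spec, nIter = 400,
                                   burnin = 150, maxRounds = 3,
                                   maxRows = 120, invDraws = 8, seed = 3)
  labs <- termLabels(sel$chosenSpec)
  expect_true("BT" %in% labs)
  expect_true("(Intercept)" %in% labs)
  # whenever depth was dropped, depth:BT was dropped no later
  for (r in sel$rounds) {
    dm <- r$dropped[r$term == "depth"]
    di <- r$dropped[r$term == "depth:BT"]
    if (length(dm) && length(dm) == length(di) && dm)
      expect_true(di)   # main effect only leaves together with/after its interaction
  }
  # dropping everything down to the intercept is refused
  expect_error(jsdmTobit:::.dropSpecTerms(spec, "(Intercept)"),
               "intercept")
})
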