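# Variable selection: the exhaustive DIC / out-of-sample grid, and the
# sensitivity + inverse-prediction pruning loop.

#' Enumerate all candidate models over optional terms
#'
#' Every subset of the optional terms is appended to the forced terms,
#' giving exactly 2^|optional| candidate specifications. Candidates are
#' built without hierarchy closure, so an interaction may enter or leave a
#' candidate independently of its parent main effects (as when depth
#' interactions are screened over a fixed set of forced main effects).
#'
#' @param template a \linkS4class{JsdmModelSpec} containing every term
#'   (forced and optional).
#' @param forced character vector of forced term labels (intercept implied).
#' @param optional character vector of optional term labels.
#' @return list with \code{candidates} (list of specs), \code{forced},
#'   \code{optional}, and \code{included} (logical matrix candidates x
#'   optional terms).
#' @export
enumerateModelGrid <- function(template, forced, optional) {
  if (length(intersect(forced, optional)))
    stop("forced and optional terms overlap: ",
         paste(intersect(forced, optional), collapse = ", "))
  labs <- setdiff(termLabels(template), "(Intercept)")
  unknown <- setdiff(c(forced, optional), labs)
  if (length(unknown))
    stop("term(s) not in template: ", paste(unknown, collapse = ", "))
  p <- length(optional)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  if (p == 0) combos <- data.frame(row.names = 1)
  inc <- as.matrix(combos)
  colnames(inc) <- optional
  candidates <- lapply(seq_len(nrow(inc)), function(i)
    .specFromLabels(template, c(forced, optional[inc[i, ]])))
  list(candidates = candidates, forced = forced, optional = optional,
       included = inc)
}

#' Reproducible train/test split
#'
#' The training size is \code{fraction * n} rounded half-up (so a 70 percent
#' split of 5,935 tows is 4,155/1,780 and of 5,217 tows is 3,652/1,565);
#' index sets are disjoint and exhaustive.
#'
#' @param n number of observations.
#' @param fraction training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
trainTestSplit <- function(n, fraction = 0.7, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  nTrain <- .roundHalfUp(fraction * n)
  set.seed(.deriveSeed(seed, 7L))
  train <- sort(sample.int(n, nTrain))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Select a model by the DIC / out-of-sample grid
#'
#' Fits every candidate on the training split with short chains, shortlists
#' the candidates with the lowest in-sample DIC, and picks from the
#' shortlist by pooled out-of-sample R-squared (highest by default; the
#' direction is configurable).
#'
#' @param grid result of \code{\link{enumerateModelGrid}}.
#' @param data covariate data.frame.
#' @param y n x S response matrix aligned with \code{data}.
#' @param kind response kind.
#' @param trainFraction training fraction (default 0.7).
#' @param shortlistSize how many lowest-DIC candidates advance (default 10).
#' @param nIter,burnin chain settings per candidate fit (default 1,000/400,
#'   the grid-stage lengths).
#' @param seed integer seed (split and fits).
#' @param direction \code{"highest"} (default) or \code{"lowest"}
#'   out-of-sample R-squared wins among the shortlist.
#' @return list: \code{report} data.frame (candidate, DIC, outOfSampleR2,
#'   error), \code{shortlist} indices, \code{chosen} index, and
#'   \code{chosenSpec}.
#' @export
selectByGrid <- function(grid, data, y, kind = c("CA", "PA"),
                         trainFraction = 0.7, shortlistSize = 10,
                         nIter = 1000L, burnin = 400L, seed = 1L,
                         direction = c("highest", "lowest")) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (!length(grid$candidates)) stop("empty model grid")
  n <- nrow(y)
  split <- trainTestSplit(n, trainFraction, seed)
  nc <- length(grid$candidates)
  dics <- r2 <- rep(NA_real_, nc)
  errs <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    res <- tryCatch({
      spec <- grid$candidates[[i]]
      dTrain <- buildDesign(data[split$train, , drop = FALSE], spec)
      fit <- fitJsdm(y[split$train, , drop = FALSE], dTrain, kind = kind,
                     nIter = nIter, burnin = burnin,
                     seed = .deriveSeed(seed, 100L + i))
      dTest <- buildDesign(data[split$test, , drop = FALSE], spec,
                           standardization = standardizationParams(dTrain))
      pr <- predictJsdm(fit, dTest, nDrawsUse = min(200L, nDraws(fit)),
                        seed = .deriveSeed(seed, 200L + i))
      # pooled R2 of predictive means; for PA fits the means are occurrence
      # probabilities and R2 against the 0/1 labels plays the same role
      rep_ <- metricsReport(pr$mean, y[split$test, , drop = FALSE], kind = "CA")
      list(dic = dic(fit)$DIC, r2 = unname(rep_$pooled["r2"]))
    }, error = function(e) e)
    if (inherits(res, "error")) errs[i] <- conditionMessage(res)
    else { dics[i] <- res$dic; r2[i] <- res$r2 }
  }
  ok <- which(is.finite(dics))
  shortlist <- ok[order(dics[ok])][seq_len(min(shortlistSize, length(ok)))]
  pick <- if (direction == "highest") which.max(r2[shortlist])
          else which.min(r2[shortlist])
  chosen <- shortlist[pick]
  list(report = data.frame(candidate = seq_len(nc), DIC = dics,
                           outOfSampleR2 = r2, error = errs),
       shortlist = shortlist, chosen = chosen,
       chosenSpec = grid$candidates[[chosen]],
       split = split)
}

# Interaction terms of a spec that involve a given main-effect label.
.interactionsInvolving <- function(spec, label) {
  labs <- termLabels(spec)
  out <- character()
  for (t in spec@terms) if (t$type == "interaction" && (t$a == label || t$b == label))
    out <- c(out, .termLabel(t))
  out
}

#' Select a model by sensitivity and inverse prediction
#'
#' The pruning loop: fit the current model, compute the posterior of the
#' whole-community sensitivity vector and the per-covariate inverse
#' prediction scores, then drop every term that both contributes little
#' sensitivity (posterior median below \code{sensFraction} of the largest
#' term's median) and belongs to a covariate the community cannot predict
#' (inverse R-squared below \code{r2Floor} for continuous covariates;
#' accuracy below chance + \code{accMargin} for factors). Interactions are
#' dropped before their main effects: a main effect is retained while any
#' of its interactions survives. The loop refits and repeats until no term
#' fails or \code{maxRounds} is reached.
#'
#' @param data covariate data.frame.
#' @param y n x S response matrix.
#' @param saturatedSpec the starting \linkS4class{JsdmModelSpec}.
#' @param kind response kind.
#' @param nIter,burnin chain settings per round (default 5,000/800, the
#'   selection-stage lengths).
#' @param sensFraction,r2Floor,accMargin drop-rule thresholds (defaults
#'   0.1, 0.1, 0.05).
#' @param maxRounds maximum fit-prune rounds.
#' @param maxRows cap on rows used for inverse prediction scoring.
#' @param invDraws posterior draws used per inversion.
#' @param seed integer seed.
#' @return list: \code{chosenSpec}, \code{rounds} (per-round data.frames of
#'   term, sensitivity median, inverse score, dropped flag), \code{fits}
#'   (final-round fit).
#' @export
selectByInversePrediction <- function(data, y, saturatedSpec,
                                      kind = c("CA", "PA"),
                                      nIter = 5000L, burnin = 800L,
                                      sensFraction = 0.1, r2Floor = 0.1,
                                      accMargin = 0.05, maxRounds = 5L,
                                      maxRows = 400L, invDraws = 20L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  spec <- saturatedSpec
  rounds <- list()
  fit <- NULL
  for (round in seq_len(maxRounds)) {
    design <- buildDesign(data, spec)
    fit <- fitJsdm(y, design, kind = kind, nIter = nIter, burnin = burnin,
                   seed = .deriveSeed(seed, 300L + round))
    sd_ <- sensitivityDraws(fit)
    colMed <- apply(sd_, 1, median)
    labs <- termLabels(spec)
    # per-term sensitivity: max over the term's design columns
    termSens <- vapply(seq_along(spec@terms), function(i)
      max(colMed[design@columnTerms == i]), numeric(1))
    names(termSens) <- labs
    termSens["(Intercept)"] <- Inf      # never droppable
    topMed <- max(termSens[is.finite(termSens)], 0)

    rows <- seq_len(nrow(y))
    if (length(rows) > maxRows) {
      set.seed(.deriveSeed(seed, 400L + round))
      rows <- sort(sample(rows, maxRows))
    }
    contVars <- unlist(lapply(spec@terms, function(t)
      if (t$type == "continuous") t$var else NULL))
    facVars <- unlist(lapply(spec@terms, function(t)
      if (t$type == "factor") t$var else NULL))
    inv <- if (length(contVars))
      invertContinuous(fit, contVars, rows = rows, nDrawsUse = invDraws,
                       seed = .deriveSeed(seed, 500L + round)) else NULL
    finv <- list()
    for (v in facVars)
      finv[[v]] <- invertFactor(fit, v, rows = rows, nDrawsUse = invDraws,
                                seed = .deriveSeed(seed, 600L + round))
    scores <- inversePredictionScores(inv, finv, data)
    scoreOf <- function(var) {
      s <- scores$score[scores$covariate == var]
      if (length(s)) s[1] else NA_real_
    }
    chanceOf <- function(var) {
      for (t in spec@terms) if (t$type == "factor" && t$var == var)
        return(1 / length(t$levels))
      NA_real_
    }

    poorlyPredicted <- function(t) {
      if (t$type == "continuous") {
        s <- scoreOf(t$var); !is.na(s) && s < r2Floor
      } else if (t$type == "factor") {
        s <- scoreOf(t$var); !is.na(s) && s < chanceOf(t$var) + accMargin
      } else if (t$type == "interaction") {
        # an interaction is prunable when either parent covariate is
        # poorly predicted (factors by accuracy, continuous by R2)
        any(vapply(c(t$a, t$b), function(v) {
          s <- scoreOf(v)
          ch <- chanceOf(v)
          if (!is.na(ch)) !is.na(s) && s < ch + accMargin
          else is.na(s) || s < r2Floor
        }, logical(1)))
      } else FALSE
    }

    fails <- vapply(seq_along(spec@terms), function(i) {
      t <- spec@terms[[i]]
      if (t$type == "intercept") return(FALSE)
      lowSens <- termSens[i] < sensFraction * topMed
      lowSens && poorlyPredicted(t)
    }, logical(1))

    # interactions drop before main effects: keep a failing main effect
    # while any interaction involving it is still in the model
    drop <- character()
    for (i in which(fails)) {
      t <- spec@terms[[i]]
      lab <- labs[i]
      if (t$type %in% c("continuous", "factor")) {
        inter <- .interactionsInvolving(spec, t$var)
        surviving <- setdiff(inter, labs[fails])
        if (length(surviving)) next
        # its failing interactions are dropped in this same round, first
      }
      drop <- c(drop, lab)
    }
    # order: interactions first
    isInter <- vapply(drop, function(l) grepl(":", l, fixed = TRUE), logical(1))
    drop <- c(drop[isInter], drop[!isInter])

    rounds[[round]] <- data.frame(
      term = labs,
      sensitivityMedian = as.numeric(termSens),
      inverseScore = vapply(spec@terms, function(t)
        switch(t$type, continuous = scoreOf(t$var), factor = scoreOf(t$var),
               NA_real_), numeric(1)),
      dropped = labs %in% drop)

    if (!length(drop)) break
    spec <- .dropSpecTerms(spec, drop)
  }
  list(chosenSpec = spec, rounds = rounds, fit = fit)
}
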