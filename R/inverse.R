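# Inverse prediction: predicting the environment from the community.
#
# The fitted model is inverted per posterior draw by maximizing the
# censored-data log-likelihood of the observed response row over the free
# base covariate(s), with interaction columns recomputed as deterministic
# functions of the free covariate. The objective treats positive CPUE
# entries exactly (MVN density on that block) and censored entries through
# their conditional censoring probabilities given the positive block,
# taken independent of one another given the positives. Covariates not
# being inverted stay at their observed values. A covariate the community
# cannot predict gives a flat objective and a near-zero score.

# Column indices of the design affected by a base covariate, with the
# multiplier (partner values) needed to rebuild them from a free value v.
.freeColumnPlan <- function(design, var) {
  spec <- design@spec
  X <- designMatrix(design)
  plan <- list()
  for (i in seq_along(spec@terms)) {
    t <- spec@terms[[i]]
    cols <- which(design@columnTerms == i)
    if (t$type == "continuous" && t$var == var) {
      plan[[length(plan) + 1]] <- list(cols = cols, partner = rep(1, nrow(X)))
    } else if (t$type == "interaction" && (t$a == var || t$b == var)) {
      other <- if (t$a == var) t$b else t$a
      isFac <- any(vapply(spec@terms, function(u)
        u$type == "factor" && u$var == other, logical(1)))
      if (isFac || length(cols) > 1) {
        # covariate x factor: rebuild the dummy block from the stored data
        lev <- NULL
        for (u in spec@terms) if (u$type == "factor" && u$var == other) lev <- u$levels
        f <- as.character(design@data[[other]])
        dm <- sapply(lev[-1], function(l) as.numeric(f == l))
        dm <- matrix(dm, nrow = nrow(X))
        plan[[length(plan) + 1]] <- list(cols = cols, partner = dm)
      } else {
        plan[[length(plan) + 1]] <- list(cols = cols,
                                         partner = .stdValues(design, other))
      }
    }
  }
  plan
}

.stdValues <- function(design, var) {
  p <- design@standardization[[var]]
  (as.numeric(design@data[[var]]) - p["mean"]) / p["sd"]
}

# Replace free covariate value v (standardized) in design row xrow.
.applyFree <- function(xrow, plan, v, i) {
  for (p in plan) {
    part <- p$partner
    if (is.matrix(part)) xrow[p$cols] <- v * part[i, ]
    else xrow[p$cols] <- v * part[i]
  }
  xrow
}

# Censored-row log-likelihood machinery for one (row pattern, Sigma draw):
# positive entries P carry the exact MVN density, censored entries C the
# conditional probability of the censoring region given w_P = y_P
# (independently of one another). For PA rows every entry is censored-type.
.rowLikContext <- function(pos, Sigma) {
  S <- ncol(Sigma)
  P <- which(pos); C <- setdiff(seq_len(S), P)
  ctx <- list(P = P, C = C)
  if (length(P)) {
    UPP <- chol(Sigma[P, P, drop = FALSE])
    ctx$UPP <- UPP
    if (length(C)) {
      K <- t(backsolve(UPP, backsolve(UPP, t(Sigma[C, P, drop = FALSE]),
                                      transpose = TRUE)))
      ctx$K <- K
      ctx$sC <- sqrt(pmax(diag(Sigma)[C] -
                            rowSums(K * Sigma[C, P, drop = FALSE]), 1e-12))
    }
  } else if (length(C)) {
    ctx$sC <- sqrt(diag(Sigma)[C])
  }
  ctx
}

# yrow: observed row; mu: candidate mean vector; signs: for PA, +1 where
# present (w > 0), -1 where absent. CA censored entries always have w <= 0.
.rowLogLik <- function(yrow, mu, ctx, kind) {
  ll <- 0
  P <- ctx$P; C <- ctx$C
  if (length(P)) {
    r <- yrow[P] - mu[P]
    z <- backsolve(ctx$UPP, r, transpose = TRUE)
    ll <- ll - 0.5 * sum(z^2)
    if (length(C)) {
      mC <- mu[C] + as.numeric(ctx$K %*% r)
      ll <- ll + sum(pnorm(0, mC, ctx$sC, log.p = TRUE))
    }
  } else if (length(C)) {
    if (kind == "PA") {
      up <- yrow[C] == 0
      if (any(up))
        ll <- ll + sum(pnorm(0, mu[C][up], ctx$sC[up], log.p = TRUE))
      if (any(!up))
        ll <- ll + sum(pnorm(0, mu[C][!up], ctx$sC[!up], log.p = TRUE,
                             lower.tail = FALSE))
    } else {
      ll <- ll + sum(pnorm(0, mu[C], ctx$sC, log.p = TRUE))
    }
  }
  ll
}

.rowPositives <- function(fit, i) {
  if (fit@kind == "CA") fit@y[i, ] > 0 else rep(FALSE, ncol(fit@y))
}

#' Invert the fitted model for continuous covariates
#'
#' For each observation row and each retained draw (subsampled), the
#' censored-data log-likelihood of the observed response row is maximized
#' over the free covariate on the standardized scale within
#' \code{[-bound, bound]}; any interaction involving the free covariate is
#' recomputed from the trial value, and the other covariates stay at their
#' observed values. Posterior medians and central 90 percent intervals
#' over draws are returned on the original covariate scale.
#'
#' @param fit a \linkS4class{JsdmFit} whose design kept its covariate table.
#' @param freeVars character vector of continuous main-effect covariates to
#'   invert, one at a time.
#' @param rows observation rows to invert (default: all training rows).
#' @param nDrawsUse posterior draws to use (default 30, evenly spaced).
#' @param bound optimization bounds on the standardized scale (default 4,
#'   generously covering the observed data).
#' @param seed kept for interface stability; the objective is deterministic
#'   given the stored draws.
#' @return list with, per free covariate, a data.frame
#'   \code{(row, estimate, lo90, hi90)} on the original scale.
#' @export
invertContinuous <- function(fit, freeVars, rows = NULL, nDrawsUse = 30L,
                             bound = 4, seed = 1L) {
  design <- fit@design
  specVars <- vapply(design@spec@terms, function(t)
    if (t$type == "continuous") t$var else NA_character_, character(1))
  bad <- setdiff(freeVars, specVars[!is.na(specVars)])
  if (length(bad))
    stop("free term(s) not continuous main effects of the fitted model: ",
         paste(bad, collapse = ", "))
  X <- designMatrix(design)
  if (is.null(rows)) rows <- seq_len(nrow(X))
  M <- nDraws(fit)
  use <- unique(.roundHalfUp(seq(1, M, length.out = min(nDrawsUse, M))))

  out <- list()
  for (v in freeVars) {
    plan <- .freeColumnPlan(design, v)
    est <- matrix(NA_real_, length(rows), length(use))
    for (j in seq_along(use)) {
      m <- use[j]
      B <- .Bat(fit, m); Sigma <- .Sat(fit, m)
      ctxCache <- list()
      for (r in seq_along(rows)) {
        i <- rows[r]
        pos <- .rowPositives(fit, i)
        key <- paste(which(pos), collapse = ",")
        if (is.null(ctxCache[[key]]))
          ctxCache[[key]] <- .rowLikContext(pos, Sigma)
        ctx <- ctxCache[[key]]
        xrow <- X[i, ]
        yrow <- fit@y[i, ]
        nll <- function(val) {
          mu <- as.numeric(crossprod(B, .applyFree(xrow, plan, val, i)))
          -.rowLogLik(yrow, mu, ctx, fit@kind)
        }
        est[r, j] <- optimize(nll, c(-bound, bound))$minimum
      }
    }
    p <- design@standardization[[v]]
    back <- function(z) z * p["sd"] + p["mean"]
    out[[v]] <- data.frame(
      row = rows,
      estimate = back(apply(est, 1, median)),
      lo90 = back(apply(est, 1, quantile, 0.05)),
      hi90 = back(apply(est, 1, quantile, 0.95)))
  }
  structure(out, class = c("jsdmInversion", "list"))
}

#' Invert the fitted model for a factor covariate
#'
#' Evaluates the censored-data likelihood of each observation row at every
#' declared level of the factor (other covariates at their observed
#' values), normalizes across levels, and averages the per-level posterior
#' probabilities over draws.
#'
#' @param fit a \linkS4class{JsdmFit}
#' @param factorVar name of a factor term of the fitted model.
#' @param rows,nDrawsUse,seed as in \code{\link{invertContinuous}}.
#' @return list with \code{probabilities} (rows x levels, summing to 1),
#'   \code{predicted} (argmax level per row), and \code{rows}.
#' @export
invertFactor <- function(fit, factorVar, rows = NULL, nDrawsUse = 30L,
                         seed = 1L) {
  design <- fit@design
  spec <- design@spec
  ft <- NULL
  for (t in spec@terms)
    if (t$type == "factor" && t$var == factorVar) ft <- t
  if (is.null(ft)) stop("'", factorVar, "' is not a factor term of the fitted model")
  lev <- ft$levels
  X <- designMatrix(design)
  if (is.null(rows)) rows <- seq_len(nrow(X))
  M <- nDraws(fit)
  use <- unique(.roundHalfUp(seq(1, M, length.out = min(nDrawsUse, M))))

  # design columns carrying the factor: its dummies and its interactions
  affected <- list()
  for (i in seq_along(spec@terms)) {
    t <- spec@terms[[i]]
    cols <- which(design@columnTerms == i)
    if (t$type == "factor" && t$var == factorVar)
      affected[[length(affected) + 1]] <- list(cols = cols, scale = rep(1, nrow(X)))
    if (t$type == "interaction" && (t$b == factorVar || t$a == factorVar)) {
      other <- if (t$b == factorVar) t$a else t$b
      affected[[length(affected) + 1]] <- list(cols = cols,
                                               scale = .stdValues(design, other))
    }
  }

  probs <- matrix(0, length(rows), length(lev), dimnames = list(NULL, lev))
  for (j in seq_along(use)) {
    m <- use[j]
    B <- .Bat(fit, m); Sigma <- .Sat(fit, m)
    ctxCache <- list()
    for (r in seq_along(rows)) {
      i <- rows[r]
      pos <- .rowPositives(fit, i)
      key <- paste(which(pos), collapse = ",")
      if (is.null(ctxCache[[key]]))
        ctxCache[[key]] <- .rowLikContext(pos, Sigma)
      ctx <- ctxCache[[key]]
      yrow <- fit@y[i, ]
      ll <- numeric(length(lev))
      for (l in seq_along(lev)) {
        xr <- X[i, ]
        dums <- as.numeric(lev[-1] == lev[l])
        for (a in affected) xr[a$cols] <- dums * a$scale[i]
        mu <- as.numeric(crossprod(B, xr))
        ll[l] <- .rowLogLik(yrow, mu, ctx, fit@kind)
      }
      ll <- ll - max(ll)
      probs[r, ] <- probs[r, ] + exp(ll) / sum(exp(ll))
    }
  }
  probs <- probs / length(use)
  probs <- probs / rowSums(probs)
  list(probabilities = probs,
       predicted = lev[max.col(probs, ties.method = "first")],
       rows = rows)
}

#' Score inverse predictions against the observed environment
#'
#' Continuous covariates are scored by the R-squared of inverse-predicted
#' versus observed values; factors by the fraction of rows classified
#' correctly.
#'
#' @param inversion result of \code{\link{invertContinuous}} (may be NULL).
#' @param factorInversions named list of \code{\link{invertFactor}} results
#'   (may be empty).
#' @param data covariate data.frame holding the observed values (rows must
#'   align with the inversion's \code{row} indices).
#' @return data.frame: covariate, type, score
#' @export
inversePredictionScores <- function(inversion = NULL, factorInversions = list(),
                                    data) {
  out <- data.frame(covariate = character(), type = character(),
                    score = numeric())
  for (v in names(inversion)) {
    tab <- inversion[[v]]
    obs <- as.numeric(data[[v]])[tab$row]
    out <- rbind(out, data.frame(covariate = v, type = "continuous",
                                 score = rSquared(tab$estimate, obs)))
  }
  for (v in names(factorInversions)) {
    fi <- factorInversions[[v]]
    rws <- if (!is.null(fi$rows)) fi$rows else seq_along(fi$predicted)
    obs <- as.character(data[[v]])[rws]
    out <- rbind(out, data.frame(covariate = v, type = "factor",
                                 score = mean(fi$predicted == obs)))
  }
  out
}
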