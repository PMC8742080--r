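# Prediction-evaluation metrics.

#' Root mean squared prediction error
#'
#' In the units of the response (kg/tow for CPUE).
#'
#' @param pred,obs numeric vectors of equal length.
#' @export
rmspe <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("empty input or length mismatch")
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination for predictions
#'
#' \code{1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)}; negative when
#' predictions are worse than the observed mean.
#'
#' @param pred,obs numeric vectors of equal length; obs must vary.
#' @export
rSquared <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  ss <- sum((obs - mean(obs))^2)
  if (ss == 0) stop("constant observations: R-squared undefined")
  1 - sum((pred - obs)^2) / ss
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney rank statistic: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param scores numeric scores, higher meaning more likely present.
#' @param labels 0/1 (or logical) presence labels; both classes required.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean precision over a fixed threshold grid
#'
#' Precision (true positives over predicted positives) is computed at every
#' threshold in \code{0, 0.01, ..., 1}, predicting presence where the score
#' is at least the threshold; thresholds with no predicted presences are
#' skipped (0/0 undefined) and the arithmetic mean of the rest is returned.
#'
#' @param scores numeric scores in any range (occurrence probabilities
#'   typically).
#' @param labels 0/1 presence labels; at least one positive required.
#' @param step threshold interval (default 0.01).
#' @export
meanPrecision <- function(scores, labels, step = 0.01) {
  labels <- as.numeric(labels)
  if (sum(labels == 1) == 0) stop("no positive labels: precision undefined")
  thr <- seq(0, 1, by = step)
  prec <- vapply(thr, function(t) {
    predPos <- scores >= t
    if (!any(predPos)) return(NA_real_)
    sum(labels[predPos] == 1) / sum(predPos)
  }, numeric(1))
  mean(prec, na.rm = TRUE)
}

#' Aggregate predictions and observations over k-means clusters of predictors
#'
#' Clusters the standardized design columns with k-means and returns
#' cluster-level means of predictions and observations; size-weighted grand
#' means are unchanged by construction, so the aggregation is
#' mean-preserving.
#'
#' @param pred,obs n x S (or vector) predictions and observations.
#' @param X n x Q predictor matrix (intercept column ignored for clustering).
#' @param k number of clusters (default 50).
#' @param seed integer seed; empty-cluster failures are retried with a new
#'   seed before erroring.
#' @return list with \code{pred}, \code{obs} (k x S cluster means),
#'   \code{size} (cluster sizes), \code{cluster} (row assignment).
#' @export
aggregateByKmeans <- function(pred, obs, X, k = 50, seed = 1L) {
  pred <- as.matrix(pred); obs <- as.matrix(obs); X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must be at most n")
  if (k == n) {
    # identity aggregation: every row its own cluster
    return(list(pred = pred, obs = obs, size = rep(1, n),
                cluster = seq_len(n)))
  }
  keep <- apply(X, 2, sd) > 1e-12
  Z <- scale(X[, keep, drop = FALSE])
  cl <- NULL
  for (attempt in 0:2) {
    set.seed(.deriveSeed(seed, 6L + attempt))
    cl <- tryCatch(kmeans(Z, centers = k, nstart = 1, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(cl) && length(unique(cl$cluster)) == k) break
    cl <- NULL
  }
  if (is.null(cl)) stop("k-means produced an empty cluster after retries")
  g <- cl$cluster
  agg <- function(M) {
    out <- rowsum(M, g) / as.numeric(table(g))
    out
  }
  list(pred = agg(pred), obs = agg(obs),
       size = as.numeric(table(g)), cluster = g)
}

#' Per-species prediction metrics
#'
#' Convenience wrapper computing RMSPE and R-squared per species for CA
#' predictions, or AUC and mean precision for PA predictions, plus pooled
#' (mean over species) summaries.
#'
#' @param pred,obs n x S matrices.
#' @param kind \code{"CA"} or \code{"PA"}.
#' @return list with \code{perSpecies} data.frame and \code{pooled} named
#'   vector.
#' @export
metricsReport <- function(pred, obs, kind = c("CA", "PA")) {
  kind <- match.arg(kind)
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  S <- ncol(obs)
  spp <- colnames(obs); if (is.null(spp)) spp <- paste0("sp", seq_len(S))
  if (kind == "CA") {
    tab <- data.frame(species = spp,
      rmspe = vapply(seq_len(S), function(s) rmspe(pred[, s], obs[, s]), 1),
      r2 = vapply(seq_len(S), function(s)
        tryCatch(rSquared(pred[, s], obs[, s]), error = function(e) NA_real_), 1))
    pooled <- c(rmspe = mean(tab$rmspe), r2 = mean(tab$r2, na.rm = TRUE))
  } else {
    tab <- data.frame(species = spp,
      auc = vapply(seq_len(S), function(s)
        tryCatch(auc(pred[, s], obs[, s]), error = function(e) NA_real_), 1),
      meanPrecision = vapply(seq_len(S), function(s)
        tryCatch(meanPrecision(pred[, s], obs[, s]), error = function(e) NA_real_), 1))
    pooled <- c(auc = mean(tab$auc, na.rm = TRUE),
                meanPrecision = mean(tab$meanPrecision, na.rm = TRUE))
  }
  list(perSpecies = tab, pooled = pooled, n = nrow(obs))
}
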