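# Residual autocorrelation diagnostics: spatial semivariogram and temporal
# PACF, per species.

#' Empirical semivariogram of residuals over great-circle distance
#'
#' \eqn{\gamma(h) = \frac{1}{2|N(h)|}\sum_{(i,j)\in N(h)} (r_i - r_j)^2}
#' with pair distances computed by the haversine formula. Default bins are
#' ten equal-width intervals up to the median pairwise distance.
#'
#' @param residuals numeric vector, one residual per location.
#' @param coords two-column matrix/data.frame of (longitude, latitude) in
#'   degrees.
#' @param binEdges increasing numeric vector of bin edges in meters;
#'   defaults as described above.
#' @return data.frame: binStart, binEnd, nPairs, gamma (NA for empty bins).
#' @export
residualSemivariogram <- function(residuals, coords, binEdges = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 2) stop("need at least 2 points")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- geosphere::distHaversine(coords[ij[, 1], , drop = FALSE],
                                coords[ij[, 2], , drop = FALSE])
  sq <- (residuals[ij[, 1]] - residuals[ij[, 2]])^2
  if (is.null(binEdges)) {
    top <- median(d)
    binEdges <- seq(0, top, length.out = 11)
  }
  if (is.unsorted(binEdges, strictly = TRUE)) stop("binEdges must be increasing")
  nb <- length(binEdges) - 1
  bin <- findInterval(d, binEdges, rightmost.closed = TRUE)
  out <- data.frame(binStart = binEdges[-length(binEdges)],
                    binEnd = binEdges[-1], nPairs = 0L, gamma = NA_real_)
  for (b in seq_len(nb)) {
    sel <- bin == b
    out$nPairs[b] <- sum(sel)
    if (any(sel)) out$gamma[b] <- sum(sq[sel]) / (2 * sum(sel))
  }
  out
}

#' Partial autocorrelation of a residual time series
#'
#' Durbin-Levinson recursion on the sample autocorrelations. Lag 0 is
#' defined as 1 by convention.
#'
#' @param series numeric vector ordered in time (e.g. annual mean residuals).
#' @param maxLag highest lag to report; series must be longer than
#'   \code{maxLag + 1}.
#' @return named numeric vector of partial autocorrelations for lags
#'   0..maxLag, each in [-1, 1].
#' @export
residualPacf <- function(series, maxLag = 10) {
  n <- length(series)
  if (n <= maxLag + 1)
    stop("series too short (", n, ") for maxLag = ", maxLag)
  rho <- as.numeric(acf(series, lag.max = maxLag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  pacf_ <- numeric(maxLag)
  phi <- matrix(0, maxLag, maxLag)
  for (k in seq_len(maxLag)) {
    if (k == 1) {
      phi[1, 1] <- rho[1]
    } else {
      num <- rho[k] - sum(phi[k - 1, 1:(k - 1)] * rho[(k - 1):1])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[1:(k - 1)])
      phi[k, k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] -
        phi[k, k] * phi[k - 1, (k - 1):1]
    }
    pacf_[k] <- phi[k, k]
  }
  pacf_ <- pmin(1, pmax(-1, pacf_))
  setNames(c(1, pacf_), paste0("lag", 0:maxLag))
}
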