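# Design-matrix construction with replayable standardization.

#' Build the design matrix for a model specification
#'
#' Expands a covariate table into the n x Q design matrix of the latent
#' Gaussian model: intercept, standardized continuous covariates, dummy
#' columns for factor levels above the baseline, and interaction columns
#' formed as elementwise products of the (standardized) parents.
#'
#' @param data data.frame holding every covariate named in \code{spec}.
#' @param spec a \linkS4class{JsdmModelSpec}.
#' @param standardization optional named list of \code{c(mean, sd)} per
#'   continuous covariate, as recorded in a training
#'   \linkS4class{JsdmDesign}; supply it when building a prediction design
#'   so new data are transformed exactly like the training data.
#' @return a \linkS4class{JsdmDesign}
#' @export
buildDesign <- function(data, spec, standardization = NULL) {
  stopifnot(is(spec, "JsdmModelSpec"))
  data <- as.data.frame(data)
  n <- nrow(data)

  vars <- unique(unlist(lapply(spec@terms, function(t)
    switch(t$type, continuous = t$var, factor = t$var,
           interaction = c(t$a, t$b), NULL))))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("missing covariate(s) in data: ", paste(miss, collapse = ", "))

  factorLevels <- list()
  for (t in spec@terms) if (t$type == "factor") factorLevels[[t$var]] <- t$levels

  contVars <- setdiff(vars, names(factorLevels))
  std <- list()
  stdCols <- list()
  for (v in contVars) {
    x <- as.numeric(data[[v]])
    if (anyNA(x)) stop("covariate '", v, "' contains missing values")
    if (spec@standardize) {
      if (is.null(standardization)) {
        m <- mean(x); s <- sd(x)
        if (!is.finite(s) || s < 1e-12)
          stop("zero variance in covariate '", v, "'; cannot standardize")
      } else {
        if (is.null(standardization[[v]]))
          stop("no standardization parameters recorded for '", v, "'")
        m <- standardization[[v]][1]; s <- standardization[[v]][2]
      }
      std[[v]] <- c(mean = m, sd = s)
      stdCols[[v]] <- (x - m) / s
    } else {
      std[[v]] <- c(mean = 0, sd = 1)
      stdCols[[v]] <- x
    }
  }

  dummy <- function(var) {
    lev <- factorLevels[[var]]
    f <- as.character(data[[var]])
    unseen <- setdiff(unique(f), lev)
    if (length(unseen))
      stop("unseen factor level(s) in '", var, "': ",
           paste(unseen, collapse = ", "))
    out <- sapply(lev[-1], function(l) as.numeric(f == l))
    out <- matrix(out, nrow = n,
                  dimnames = list(NULL, paste0(var, lev[-1])))
    out
  }

  cols <- list(); map <- integer()
  for (i in seq_along(spec@terms)) {
    t <- spec@terms[[i]]
    block <- switch(t$type,
      intercept = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
      continuous = matrix(stdCols[[t$var]], n, 1, dimnames = list(NULL, t$var)),
      factor = dummy(t$var),
      interaction = {
        a <- stdCols[[t$a]]
        if (!is.null(factorLevels[[t$b]])) {
          d <- dummy(t$b)
          out <- a * d
          colnames(out) <- paste(t$a, colnames(d), sep = ":")
          out
        } else {
          matrix(a * stdCols[[t$b]], n, 1,
                 dimnames = list(NULL, paste(t$a, t$b, sep = ":")))
        }
      })
    cols[[i]] <- block
    map <- c(map, rep(i, ncol(block)))
  }
  X <- do.call(cbind, cols)
  new("JsdmDesign", values = X, columnTerms = map, standardization = std,
      spec = spec, data = data)
}

#' Numeric design matrix of a JsdmDesign
#' @param design a \linkS4class{JsdmDesign}
#' @export
designMatrix <- function(design) design@values

#' Standardization parameters recorded in a design
#' @param design a \linkS4class{JsdmDesign}
#' @return named list of c(mean, sd) per continuous covariate
#' @export
standardizationParams <- function(design) design@standardization

setMethod("show", "JsdmDesign", function(object) {
  cat("JsdmDesign: ", nrow(object@values), " rows x ", ncol(object@values),
      " columns\n  columns: ", paste(colnames(object@values), collapse = ", "),
      "\n", sep = "")
})

#' Censor a latent matrix to the observation scale
#'
#' Continuous abundance keeps positive latent values and maps the rest to an
#' exact zero; presence/absence records the sign.
#'
#' @param w numeric matrix (or vector) of latent values.
#' @param kind \code{"CA"} or \code{"PA"}.
#' @return matrix of observations; CA is \code{w * (w > 0)}, PA is
#'   \code{as.numeric(w > 0)}.
#' @export
censorToObserved <- function(w, kind = c("CA", "PA")) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(w)))
  if (kind == "CA") {
    y <- w
    y[y <= 0] <- 0
    y
  } else {
    y <- (w > 0) * 1
    y
  }
}
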