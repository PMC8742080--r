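# Term descriptors and the model-specification constructor.

.termLabel <- function(t) {
  switch(t$type,
    intercept = "(Intercept)",
    continuous = t$var,
    factor = t$var,
    interaction = paste(t$a, t$b, sep = ":"),
    stop("unknown term type: ", t$type))
}

.termIntercept <- function() list(type = "intercept")
.termContinuous <- function(var) list(type = "continuous", var = var)
.termFactor <- function(var, levels) list(type = "factor", var = var, levels = levels)
.termInteraction <- function(a, b) list(type = "interaction", a = a, b = b)

#' Construct a model specification
#'
#' @param continuous character vector of continuous covariate names.
#' @param factors named list; each element is the ordered level vector of a
#'   factor covariate. The first level is the baseline (e.g. subregion with
#'   baseline Gulf of Maine).
#' @param interactions list of length-2 character vectors \code{c(a, b)};
#'   \code{a} must be continuous, \code{b} continuous or a factor.
#' @param response \code{"CA"} (continuous abundance / CPUE tobit) or
#'   \code{"PA"} (presence-absence probit).
#' @param standardize standardize continuous covariates (default TRUE);
#'   interaction columns are products of the standardized parents.
#' @param requireHierarchy if TRUE (default) every interaction's parent main
#'   effects must be included as terms. Model-grid enumeration relaxes this
#'   so interactions can enter or leave candidates independently.
#' @return a \linkS4class{JsdmModelSpec}
#' @examples
#' spec <- jsdmModelSpec(
#'   continuous = c("BT", "depth", "BSAL", "SST"),
#'   factors = list(subregion = c("GoM", "SNE")),
#'   interactions = list(c("depth", "BT"), c("depth", "BSAL"), c("depth", "SST")))
#' @export
jsdmModelSpec <- function(continuous = character(), factors = list(),
                          interactions = list(), response = c("CA", "PA"),
                          standardize = TRUE, requireHierarchy = TRUE) {
  response <- match.arg(response)
  terms <- list(.termIntercept())
  for (v in continuous) terms <- c(terms, list(.termContinuous(v)))
  for (nm in names(factors)) {
    lev <- as.character(factors[[nm]])
    if (length(lev) < 2) stop("factor '", nm, "' needs at least 2 levels")
    terms <- c(terms, list(.termFactor(nm, lev)))
  }
  for (ia in interactions) {
    if (length(ia) != 2) stop("each interaction must name exactly 2 covariates")
    terms <- c(terms, list(.termInteraction(ia[1], ia[2])))
  }
  if (requireHierarchy) {
    main <- c(continuous, names(factors))
    for (ia in interactions) {
      miss <- setdiff(ia, main)
      if (length(miss))
        stop("interaction ", paste(ia, collapse = ":"),
             " requires main effect(s): ", paste(miss, collapse = ", "))
    }
  }
  new("JsdmModelSpec", responseKind = response, terms = terms,
      standardize = standardize)
}

#' Term labels of a model specification
#' @param spec a \linkS4class{JsdmModelSpec}
#' @return character vector, one label per term (intercept included)
#' @export
termLabels <- function(spec) vapply(spec@terms, .termLabel, character(1))

#' Response kind accessor
#' @param x a \linkS4class{JsdmModelSpec} or \linkS4class{JsdmFit}
#' @export
responseKind <- function(x) {
  if (is(x, "JsdmModelSpec")) x@responseKind else x@kind
}

# Remove terms by label (intercept cannot be removed).
.dropSpecTerms <- function(spec, labels) {
  keep <- !(termLabels(spec) %in% labels)
  if (!keep[1] || "(Intercept)" %in% labels)
    stop("cannot drop the intercept term")
  new("JsdmModelSpec", responseKind = spec@responseKind,
      terms = spec@terms[keep], standardize = spec@standardize)
}

# Subset a spec to forced + chosen optional labels without hierarchy closure.
.specFromLabels <- function(template, labels) {
  labs <- termLabels(template)
  keep <- labs == "(Intercept)" | labs %in% labels
  new("JsdmModelSpec", responseKind = template@responseKind,
      terms = template@terms[keep], standardize = template@standardize)
}

setMethod("show", "JsdmModelSpec", function(object) {
  labs <- termLabels(object)
  cat("JsdmModelSpec (", object@responseKind, ")\n", sep = "")
  cat("  terms: ", paste(labs, collapse = " + "), "\n", sep = "")
  cat("  standardize:", object@standardize, "\n")
})
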