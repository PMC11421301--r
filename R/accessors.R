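# Generics, accessors and show methods.

#' Number of age bins
#' @param x an [AgeGrid-class], [DcsmSpec-class] or [PairDataset-class].
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "AgeGrid", function(x) x@nBins)
#' @rdname nBins
#' @export
setMethod("nBins", "DcsmSpec", function(x) x@grid@nBins)
#' @rdname nBins
#' @export
setMethod("nBins", "PairDataset", function(x) x@grid@nBins)

#' Representative age of a bin
#'
#' The bin's lower bound (the model intercept is defined at the start of
#' the first bin, i.e. exact age 50 on the default grid).
#'
#' @param grid an [AgeGrid-class].
#' @param bin 0-based bin index (vectorized).
#' @return numeric ages.
#' @export
binAge <- function(grid, bin) grid@startAge + grid@binWidth * bin

#' Trait names of an object
#' @param x a [PairDataset-class] or [DcsmSpec-class].
#' @return character vector of trait names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname traitNames
#' @export
setMethod("traitNames", "PairDataset", function(x) x@traits)
#' @rdname traitNames
#' @export
setMethod("traitNames", "DcsmSpec", function(x) x@traits)

#' Number of twin pairs (including singletons)
#' @param x a [PairDataset-class].
#' @return integer.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "PairDataset",
          function(x) length(unique(x@persons$pairId)))

#' Number of persons
#' @param x a [PairDataset-class].
#' @return integer.
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' @rdname nPersons
#' @export
setMethod("nPersons", "PairDataset", function(x) nrow(x@persons))

#' Free parameter estimates of a fit
#' @param object a [DcsmFit-class].
#' @param ... ignored.
#' @return named numeric vector on the natural scale.
#' @export
setMethod("coef", "DcsmFit", function(object, ...) object@estimates)

#' Log-likelihood of a fit
#' @param object a [DcsmFit-class].
#' @param ... ignored.
#' @return object of class logLik with df attribute.
#' @export
setMethod("logLik", "DcsmFit", function(object, ...) {
  structure(object@loglik, df = object@nFree, class = "logLik")
})

#' Standard errors of the free parameters
#' @param fit a [DcsmFit-class].
#' @return named numeric vector (NA when unavailable).
#' @export
standardErrors <- function(fit) {
  stopifnot(is(fit, "DcsmFit"))
  fit@se
}

setMethod("show", "AgeGrid", function(object) {
  cat(sprintf("AgeGrid: %d bins of %g years, ages [%g, %g)\n",
              object@nBins, object@binWidth, object@startAge,
              object@startAge + object@binWidth * object@nBins))
})

setMethod("show", "PairDataset", function(object) {
  s <- datasetSummary(object)
  cat(sprintf(
    "PairDataset: %d persons in %d pairs (%d singletons), %d observations\n",
    s$nPersons, s$nPairs, s$nSingletons, s$nObservations))
  cat("  traits:", paste(object@traits, collapse = ", "),
      if (isTRUE(object@paceRescaled))
        sprintf("(%s on the x10 scale)", object@paceTrait) else "", "\n")
  show(object@grid)
})

setMethod("show", "DcsmSpec", function(object) {
  nT <- length(object@traits)
  cat(sprintf("DcsmSpec: %s dual change score model\n",
              if (nT == 1L) "univariate" else "bivariate"))
  cat("  traits:", paste(object@traits, collapse = ", "), "\n")
  cat("  proportional (beta):",
      paste(object@traits[object@proportional], collapse = ", "), "\n")
  if (nT == 2L) {
    dirs <- c(
      if (object@coupling[["to1"]])
        sprintf("%s -> %s", object@traits[2], object@traits[1]),
      if (object@coupling[["to2"]])
        sprintf("%s -> %s", object@traits[1], object@traits[2]))
    cat("  coupling (gamma):",
        if (length(dirs)) paste(dirs, collapse = ", ") else "none", "\n")
  }
  cat("  individual level:", paste(object@indLevel, collapse = "/"),
      " pair level:", paste(object@pairLevel, collapse = "/"), "\n")
  cat("  free parameters:", nFreeParams(object), "\n")
})

setMethod("show", "DcsmFit", function(object) {
  cat(sprintf("DcsmFit: logLik = %.3f on %d free parameters (%s)\n",
              object@loglik, object@nFree,
              if (object@converged) "converged" else "NOT converged"))
  est <- object@estimates
  se <- object@se
  tab <- data.frame(Estimate = round(est, 4),
                    SE = round(se[names(est)], 4))
  print(tab)
})

setMethod("show", "LrtResult", function(object) {
  cat(sprintf(
    "Likelihood ratio test: chi^2 = %.4f, df = %d, p = %.4g\n",
    object@statistic, object@df, object@pValue))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d individuals, pair fraction %.2f, P(woman) %.3f\n",
    object@nIndividuals, object@pairFraction, object@sexRatio))
  cat("  waves 1-6 probs:",
      paste(sprintf("%.3f", object@waveCountProbs), collapse = " "), "\n")
  cat(sprintf("  spacing %g-%g y, entry ages %g-%g\n",
              object@waveSpacing[1], object@waveSpacing[2],
              object@entryAgeRange[1], object@entryAgeRange[2]))
})
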