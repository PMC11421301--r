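# Likelihood ratio tests and the nested model-selection ladders.

#' Likelihood ratio test of nested DCSM fits
#'
#' The nested specification must arise from the full one by fixing
#' parameters to zero (checked through the free-parameter sets). The
#' statistic is 2 x (loglik_full - loglik_nested), floored at 0 with a
#' warning if negative, against a chi-square reference with df equal to
#' the difference in free-parameter counts. For variance-component
#' boundaries this naive reference is conservative (mixture references
#' are not implemented).
#'
#' @param full,nested [DcsmFit-class] objects; both should be converged.
#' @return An [LrtResult-class].
#' @export
likelihoodRatioTest <- function(full, nested) {
  stopifnot(is(full, "DcsmFit"), is(nested, "DcsmFit"))
  fn <- names(full@estimates)
  nn <- names(nested@estimates)
  if (!all(nn %in% fn))
    stop("models are not nested: nested fit has parameters absent from the full fit")
  df <- full@nFree - nested@nFree
  if (df <= 0L)
    stop("models are not nested: no parameter-count difference")
  if (!full@converged || !nested@converged)
    warning("likelihood ratio test on non-converged fit(s)")
  stat <- 2 * (full@loglik - nested@loglik)
  if (stat < 0) {
    warning(sprintf(
      "negative LRT statistic (%.4g) floored at 0; check convergence", stat))
    stat <- 0
  }
  new("LrtResult", statistic = stat, df = as.integer(df),
      pValue = pchisq(stat, df = df, lower.tail = FALSE),
      full = full, nested = nested)
}

# Fit `spec`, preferring a warm start (another model's parameters); the
# default data-driven start is tried as well only when the warm-started
# run fails or does not converge, and the better optimum is kept.
fitBest <- function(spec, data, warm = NULL, computeSE = TRUE, ...) {
  fit <- NULL
  if (!is.null(warm)) {
    fit <- tryCatch(
      fitDcsm(spec, data, start = warm, computeSE = computeSE, ...),
      error = function(e) NULL)
  }
  if (is.null(fit) || !fit@converged) {
    fitD <- tryCatch(fitDcsm(spec, data, computeSE = computeSE, ...),
                     error = function(e) NULL)
    if (is.null(fit) ||
        (!is.null(fitD) && fitD@loglik > fit@loglik)) fit <- fitD
  }
  if (is.null(fit)) stop("all starts failed for the requested fit")
  fit
}

# Enforce monotone nesting: if the nested optimum beats the full one,
# refit the full model warm-started from the nested parameters.
ensureMonotone <- function(full, nested, data, computeSE = TRUE, ...) {
  if (nested@loglik > full@loglik + 1e-6) {
    refit <- tryCatch(
      fitDcsm(full@spec, data, start = nested@params,
              computeSE = computeSE, ...),
      error = function(e) NULL)
    if (!is.null(refit) && refit@loglik > full@loglik) full <- refit
  }
  full
}

#' Univariate model selection: proportional change vs linear growth
#'
#' Fits the full univariate dual change score model (constant plus
#' proportional change) and the nested linear-only model (beta fixed to
#' 0), compares them by likelihood ratio test, and retains the
#' proportional term iff p < alpha.
#'
#' @param data a [PairDataset-class].
#' @param trait trait name present in the data.
#' @param indLevel,pairLevel random-effect structure per level.
#' @param alpha LRT significance level (default 0.05).
#' @param computeSE compute standard errors for the fits.
#' @param ... passed to [fitDcsm()].
#' @return list of class \code{DcsmSelection}: \code{fits} (full,
#'   linear), \code{lrt}, \code{retained} ("full" or "linear"),
#'   \code{spec} of the retained model.
#' @export
univariateSelection <- function(data, trait, indLevel = "full",
                                pairLevel = "full", alpha = 0.05,
                                computeSE = TRUE, ...) {
  stopifnot(trait %in% data@traits)
  if (!any(data@observations$trait == trait))
    stop("no observations for trait ", trait)
  specFull <- dcsmSpec(trait, proportional = TRUE, indLevel = indLevel,
                       pairLevel = pairLevel, grid = data@grid)
  specLin <- dcsmSpec(trait, proportional = FALSE, indLevel = indLevel,
                      pairLevel = pairLevel, grid = data@grid)
  fitFull <- fitDcsm(specFull, data, computeSE = computeSE, ...)
  fitLin <- fitBest(specLin, data, warm = fitFull@params,
                    computeSE = computeSE, ...)
  fitFull <- ensureMonotone(fitFull, fitLin, data, computeSE = computeSE, ...)
  lrt <- likelihoodRatioTest(fitFull, fitLin)
  retained <- if (lrt@pValue < alpha) "full" else "linear"
  structure(list(
    trait = trait,
    fits = list(full = fitFull, linear = fitLin),
    lrt = lrt, alpha = alpha, retained = retained,
    spec = if (retained == "full") specFull else specLin),
    class = "DcsmSelection")
}

#' Bivariate coupling selection ladder
#'
#' Fits four bivariate models on top of the supplied univariate
#' structure — bidirectional coupling, no coupling, and the two
#' unidirectional models — and follows the selection sequence:
#' the no-coupling model is accepted if it does not fit significantly
#' worse than the bidirectional model; otherwise each unidirectional
#' model is accepted if it is not significantly worse than the
#' bidirectional one. If both unidirectional models are acceptable the
#' tie is reported, not silently broken.
#'
#' @param data a [PairDataset-class] with both traits.
#' @param traits the two trait names (trait 2's level couples into
#'   trait 1's change under direction \code{to1}).
#' @param proportional per-trait logical from the retained univariate
#'   structure.
#' @param indLevel,pairLevel per-trait random-effect structure.
#' @param alpha LRT level (default 0.05).
#' @param computeSE compute standard errors.
#' @param ... passed to [fitDcsm()].
#' @return list of class \code{DcsmSelection}: \code{fits}
#'   (bidirectional, none, to1, to2), \code{lrts} (vs bidirectional),
#'   \code{selected} ("none", "to1", "to2", "bidirectional" or
#'   c("to1","to2") on a tie), \code{spec} of the selected model (first
#'   of the tie, if any), \code{tie} flag.
#' @export
bivariateSelection <- function(data, traits = data@traits,
                               proportional = c(TRUE, FALSE),
                               indLevel = "full", pairLevel = "full",
                               alpha = 0.05, computeSE = TRUE, ...) {
  stopifnot(length(traits) == 2L, all(traits %in% data@traits))
  mk <- function(coupling) {
    dcsmSpec(traits, proportional = proportional, coupling = coupling,
             indLevel = indLevel, pairLevel = pairLevel,
             residCross = TRUE, grid = data@grid)
  }
  specs <- list(bidirectional = mk(c(TRUE, TRUE)),
                none = mk(c(FALSE, FALSE)),
                to1 = mk(c(TRUE, FALSE)),
                to2 = mk(c(FALSE, TRUE)))
  fits <- list()
  fits$bidirectional <- fitDcsm(specs$bidirectional, data,
                                computeSE = computeSE, ...)
  for (nm in c("none", "to1", "to2")) {
    fits[[nm]] <- fitBest(specs[[nm]], data, warm = fits$bidirectional@params,
                          computeSE = computeSE, ...)
    fits$bidirectional <- ensureMonotone(fits$bidirectional, fits[[nm]],
                                         data, computeSE = computeSE, ...)
  }
  lrts <- lapply(fits[c("none", "to1", "to2")], function(f)
    likelihoodRatioTest(fits$bidirectional, f))
  tie <- FALSE
  if (lrts$none@pValue >= alpha) {
    selected <- "none"
  } else {
    ok <- c(to1 = lrts$to1@pValue >= alpha, to2 = lrts$to2@pValue >= alpha)
    if (!any(ok)) {
      selected <- "bidirectional"
    } else if (all(ok)) {
      selected <- c("to1", "to2")
      tie <- TRUE
    } else {
      selected <- names(ok)[ok]
    }
  }
  structure(list(
    traits = traits,
    fits = fits, lrts = lrts, alpha = alpha,
    selected = selected, tie = tie,
    spec = specs[[selected[1]]]),
    class = "DcsmSelection")
}

#' @export
print.DcsmSelection <- function(x, ...) {
  if (!is.null(x[["trait"]])) {
    cat(sprintf("Univariate selection for '%s': retained = %s\n",
                x$trait, x$retained))
    cat(sprintf("  LRT chi^2 = %.4f, df = %d, p = %.4g\n",
                x$lrt@statistic, x$lrt@df, x$lrt@pValue))
  } else {
    cat(sprintf("Bivariate coupling selection (%s, %s): selected = %s%s\n",
                x$traits[1], x$traits[2],
                paste(x$selected, collapse = " & "),
                if (x$tie) " (tie)" else ""))
    for (nm in names(x$lrts))
      cat(sprintf("  vs %-13s chi^2 = %8.4f, df = %d, p = %.4g\n",
                  nm, x$lrts[[nm]]@statistic, x$lrts[[nm]]@df,
                  x$lrts[[nm]]@pValue))
  }
  invisible(x)
}
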