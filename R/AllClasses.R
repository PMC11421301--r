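# S4 classes for the age grid, pair-structured data, model specification,
# parameters, and fit results.

#' Age grid of half-open bins
#'
#' Discretization of chronological age into contiguous half-open bins
#' \code{[start + w*t, start + w*t + w)} for bin index \code{t = 0, ...,
#' nBins - 1}. The default grid covers ages 50 to <90 in 2-year bins,
#' the timescale on which the models are indexed; data at or beyond the
#' upper bound are unassignable and dropped on import.
#'
#' @slot startAge numeric(1), lower bound of the first bin (years).
#' @slot binWidth numeric(1), bin width (years).
#' @slot nBins integer(1), number of bins.
#' @export
setClass("AgeGrid",
  representation(startAge = "numeric", binWidth = "numeric", nBins = "integer"),
  prototype(startAge = 50, binWidth = 2, nBins = 20L)
)

setValidity("AgeGrid", function(object) {
  msg <- character()
  if (length(object@startAge) != 1L || !is.finite(object@startAge))
    msg <- c(msg, "startAge must be a single finite number")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 1L)
    msg <- c(msg, "nBins must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct an age grid
#'
#' @param startAge lower bound of the first bin (years). Default 50.
#' @param binWidth bin width in years. Default 2.
#' @param nBins number of bins. Default 20 (covering 50 to <90).
#' @return An [AgeGrid-class] object.
#' @examples
#' g <- ageGrid()
#' nBins(g)
#' assignAgeBin(c(50, 68.2, 89.9, 90), g)
#' @export
ageGrid <- function(startAge = 50, binWidth = 2, nBins = 20L) {
  new("AgeGrid", startAge = as.numeric(startAge),
      binWidth = as.numeric(binWidth), nBins = as.integer(nBins))
}

#' Twin-pair longitudinal dataset on an age grid
#'
#' Long-format observations of one or two traits, binned on an
#' [AgeGrid-class] and grouped into twin pairs. Singletons (co-twin not
#' participating) are permitted and handled in the likelihood as a
#' co-twin with every observation missing. Zygosity is retained as
#' metadata only; the models use a single pair-level variance component
#' rather than an MZ/DZ genetic decomposition.
#'
#' @slot grid the [AgeGrid-class].
#' @slot persons data.frame with one row per person: \code{personId},
#'   \code{pairId}, \code{member} (1 or 2 within pair), \code{sex}
#'   (0 = man, 1 = woman), \code{zygosity}.
#' @slot observations data.frame with one row per (person, bin, trait)
#'   observation: \code{personId}, \code{bin} (0-based), \code{age}
#'   (raw age of the kept visit), \code{trait}, \code{value}.
#' @slot traits character vector of trait names (length 1 or 2).
#' @slot paceRescaled logical; TRUE when a pace-of-aging trait has been
#'   multiplied by 10 (done exactly once on import).
#' @slot paceTrait name of the rescaled trait, or NA.
#' @export
setClass("PairDataset",
  representation(grid = "AgeGrid", persons = "data.frame",
                 observations = "data.frame", traits = "character",
                 paceRescaled = "logical", paceTrait = "character"),
  prototype(paceRescaled = FALSE, paceTrait = NA_character_)
)

setValidity("PairDataset", function(object) {
  msg <- character()
  p <- object@persons
  o <- object@observations
  needP <- c("personId", "pairId", "member", "sex", "zygosity")
  needO <- c("personId", "bin", "age", "trait", "value")
  if (!all(needP %in% names(p))) {
    return(paste("persons must have columns:", paste(needP, collapse = ", ")))
  }
  if (!all(needO %in% names(o))) {
    return(paste("observations must have columns:", paste(needO, collapse = ", ")))
  }
  if (anyDuplicated(p$personId))
    msg <- c(msg, "each person may appear once (and under a single pairId)")
  if (any(!p$sex %in% c(0L, 1L)))
    msg <- c(msg, "sex must be coded 0 (man) / 1 (woman)")
  if (any(table(p$pairId) > 2L))
    msg <- c(msg, "a pairId may contain at most two persons")
  if (nrow(o)) {
    if (!all(o$personId %in% p$personId))
      msg <- c(msg, "observations reference unknown persons")
    if (any(o$bin < 0L | o$bin >= object@grid@nBins))
      msg <- c(msg, "observation bins outside the age grid")
    if (!all(o$trait %in% object@traits))
      msg <- c(msg, "observation traits not listed in traits slot")
    if (anyDuplicated(o[, c("personId", "bin", "trait")]))
      msg <- c(msg, "at most one observation per person, bin and trait")
  }
  if (!length(object@traits) %in% 1:2)
    msg <- c(msg, "traits must have length 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Dual change score model specification
#'
#' Structural switches of the model: which traits enter, which
#' proportional (beta) and coupling (gamma) dynamics are free, and which
#' random-effect structure is estimated at the individual and twin-pair
#' level. Parameters switched off are fixed to zero and carry no degree
#' of freedom.
#'
#' The level selectors are per trait: \code{"full"} (intercept and slope
#' factors), \code{"intercept"} (intercept factor only — used for the
#' pace-of-aging models, where the clock's pair-level slope variance is
#' dropped), or \code{"none"}.
#'
#' @slot traits character, trait names; length 1 (univariate) or 2.
#' @slot proportional named logical per trait: beta free?
#' @slot coupling named logical \code{c(to1 = , to2 = )}: \code{to1} frees
#'   the coupling of trait 2's previous level into trait 1's change
#'   (e.g. clock -> FI) and \code{to2} the reverse.
#' @slot indLevel,pairLevel named character per trait: "full",
#'   "intercept" or "none".
#' @slot residCross logical: free within-person within-bin residual
#'   covariance between the two traits.
#' @slot sexEffects logical: adjust intercepts and slopes for sex
#'   (default TRUE; switch off for single-sex toys).
#' @slot grid the [AgeGrid-class].
#' @export
setClass("DcsmSpec",
  representation(traits = "character", proportional = "logical",
                 coupling = "logical", indLevel = "character",
                 pairLevel = "character", residCross = "logical",
                 sexEffects = "logical", grid = "AgeGrid")
)

setValidity("DcsmSpec", function(object) {
  msg <- character()
  nT <- length(object@traits)
  if (!nT %in% 1:2) msg <- c(msg, "traits must have length 1 or 2")
  if (length(object@proportional) != nT)
    msg <- c(msg, "proportional must have one flag per trait")
  if (length(object@coupling) != 2L ||
      !identical(names(object@coupling), c("to1", "to2")))
    msg <- c(msg, "coupling must be logical c(to1=, to2=)")
  if (nT == 1L && any(object@coupling))
    msg <- c(msg, "coupling requires two traits")
  if (nT == 1L && object@residCross)
    msg <- c(msg, "residCross requires two traits")
  lev <- c("full", "intercept", "none")
  if (length(object@indLevel) != nT || !all(object@indLevel %in% lev))
    msg <- c(msg, "indLevel must be per-trait: full/intercept/none")
  if (length(object@pairLevel) != nT || !all(object@pairLevel %in% lev))
    msg <- c(msg, "pairLevel must be per-trait: full/intercept/none")
  if (length(msg)) msg else TRUE
})

#' Construct a model specification
#'
#' @param traits trait names, length 1 or 2. The first trait is the
#'   "outcome-like" trait in coupling direction \code{to1} (trait 2's
#'   level predicting trait 1's change).
#' @param proportional logical per trait (recycled): include the
#'   proportional change effect beta?
#' @param coupling logical of length 2, \code{c(to1, to2)}; ignored (and
#'   must be FALSE) for univariate specs.
#' @param indLevel,pairLevel per-trait random-effect structure:
#'   \code{"full"}, \code{"intercept"} or \code{"none"} (recycled).
#' @param residCross free residual covariance between the two traits
#'   within person and bin. Default TRUE for bivariate specs.
#' @param sexEffects regress sex on the intercepts and slopes (default
#'   TRUE).
#' @param grid an [AgeGrid-class].
#' @return A [DcsmSpec-class].
#' @examples
#' # bivariate frailty-clock model with clock -> FI coupling only
#' sp <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, FALSE),
#'                coupling = c(TRUE, FALSE),
#'                pairLevel = c("full", "intercept"))
#' nFreeParams(sp)
#' @export
dcsmSpec <- function(traits,
                     proportional = TRUE,
                     coupling = c(FALSE, FALSE),
                     indLevel = "full",
                     pairLevel = "full",
                     residCross = length(traits) == 2L,
                     sexEffects = TRUE,
                     grid = ageGrid()) {
  nT <- length(traits)
  proportional <- setNames(rep_len(as.logical(proportional), nT), traits)
  coupling <- setNames(rep_len(as.logical(coupling), 2L), c("to1", "to2"))
  indLevel <- setNames(rep_len(indLevel, nT), traits)
  pairLevel <- setNames(rep_len(pairLevel, nT), traits)
  new("DcsmSpec", traits = traits, proportional = proportional,
      coupling = coupling, indLevel = indLevel, pairLevel = pairLevel,
      residCross = as.logical(residCross),
      sexEffects = as.logical(sexEffects), grid = grid)
}

#' Dual change score model parameters
#'
#' All parameters of the (up to bivariate) model. Vectors are length 2
#' in factor/trait order (trait 1, trait 2); for univariate models the
#' second entries are ignored and fixed at 0. Growth-factor covariance
#' matrices are 4 x 4 over the factor order (I1, S1, I2, S2) — intercept
#' and slope of trait 1, then of trait 2.
#'
#' The constant change multipliers alpha are fixed to 1 and are not
#' represented as parameters.
#'
#' @slot muI,muS mean intercepts (trait units at the first bin, e.g. age
#'   50) and mean slopes (trait units per bin).
#' @slot beta proportional change effects per trait (per bin).
#' @slot gamma coupling effects \code{c(to1 = , to2 = )}: \code{to1}
#'   multiplies trait 2's previous level in trait 1's change equation.
#' @slot sexI,sexS additive effects of sex (women vs men) on intercepts
#'   and slopes.
#' @slot sigmaInd,sigmaPair 4 x 4 covariance matrices of the growth
#'   factors at the individual and twin-pair level.
#' @slot resVar occasion residual variances per trait.
#' @slot resCov residual covariance between the two traits within person
#'   and bin.
#' @export
setClass("DcsmParams",
  representation(muI = "numeric", muS = "numeric", beta = "numeric",
                 gamma = "numeric", sexI = "numeric", sexS = "numeric",
                 sigmaInd = "matrix", sigmaPair = "matrix",
                 resVar = "numeric", resCov = "numeric")
)

setValidity("DcsmParams", function(object) {
  msg <- character()
  for (nm in c("muI", "muS", "beta", "sexI", "sexS", "resVar")) {
    if (length(slot(object, nm)) != 2L || any(!is.finite(slot(object, nm))))
      msg <- c(msg, sprintf("%s must be finite numeric of length 2", nm))
  }
  if (length(object@gamma) != 2L ||
      !identical(names(object@gamma), c("to1", "to2")))
    msg <- c(msg, "gamma must be named c(to1=, to2=)")
  for (nm in c("sigmaInd", "sigmaPair")) {
    S <- slot(object, nm)
    if (!all(dim(S) == c(4L, 4L)) || any(!is.finite(S))) {
      msg <- c(msg, sprintf("%s must be a finite 4x4 matrix", nm))
      next
    }
    if (max(abs(S - t(S))) > 1e-8)
      msg <- c(msg, sprintf("%s must be symmetric", nm))
    else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, sprintf("%s must be positive semi-definite", nm))
  }
  if (length(object@resVar) == 2L && any(object@resVar < 0))
    msg <- c(msg, "residual variances must be non-negative")
  if (length(object@resCov) != 1L || !is.finite(object@resCov))
    msg <- c(msg, "resCov must be a single finite number")
  else if (length(object@resVar) == 2L && all(is.finite(object@resVar)) &&
           abs(object@resCov) > sqrt(prod(object@resVar)) + 1e-8)
    msg <- c(msg, "resCov exceeds the residual Cauchy-Schwarz bound")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param muI,muS,beta,sexI,sexS numeric length-2 vectors (trait 1,
#'   trait 2); scalars are padded with 0.
#' @param gamma numeric length 2, coupling \code{c(to1, to2)}.
#' @param sigmaInd,sigmaPair 4 x 4 growth-factor covariance matrices
#'   over factors (I1, S1, I2, S2).
#' @param resVar residual variances per trait (positive).
#' @param resCov within-bin residual covariance between traits.
#' @return A [DcsmParams-class].
#' @export
dcsmParams <- function(muI = c(0, 0), muS = c(0, 0), beta = c(0, 0),
                       gamma = c(0, 0), sexI = c(0, 0), sexS = c(0, 0),
                       sigmaInd = matrix(0, 4, 4),
                       sigmaPair = matrix(0, 4, 4),
                       resVar = c(1, 1), resCov = 0) {
  pad2 <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- c(x, 0)
    unname(x)
  }
  gamma <- setNames(pad2(gamma), c("to1", "to2"))
  new("DcsmParams", muI = pad2(muI), muS = pad2(muS), beta = pad2(beta),
      gamma = gamma, sexI = pad2(sexI), sexS = pad2(sexS),
      sigmaInd = unname(as.matrix(sigmaInd)),
      sigmaPair = unname(as.matrix(sigmaPair)),
      resVar = pad2(resVar), resCov = as.numeric(resCov))
}

#' Model-implied moments over a twin pair's observation layout
#'
#' Mean vector and covariance matrix of the stacked observed variables
#' of one twin pair: twin 1's trait-by-bin block followed by twin 2's.
#'
#' @slot mean numeric vector over the pair layout.
#' @slot cov covariance matrix over the same layout.
#' @slot layout data.frame mapping (twin, trait, bin) to row position.
#' @export
setClass("ImpliedMoments",
  representation(mean = "numeric", cov = "matrix", layout = "data.frame")
)

#' Fitted dual change score model
#'
#' @slot spec the [DcsmSpec-class] fitted.
#' @slot params estimated parameters as a [DcsmParams-class].
#' @slot estimates named numeric vector of the free parameters on the
#'   natural scale.
#' @slot se named numeric vector of delta-method standard errors
#'   (NA when the observed information was singular or not computed).
#' @slot loglik maximized log-likelihood.
#' @slot nFree number of free parameters.
#' @slot converged logical.
#' @slot nEval number of objective evaluations.
#' @slot details list: optimizer messages, gradient norm, start values,
#'   data summary.
#' @export
setClass("DcsmFit",
  representation(spec = "DcsmSpec", params = "DcsmParams",
                 estimates = "numeric", se = "numeric", loglik = "numeric",
                 nFree = "integer", converged = "logical",
                 nEval = "integer", details = "list")
)

setValidity("DcsmFit", function(object) {
  if (length(object@estimates) != object@nFree)
    return("estimates length must equal nFree")
  TRUE
})

#' Likelihood ratio test result
#'
#' @slot statistic 2 x (loglik_full - loglik_nested), floored at 0.
#' @slot df difference in free parameter counts.
#' @slot pValue chi-square upper tail probability.
#' @slot full,nested the two [DcsmFit-class] objects compared.
#' @export
setClass("LrtResult",
  representation(statistic = "numeric", df = "integer", pValue = "numeric",
                 full = "DcsmFit", nested = "DcsmFit")
)

#' Study design for the synthetic twin cohort
#'
#' Sampling design emulating a longitudinal twin study of aging (SATSA):
#' same-sex twin pairs, 1-6 visits per person at 3-6 year spacing,
#' entry between ages 50 and 84, visits at or past age 90 dropped.
#'
#' @slot nIndividuals number of persons (default 524).
#' @slot pairFraction share of persons whose co-twin participates.
#' @slot sexRatio probability a pair (or singleton) is female.
#' @slot waveCountProbs probabilities of 1-6 visits per person.
#' @slot waveSpacing range (years) of the uniform inter-visit spacing.
#' @slot entryAgeRange range of the uniform age at first visit.
#' @slot zygosityProbs probabilities of MZ/DZ/unknown (metadata only).
#' @export
setClass("StudyDesign",
  representation(nIndividuals = "integer", pairFraction = "numeric",
                 sexRatio = "numeric", waveCountProbs = "numeric",
                 waveSpacing = "numeric", entryAgeRange = "numeric",
                 zygosityProbs = "numeric")
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@pairFraction < 0 || object@pairFraction > 1)
    msg <- c(msg, "pairFraction must be in [0, 1]")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must be in [0, 1]")
  if (abs(sum(object@waveCountProbs) - 1) > 1e-8 ||
      any(object@waveCountProbs < 0))
    msg <- c(msg, "waveCountProbs must be non-negative and sum to 1")
  if (length(object@waveSpacing) != 2L || diff(object@waveSpacing) < 0 ||
      any(object@waveSpacing <= 0))
    msg <- c(msg, "waveSpacing must be an increasing positive range")
  if (length(object@entryAgeRange) != 2L || diff(object@entryAgeRange) < 0)
    msg <- c(msg, "entryAgeRange must be an increasing range")
  if (abs(sum(object@zygosityProbs) - 1) > 1e-8)
    msg <- c(msg, "zygosityProbs must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a study design
#'
#' Defaults emulate the SATSA analysis sample: 524 individuals, 58.6%
#' women, visit counts distributed as 157/123/113/89/41/1 over 1-6
#' waves (about 1 309 scheduled visits), 3-6 years between waves, entry
#' ages uniform on [50, 84].
#'
#' @param nIndividuals,pairFraction,sexRatio,waveCountProbs,waveSpacing,entryAgeRange,zygosityProbs
#'   see [StudyDesign-class].
#' @return A [StudyDesign-class].
#' @export
studyDesign <- function(nIndividuals = 524L,
                        pairFraction = 0.5,
                        sexRatio = 0.586,
                        waveCountProbs = c(157, 123, 113, 89, 41, 1) / 524,
                        waveSpacing = c(3, 6),
                        entryAgeRange = c(50, 84),
                        zygosityProbs = c(MZ = 0.345, DZ = 0.653,
                                          UNK = 0.002)) {
  new("StudyDesign", nIndividuals = as.integer(nIndividuals),
      pairFraction = pairFraction, sexRatio = sexRatio,
      waveCountProbs = waveCountProbs / sum(waveCountProbs),
      waveSpacing = as.numeric(waveSpacing),
      entryAgeRange = as.numeric(entryAgeRange),
      zygosityProbs = zygosityProbs)
}
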