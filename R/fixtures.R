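# Preset model configurations: generating values for simulation studies,
# emulating bivariate frailty-index / epigenetic-clock dynamics in an
# aging twin cohort (trait 1 = frailty index in percent, trait 2 = an
# epigenetic clock; pace-of-aging clocks on the x10 scale).

symMat4 <- function(v11, v21, v22, v31, v32, v33, v41, v42, v43, v44) {
  m <- matrix(0, 4, 4)
  m[lower.tri(m, diag = TRUE)] <- c(v11, v21, v31, v41, v22, v32, v42,
                                    v33, v43, v44)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# Repair rounded covariance tables: apply the eigenvalue clip on the
# block of factors the spec keeps active, leaving fixed rows at zero.
repairSigma <- function(S, spec, level) {
  act <- activeFactors(spec, level)
  out <- matrix(0, 4, 4)
  out[act, act] <- nearPsd(S[act, act, drop = FALSE])
  out
}

#' Preset dual change score model configurations
#'
#' Ready-made (spec, params) pairs used as generating values in
#' simulation and recovery studies. Magnitudes are representative of
#' frailty-index and epigenetic-clock dynamics estimated in Swedish twin
#' data on the default 2-year grid from age 50:
#'
#' \describe{
#'   \item{"pace"}{bivariate FI + pace-of-aging clock (x10 scale):
#'     unidirectional coupling from the clock to FI change (gamma =
#'     1.19), proportional change on FI only, pair-level intercept
#'     variance only for the clock.}
#'   \item{"pcclock"}{bivariate FI + age-trained PC clock (years): no
#'     coupling, proportional change on FI only, full pair-level
#'     structure for both traits.}
#'   \item{"fiUnivariate"}{univariate FI model: accelerating deficit
#'     accumulation (intercept 6.01%, slope -0.69 per bin, proportional
#'     effect 0.15).}
#' }
#'
#' Covariance tables rounded to two decimals are not exactly positive
#' semi-definite (variance components near the zero boundary); the
#' presets apply [nearPsd()] to the active blocks, which perturbs the
#' second moments by at most a few hundredths. Mean structure and
#' dynamics are unmodified.
#'
#' @param name one of "pace", "pcclock", "fiUnivariate".
#' @return list with elements \code{spec} ([DcsmSpec-class]) and
#'   \code{params} ([DcsmParams-class]).
#' @examples
#' m <- presetModel("pace")
#' m$spec
#' @export
presetModel <- function(name = c("pace", "pcclock", "fiUnivariate")) {
  name <- match.arg(name)
  if (name == "pace") {
    spec <- dcsmSpec(c("fi", "clock"),
                     proportional = c(TRUE, FALSE),
                     coupling = c(TRUE, FALSE),
                     indLevel = "full",
                     pairLevel = c("full", "intercept"),
                     residCross = TRUE)
    sigmaInd <- symMat4(9.94,
                        -2.24, 1.10,
                        1.94, -0.96, 1.01,
                        -0.13, 0.04, -0.05, 0.00)
    sigmaPair <- symMat4(2.66,
                         0.29, 0.71,
                         -0.17, -0.64, 0.56,
                         0, 0, 0, 0)
    params <- dcsmParams(
      muI = c(6.55, 10.04), muS = c(-12.31, 0.06),
      beta = c(0.06, 0), gamma = c(1.19, 0),
      sexI = c(0.60, 0.01), sexS = c(0.29, -0.03),
      sigmaInd = repairSigma(sigmaInd, spec, spec@indLevel),
      sigmaPair = repairSigma(sigmaPair, spec, spec@pairLevel),
      resVar = c(14.52, 0.99), resCov = 0.03)
  } else if (name == "pcclock") {
    spec <- dcsmSpec(c("fi", "clock"),
                     proportional = c(TRUE, FALSE),
                     coupling = c(FALSE, FALSE),
                     indLevel = "full",
                     pairLevel = "full",
                     residCross = TRUE)
    sigmaInd <- symMat4(19.95,
                        -3.15, 0.52,
                        6.27, -1.06, 5.89,
                        -0.47, 0.08, -0.26, 0.06)
    sigmaPair <- symMat4(6.71,
                         -0.91, 0.12,
                         -2.41, 0.65, 54.16,
                         0.12, -0.03, -0.61, 0.00)
    params <- dcsmParams(
      muI = c(6.03, 50.49), muS = c(-0.73, 1.12),
      beta = c(0.15, 0), gamma = c(0, 0),
      sexI = c(2.39, -2.43), sexS = c(-0.36, 0.05),
      sigmaInd = repairSigma(sigmaInd, spec, spec@indLevel),
      sigmaPair = repairSigma(sigmaPair, spec, spec@pairLevel),
      resVar = c(15.52, 9.85), resCov = -0.05)
  } else {
    spec <- dcsmSpec("fi", proportional = TRUE, indLevel = "full",
                     pairLevel = "full")
    sigmaInd <- symMat4(19.95, -3.15, 0.52, 0, 0, 0, 0, 0, 0, 0)
    sigmaPair <- symMat4(6.71, -0.91, 0.12, 0, 0, 0, 0, 0, 0, 0)
    params <- dcsmParams(
      muI = c(6.01, 0), muS = c(-0.69, 0), beta = c(0.15, 0),
      sexI = c(2.39, 0), sexS = c(-0.36, 0),
      sigmaInd = repairSigma(sigmaInd, spec, spec@indLevel),
      sigmaPair = repairSigma(sigmaPair, spec, spec@pairLevel),
      resVar = c(15.52, 1), resCov = 0)
  }
  list(spec = spec, params = params)
}
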