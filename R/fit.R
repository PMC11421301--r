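# FIML maximization, standard errors, and default start values.

# Data-driven default start: means from the earliest populated bin,
# slopes from per-person least-squares slopes, beta = gamma = 0,
# diagonal factor covariances sized from the trait's marginal variance.
defaultStart <- function(spec, data) {
  tr <- spec@traits
  nT <- length(tr)
  obs <- data@observations
  muI <- muS <- rep(0, 2)
  resVar <- c(1, 1)
  vI <- vS <- rep(1, 2)
  for (i in seq_len(nT)) {
    o <- obs[obs$trait == tr[i], , drop = FALSE]
    if (!nrow(o)) stop("no observations for trait ", tr[i])
    v <- var(o$value)
    if (!is.finite(v) || v <= 0) v <- 1
    bin0 <- o$value[o$bin == min(o$bin)]
    fitLm <- lm(value ~ bin, data = o)
    muI[i] <- if (length(bin0) >= 5L) mean(bin0) else unname(coef(fitLm)[1])
    # per-person least-squares slopes where >= 2 visits
    spl <- split(o, o$personId)
    sl <- vapply(spl, function(d) {
      if (nrow(d) < 2L || length(unique(d$bin)) < 2L) return(NA_real_)
      unname(coef(lm(value ~ bin, data = d))[2])
    }, numeric(1))
    sl <- sl[is.finite(sl)]
    muS[i] <- if (length(sl) >= 5L) mean(sl) else unname(coef(fitLm)[2])
    resVar[i] <- max(0.5 * var(resid(fitLm)), 1e-3 * v)
    vI[i] <- max(0.3 * v, 1e-3)
    vS[i] <- max(0.3 * v / 50, 1e-5)
  }
  diagSig <- function(frac) {
    d <- rep(0, 4)
    for (i in seq_len(nT)) {
      d[2 * i - 1] <- frac * vI[i]
      d[2 * i] <- frac * vS[i]
    }
    diag(d, 4)
  }
  dcsmParams(muI = muI, muS = muS, beta = c(0, 0), gamma = c(0, 0),
             sexI = c(0, 0), sexS = c(0, 0),
             sigmaInd = diagSig(1), sigmaPair = diagSig(0.3),
             resVar = resVar, resCov = 0)
}

#' Fit a dual change score model by FIML
#'
#' Maximizes the casewise multivariate-normal log-likelihood over the
#' free parameters of \code{spec}. Covariance blocks are optimized
#' through triangular square-root factors so every iterate is positive
#' semi-definite; residual variances through logs. Quasi-Newton (BFGS)
#' runs are restarted from the previous optimum until the relative
#' objective change falls below 1e-8; convergence additionally requires
#' a small gradient relative to the objective magnitude. Standard errors
#' come from the observed information matrix at the optimum, mapped to
#' the natural scale by the delta method.
#'
#' @param spec a [DcsmSpec-class].
#' @param data a [PairDataset-class] on the same grid.
#' @param start optional [DcsmParams-class] start values (e.g. a warm
#'   start from a nested or encompassing fit); default data-driven.
#' @param computeSE compute standard errors (numerical Hessian; skip to
#'   save time in simulation loops). Default TRUE.
#' @param control list: \code{maxit} per BFGS run (default 600),
#'   \code{maxRestarts} (default 4), \code{reltol} (default 1e-10),
#'   \code{gradTol} relative gradient tolerance (default 1e-4).
#' @return A [DcsmFit-class]. Non-convergence is reported through the
#'   \code{converged} flag, never silently.
#' @export
fitDcsm <- function(spec, data, start = NULL, computeSE = TRUE,
                    control = list()) {
  stopifnot(is(spec, "DcsmSpec"), is(data, "PairDataset"))
  validObject(spec)
  ctl <- list(maxit = 600L, maxRestarts = 4L, reltol = 1e-10,
              gradTol = 1e-4)
  ctl[names(control)] <- control
  template <- paramTemplate(spec)
  prep <- prepareFimlData(data, spec)
  if (!length(unlist(prep$val))) stop("dataset has no observations")

  negll <- local({
    nEval <- 0L
    function(phi) {
      nEval <<- nEval + 1L
      p <- tryCatch(unpackParams(phi, spec, template),
                    error = function(e) NULL)
      if (is.null(p)) return(1e10)
      ll <- tryCatch(fimlLoglikValue(spec, p, prep)[1],
                     error = function(e) NA_real_)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  })
  getNEval <- function() environment(negll)$nEval

  p0 <- if (is.null(start)) defaultStart(spec, data) else start
  phi <- packParams(p0, spec, template)
  if (!is.finite(negll(phi)) || negll(phi) >= 1e10)
    stop("start values yield a non-finite likelihood")

  value <- Inf
  code <- 1L
  grad <- NULL
  gradOk <- FALSE
  for (r in seq_len(ctl$maxRestarts)) {
    opt <- optim(phi, negll, method = "BFGS",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                                ndeps = rep(1e-5, length(phi)),
                                parscale = pmax(abs(phi), 0.1)))
    improved <- (value - opt$value) > 1e-8 * (abs(opt$value) + 1)
    phi <- opt$par
    value <- opt$value
    code <- opt$convergence
    if (!improved && code == 0L) {
      # restarting BFGS resets its curvature approximation; keep going
      # until the gradient criterion holds or restarts are exhausted
      grad <- numGradient(negll, phi)
      gradOk <- max(abs(grad)) < ctl$gradTol * (1 + abs(value))
      if (gradOk) break
    }
  }
  if (is.null(grad)) {
    grad <- numGradient(negll, phi)
    gradOk <- max(abs(grad)) < ctl$gradTol * (1 + abs(value))
  }
  converged <- (code == 0L) && gradOk

  est <- unpackParams(phi, spec, template)
  natural <- naturalParams(est, spec, template)
  se <- setNames(rep(NA_real_, length(natural)), names(natural))
  if (computeSE) {
    H <- tryCatch(optimHess(phi, negll), error = function(e) NULL)
    covPhi <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(covPhi)) {
      J <- numJacobian(function(x)
        naturalParams(unpackParams(x, spec, template), spec, template), phi)
      covNat <- J %*% covPhi %*% t(J)
      d <- diag(covNat)
      se[d >= 0] <- sqrt(d[d >= 0])
      se[d < 0] <- NA_real_
    }
  }

  new("DcsmFit", spec = spec, params = est, estimates = natural, se = se,
      loglik = -value, nFree = nrow(template), converged = converged,
      nEval = as.integer(getNEval()),
      details = list(gradMax = max(abs(grad)), optimCode = code,
                     start = packParams(p0, spec, template),
                     nPairs = length(prep$pairIds),
                     nObs = length(unlist(prep$val))))
}
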