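# Synthetic twin-cohort generator: observation schedules emulating the
# SATSA design, generative simulation from the model, and parameter
# recovery experiments.

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

sampleDesignImpl <- function(design) {
  n <- design@nIndividuals
  nPairsComplete <- floor(n * design@pairFraction / 2)
  nSingles <- n - 2L * nPairsComplete
  nUnits <- nPairsComplete + nSingles
  unitSex <- rbinom(nUnits, 1L, design@sexRatio)
  unitZyg <- sample(names(design@zygosityProbs), nUnits, replace = TRUE,
                    prob = design@zygosityProbs)
  unitSize <- c(rep(2L, nPairsComplete), rep(1L, nSingles))
  pairId <- sprintf("F%05d", seq_len(nUnits))
  personPair <- rep(pairId, unitSize)
  personSex <- rep(unitSex, unitSize)         # same-sex pairs
  personZyg <- rep(unitZyg, unitSize)
  personId <- sprintf("P%05d", seq_along(personPair))
  nWaves <- sample(seq_along(design@waveCountProbs), length(personId),
                   replace = TRUE, prob = design@waveCountProbs)
  rows <- vector("list", length(personId))
  for (i in seq_along(personId)) {
    k <- nWaves[i]
    entry <- runif(1, design@entryAgeRange[1], design@entryAgeRange[2])
    sp <- if (k > 1L) runif(k - 1L, design@waveSpacing[1],
                            design@waveSpacing[2]) else numeric()
    ages <- entry + cumsum(c(0, sp))
    rows[[i]] <- data.frame(personId = personId[i], pairId = personPair[i],
                            sex = personSex[i], zygosity = personZyg[i],
                            wave = seq_len(k), age = ages,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Sample an observation schedule
#'
#' Draws persons (same-sex twin pairs plus singletons), sexes, zygosity
#' and raw visit ages from a [StudyDesign-class]. Visit ages may exceed
#' the grid; they are dropped later when the dataset is built, as in the
#' real pipeline. Deterministic given the seed.
#'
#' @param design a [StudyDesign-class].
#' @param seed integer seed.
#' @return data.frame with one row per scheduled visit: personId,
#'   pairId, sex, zygosity, wave, age.
#' @export
sampleDesign <- function(design, seed = 1L) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  withSeed(seed, sampleDesignImpl(design))
}

# Draw n deviates from N(0, Sigma) with Sigma possibly singular.
rmvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  C <- safeCholLower(Sigma)
  matrix(rnorm(n * k), n, k) %*% t(C)
}

#' Simulate a twin-pair dataset from the model
#'
#' Runs the dual change score model generatively: pair-level growth
#' factors shared by co-twins, individual-level factors, latent
#' trajectories by the forward recursion (constant + proportional +
#' coupling change), sex effects on the factor means, and occasion
#' residuals with the within-bin cross-trait covariance. Only scheduled
#' visits inside the age grid are kept; everything else is missing.
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class] of generating values.
#' @param design a [StudyDesign-class].
#' @param seed integer seed.
#' @param clipFI clip trait 1 to [0, 100] (stress test; the Gaussian
#'   model itself has no bounds). Default FALSE.
#' @return A [PairDataset-class].
#' @export
simulateDataset <- function(spec, params, design, seed = 1L,
                            clipFI = FALSE) {
  stopifnot(is(spec, "DcsmSpec"), is(params, "DcsmParams"),
            is(design, "StudyDesign"))
  validObject(params)
  withSeed(seed, {
    sched <- sampleDesignImpl(design)
    sched$bin <- assignAgeBin(sched$age, spec@grid)
    sched <- sched[!is.na(sched$bin), , drop = FALSE]
    # same-bin repeats cannot occur when spacing exceeds the bin width,
    # but guard deterministically anyway
    sched <- sched[order(sched$personId, sched$age), , drop = FALSE]
    sched <- sched[!duplicated(sched[, c("personId", "bin")]), , drop = FALSE]

    persons <- unique(sched[, c("personId", "pairId", "sex", "zygosity")])
    nP <- nrow(persons)
    nT <- length(spec@traits)
    nb <- nBins(spec)
    k <- 2L * nT
    L <- buildLatentLoadings(spec, params)
    Si <- maskSigma(params@sigmaInd[seq_len(k), seq_len(k), drop = FALSE],
                    spec, spec@indLevel)
    Sp <- maskSigma(params@sigmaPair[seq_len(k), seq_len(k), drop = FALSE],
                    spec, spec@pairLevel)
    pairIds <- unique(persons$pairId)
    zPair <- rmvn(length(pairIds), Sp)
    zInd <- rmvn(nP, Si)
    m0 <- factorMeans(spec, params, 0)
    sShift <- factorMeans(spec, params, 1) - m0
    fac <- matrix(m0, nP, k, byrow = TRUE) +
      outer(persons$sex, sShift) +
      zPair[match(persons$pairId, pairIds), , drop = FALSE] + zInd
    latent <- fac %*% t(L)              # nP x (nT*nb), trait-major

    # occasion residuals per kept visit
    Rbin <- matrix(0, nT, nT)
    diag(Rbin) <- params@resVar[seq_len(nT)]
    if (nT == 2L && spec@residCross) Rbin[1, 2] <- Rbin[2, 1] <- params@resCov
    eps <- rmvn(nrow(sched), Rbin)

    pidx <- match(sched$personId, persons$personId)
    rec <- data.frame(person_id = sched$personId, pair_id = sched$pairId,
                      sex = sched$sex, zygosity = sched$zygosity,
                      age = sched$age, stringsAsFactors = FALSE)
    for (i in seq_len(nT)) {
      v <- latent[cbind(pidx, (i - 1L) * nb + sched$bin + 1L)] + eps[, i]
      if (clipFI && i == 1L) v <- pmin(pmax(v, 0), 100)
      rec[[spec@traits[i]]] <- v
    }
    buildPairDataset(rec, grid = spec@grid,
                     traits = setNames(spec@traits, spec@traits))
  })
}

#' Simulate complete twin pairs as a moment-check matrix
#'
#' Draws fully observed twin pairs (every bin, both twins) and returns
#' them as a matrix over the pair layout of [impliedMoments()], for
#' Monte-Carlo checks of the analytic moments.
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class].
#' @param nPairs number of pairs.
#' @param sexes sexes of twin 1 and 2 (fixed across pairs).
#' @param seed integer seed.
#' @return numeric matrix nPairs x (2 * nTraits * nBins).
#' @export
simulatePairMatrix <- function(spec, params, nPairs, sexes = c(0, 0),
                               seed = 1L) {
  stopifnot(length(sexes) == 2L)
  withSeed(seed, {
    nT <- length(spec@traits)
    nb <- nBins(spec)
    k <- 2L * nT
    L <- buildLatentLoadings(spec, params)
    Si <- maskSigma(params@sigmaInd[seq_len(k), seq_len(k), drop = FALSE],
                    spec, spec@indLevel)
    Sp <- maskSigma(params@sigmaPair[seq_len(k), seq_len(k), drop = FALSE],
                    spec, spec@pairLevel)
    R <- residualMatrix(spec, params)
    cholR <- safeCholLower(R)
    zP <- rmvn(nPairs, Sp)
    out <- matrix(0, nPairs, 2L * nT * nb)
    for (tw in 1:2) {
      fac <- matrix(factorMeans(spec, params, sexes[tw]), nPairs, k,
                    byrow = TRUE) + zP + rmvn(nPairs, Si)
      eps <- matrix(rnorm(nPairs * nT * nb), nPairs) %*% t(cholR)
      out[, (tw - 1L) * nT * nb + seq_len(nT * nb)] <- fac %*% t(L) + eps
    }
    out
  })
}

#' Parameter recovery experiment
#'
#' Simulates replicate datasets from known generating values, fits the
#' model to each, and summarizes recovery: per-parameter mean estimate,
#' bias, empirical SD, Monte-Carlo SE of the mean, mean reported SE, and
#' coverage of nominal 95% Wald intervals. Replicates that fail to
#' converge are counted and excluded from the summaries.
#'
#' @param spec a [DcsmSpec-class].
#' @param params generating [DcsmParams-class].
#' @param design a [StudyDesign-class].
#' @param nReps number of replicates (>= 1).
#' @param seed integer seed; replicate r uses seed + r.
#' @param computeSE compute per-fit standard errors (needed for
#'   coverage; skip to save time). Default TRUE.
#' @param fitControl control list passed to [fitDcsm()].
#' @return list of class \code{RecoveryReport}: \code{summary}
#'   data.frame, \code{estimates} matrix (replicates x parameters),
#'   \code{se} matrix, \code{loglik}, \code{converged}, \code{nReps},
#'   \code{nUsed}.
#' @export
recoveryExperiment <- function(spec, params, design, nReps = 10L,
                               seed = 1L, computeSE = TRUE,
                               fitControl = list()) {
  stopifnot(nReps >= 1L)
  truth <- naturalParams(params, spec)
  est <- se <- matrix(NA_real_, nReps, length(truth),
                      dimnames = list(NULL, names(truth)))
  ll <- rep(NA_real_, nReps)
  conv <- rep(FALSE, nReps)
  for (r in seq_len(nReps)) {
    sr <- (seed + r) %% .Machine$integer.max
    dat <- simulateDataset(spec, params, design, seed = sr)
    fit <- tryCatch(
      fitDcsm(spec, dat, computeSE = computeSE, control = fitControl),
      error = function(e) NULL)
    if (is.null(fit)) next
    est[r, ] <- fit@estimates[colnames(est)]
    se[r, ] <- fit@se[colnames(se)]
    ll[r] <- fit@loglik
    conv[r] <- fit@converged
  }
  use <- conv
  nUsed <- sum(use)
  if (nUsed == 0L) stop("no replicate converged")
  meanEst <- colMeans(est[use, , drop = FALSE])
  empSD <- apply(est[use, , drop = FALSE], 2, sd)
  meanSE <- colMeans(se[use, , drop = FALSE], na.rm = TRUE)
  covered <- abs(est[use, , drop = FALSE] -
                   matrix(truth, nUsed, length(truth), byrow = TRUE)) <=
    qnorm(0.975) * se[use, , drop = FALSE]
  coverage <- colMeans(covered, na.rm = TRUE)
  summary <- data.frame(
    parameter = names(truth), truth = unname(truth),
    meanEst = unname(meanEst), bias = unname(meanEst - truth),
    empSD = unname(empSD),
    mcSE = unname(empSD / sqrt(nUsed)),
    meanSE = unname(meanSE), coverage = unname(coverage),
    row.names = NULL)
  structure(list(summary = summary, estimates = est, se = se,
                 loglik = ll, converged = conv,
                 nReps = nReps, nUsed = nUsed, seed = seed),
            class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, digits = 4, ...) {
  cat(sprintf("Recovery experiment: %d/%d replicates converged\n",
              x$nUsed, x$nReps))
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}
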