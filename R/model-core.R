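# Reduced form of the dual change score model: forward-recursion factor
# loadings, model-implied moments over the pair layout, and the FIML
# log-likelihood.

# Active factor indices (into the order I1, S1, I2, S2) for a spec and a
# level selector ("full"/"intercept"/"none" per trait).
activeFactors <- function(spec, level = NULL) {
  nT <- length(spec@traits)
  base <- seq_len(2L * nT)          # I1,S1[,I2,S2]
  if (is.null(level)) return(base)
  keep <- logical(2L * nT)
  for (i in seq_len(nT)) {
    keep[2L * i - 1L] <- level[i] %in% c("full", "intercept")
    keep[2L * i] <- level[i] == "full"
  }
  base[keep]
}

# Zero out covariance entries that the spec fixes (inactive factors).
maskSigma <- function(S, spec, level) {
  nT <- length(spec@traits)
  k <- 2L * nT
  act <- activeFactors(spec, level)
  M <- matrix(0, k, k)
  M[act, act] <- S[act, act]
  M
}

#' Latent loading matrix by forward recursion
#'
#' Expresses each trait's latent true score at every bin as a linear
#' combination of the growth factors (I1, S1[, I2, S2]). The recursion
#' is the dual change score update: the latent score at bin t equals the
#' score at t-1 plus a constant change (alpha = 1 times the slope
#' factor), a proportional change (beta times the trait's own previous
#' score), and, in bivariate models, coupling (gamma times the other
#' trait's previous score). Bin 0 loads only on the intercepts.
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class].
#' @return matrix of dimension (nTraits * nBins) x (2 * nTraits); rows
#'   are trait-major (trait 1 bins 0..T-1, then trait 2), columns are
#'   the factors (I1, S1[, I2, S2]).
#' @examples
#' sp <- dcsmSpec("fi", grid = ageGrid(nBins = 4))
#' # with beta = 0 the recursion collapses to a linear growth curve:
#' buildLatentLoadings(sp, dcsmParams())
#' @export
buildLatentLoadings <- function(spec, params) {
  nT <- length(spec@traits)
  nb <- nBins(spec)
  k <- 2L * nT
  # transition on the trait scores and constant-change injection
  A <- diag(1 + params@beta[seq_len(nT)], nT)
  Sinj <- matrix(0, nT, k)
  Sinj[1L, 2L] <- 1
  if (nT == 2L) {
    A[1L, 2L] <- params@gamma[["to1"]]
    A[2L, 1L] <- params@gamma[["to2"]]
    Sinj[2L, 4L] <- 1
  }
  ell <- matrix(0, nT, k)            # loadings of the current bin
  ell[1L, 1L] <- 1
  if (nT == 2L) ell[2L, 3L] <- 1
  L <- matrix(0, nT * nb, k)
  rowAt <- function(trait, bin) (trait - 1L) * nb + bin + 1L
  L[rowAt(seq_len(nT), 0L), ] <- ell
  if (nb > 1L) for (t in seq_len(nb - 1L)) {
    ell <- A %*% ell + Sinj
    L[rowAt(seq_len(nT), t), ] <- ell
  }
  dimnames(L) <- list(
    paste(rep(spec@traits, each = nb), rep(0:(nb - 1L), nT), sep = "."),
    paste(rep(c("I", "S"), nT), rep(spec@traits, each = 2L), sep = ".")[seq_len(k)])
  L
}

# Occasion-residual covariance for one twin over the trait-major layout.
residualMatrix <- function(spec, params) {
  nT <- length(spec@traits)
  nb <- nBins(spec)
  R <- diag(rep(params@resVar[seq_len(nT)], each = nb), nT * nb)
  if (nT == 2L && spec@residCross) {
    idx <- seq_len(nb)
    R[cbind(idx, nb + idx)] <- params@resCov
    R[cbind(nb + idx, idx)] <- params@resCov
  }
  R
}

#' Index layout of a pair's observed variables
#'
#' @param spec a [DcsmSpec-class].
#' @return data.frame with columns \code{row}, \code{twin} (1/2),
#'   \code{trait}, \code{bin} (0-based).
#' @export
momentLayout <- function(spec) {
  nT <- length(spec@traits)
  nb <- nBins(spec)
  data.frame(row = seq_len(2L * nT * nb),
             twin = rep(1:2, each = nT * nb),
             trait = rep(rep(spec@traits, each = nb), 2L),
             bin = rep(rep(0:(nb - 1L), nT), 2L))
}

# Factor means at a given sex (0 = man reference, 1 = woman).
factorMeans <- function(spec, params, sex) {
  nT <- length(spec@traits)
  m <- as.vector(rbind(params@muI[seq_len(nT)], params@muS[seq_len(nT)]))
  s <- as.vector(rbind(params@sexI[seq_len(nT)], params@sexS[seq_len(nT)]))
  m + sex * s
}

#' Model-implied moments for one twin pair
#'
#' Mean vector and covariance matrix of the stacked observed variables
#' (twin 1's trait-by-bin block, then twin 2's). The covariance is the
#' individual-level factor covariance propagated within each twin, plus
#' the pair-level factor covariance shared across co-twins, plus the
#' occasion residual structure (per-trait variances on the diagonal of
#' every bin; a within-person within-bin covariance between the two
#' traits; zero residual covariance across twins and across bins). Sex
#' enters the means only.
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class].
#' @param sexes length-2 vector, sex (0/1) of twin 1 and twin 2.
#' @return An [ImpliedMoments-class].
#' @export
impliedMoments <- function(spec, params, sexes = c(0, 0)) {
  stopifnot(length(sexes) == 2L, all(sexes %in% 0:1))
  validObject(params)
  core <- impliedMomentsCore(spec, params, sexes, guard = TRUE)
  new("ImpliedMoments", mean = core$mean, cov = core$cov,
      layout = momentLayout(spec))
}

# Allocation-light version used inside optimization loops; `guard`
# re-checks PSD of the factor covariances (the optimizer's square-root
# parameterization guarantees it, so the check is skipped there).
impliedMomentsCore <- function(spec, params, sexes = c(0, 0),
                               guard = FALSE) {
  nT <- length(spec@traits)
  k <- 2L * nT
  L <- buildLatentLoadings(spec, params)
  Si <- maskSigma(params@sigmaInd[seq_len(k), seq_len(k), drop = FALSE],
                  spec, spec@indLevel)
  Sp <- maskSigma(params@sigmaPair[seq_len(k), seq_len(k), drop = FALSE],
                  spec, spec@pairLevel)
  if (guard) {
    guardPsd(Si, "sigmaInd")
    guardPsd(Sp, "sigmaPair")
  }
  within <- L %*% Si %*% t(L) + residualMatrix(spec, params)
  across <- L %*% Sp %*% t(L)
  # enforce exact symmetry (the products are symmetric only in exact
  # arithmetic, and the Cholesky kernel requires a symmetric matrix)
  across <- (across + t(across)) / 2
  diagBlock <- within + across
  diagBlock <- (diagBlock + t(diagBlock)) / 2
  n1 <- nT * nBins(spec)
  cov <- matrix(0, 2L * n1, 2L * n1)
  cov[1:n1, 1:n1] <- diagBlock
  cov[n1 + 1:n1, n1 + 1:n1] <- diagBlock
  cov[1:n1, n1 + 1:n1] <- across
  cov[n1 + 1:n1, 1:n1] <- across
  mu <- c(L %*% factorMeans(spec, params, sexes[1]),
          L %*% factorMeans(spec, params, sexes[2]))
  list(mean = as.numeric(mu), cov = cov, loadings = L)
}

# PSD guard: eigenvalues >= -1e-10 are tolerated (clipped implicitly by
# downstream Cholesky of pattern submatrices); harder violations error.
guardPsd <- function(S, what) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10)
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 what, ev))
  invisible(TRUE)
}

# Precompute the FIML inputs for a dataset under a spec: per-pair
# 0-based index vectors into the pair layout, observed values, and the
# twins' sexes. Pairs with no observations contribute empty entries.
prepareFimlData <- function(data, spec) {
  stopifnot(is(data, "PairDataset"))
  miss <- setdiff(spec@traits, data@traits)
  if (length(miss))
    stop("dataset lacks trait(s): ", paste(miss, collapse = ", "))
  nT <- length(spec@traits)
  nb <- nBins(spec)
  if (nb != nBins(data) || spec@grid@startAge != data@grid@startAge ||
      spec@grid@binWidth != data@grid@binWidth)
    stop("spec and dataset must share the same age grid")
  per <- data@persons
  obs <- data@observations
  obs <- obs[obs$trait %in% spec@traits, , drop = FALSE]
  traitIdx <- match(obs$trait, spec@traits)
  member <- per$member[match(obs$personId, per$personId)]
  row0 <- (member - 1L) * nT * nb + (traitIdx - 1L) * nb + obs$bin # 0-based
  pairIds <- sort(unique(per$pairId))
  pairOf <- per$pairId[match(obs$personId, per$personId)]
  sexA <- integer(length(pairIds))
  sexB <- integer(length(pairIds))
  idx <- vector("list", length(pairIds))
  val <- vector("list", length(pairIds))
  spl <- split(seq_len(nrow(obs)), factor(pairOf, levels = pairIds))
  for (i in seq_along(pairIds)) {
    pid <- pairIds[i]
    members <- per[per$pairId == pid, , drop = FALSE]
    sexA[i] <- members$sex[members$member == 1L]
    sexB[i] <- if (any(members$member == 2L))
      members$sex[members$member == 2L] else 0L
    rows <- spl[[i]]
    o <- order(row0[rows])
    idx[[i]] <- as.integer(row0[rows][o])
    val[[i]] <- as.numeric(obs$value[rows][o])
  }
  list(pairIds = pairIds, idx = idx, val = val,
       sexA = sexA, sexB = sexB)
}

#' Full-information maximum likelihood log-likelihood
#'
#' Sum over twin pairs of the multivariate-normal log-density of each
#' pair's observed sub-vector under the corresponding sub-moments of
#' [impliedMoments()], i.e. the casewise (FIML) likelihood under
#' arbitrary missingness. Pairs with no observations contribute 0.
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class].
#' @param data a [PairDataset-class] on the same grid.
#' @param prep optional precomputed result of the internal data
#'   preparation (used to avoid re-indexing inside optimization loops).
#' @return scalar log-likelihood.
#' @export
fimlLoglik <- function(spec, params, data, prep = NULL) {
  if (is.null(prep)) prep <- prepareFimlData(data, spec)
  ll <- fimlLoglikValue(spec, params, prep)
  if (is.na(ll[1])) {
    bad <- ll[2] + 1
    stop(sprintf(
      "singular pattern covariance for pair '%s' (%d observed entries)",
      prep$pairIds[bad], length(prep$idx[[bad]])))
  }
  ll[1]
}

# Kernel call; returns c(loglik, failIndex0based or -1). NA loglik on a
# singular pattern covariance.
fimlLoglikValue <- function(spec, params, prep) {
  nT <- length(spec@traits)
  nb <- nBins(spec)
  mom <- impliedMomentsCore(spec, params, sexes = c(0, 0))
  sexShift <- as.numeric(mom$loadings %*%
                           (factorMeans(spec, params, 1) -
                              factorMeans(spec, params, 0)))
  zero <- numeric(nT * nb)
  addA <- c(sexShift, zero)
  addB <- c(zero, sexShift)
  fiml_kernel(mom$mean, addA, addB, mom$cov, prep$idx, prep$val,
              as.integer(prep$sexA), as.integer(prep$sexB))
}
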