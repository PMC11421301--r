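# Free-parameter template for a spec, the unconstrained <-> natural
# reparameterization used by the optimizer, and numerical-derivative
# helpers.
#
# Covariance blocks are parameterized through lower-triangular square
# roots (Sigma = C C'), so every iterate is positive semi-definite;
# residual variances through logs; the residual cross-trait covariance
# through a tanh-bounded correlation.

factorLabels <- function(spec) {
  nT <- length(spec@traits)
  paste(rep(c("I", "S"), nT), rep(spec@traits, each = 2L),
        sep = ".")[seq_len(2L * nT)]
}

# Template: data.frame describing the unconstrained vector phi.
paramTemplate <- function(spec) {
  tr <- spec@traits
  nT <- length(tr)
  fl <- factorLabels(spec)
  rows <- list()
  add <- function(phi, natural, block) {
    rows[[length(rows) + 1L]] <<- data.frame(
      phi = phi, natural = natural, block = block,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nT)) {
    add(paste0("mean.I.", tr[i]), paste0("mean.I.", tr[i]), "meanI")
    add(paste0("mean.S.", tr[i]), paste0("mean.S.", tr[i]), "meanS")
  }
  for (i in seq_len(nT)) if (spec@proportional[i])
    add(paste0("beta.", tr[i]), paste0("beta.", tr[i]), "beta")
  if (nT == 2L) {
    if (spec@coupling[["to1"]])
      add(paste0("gamma.", tr[2], ".to.", tr[1]),
          paste0("gamma.", tr[2], ".to.", tr[1]), "gammaTo1")
    if (spec@coupling[["to2"]])
      add(paste0("gamma.", tr[1], ".to.", tr[2]),
          paste0("gamma.", tr[1], ".to.", tr[2]), "gammaTo2")
  }
  if (spec@sexEffects) for (i in seq_len(nT)) {
    add(paste0("sex.I.", tr[i]), paste0("sex.I.", tr[i]), "sexI")
    add(paste0("sex.S.", tr[i]), paste0("sex.S.", tr[i]), "sexS")
  }
  for (lev in c("ind", "pair")) {
    sel <- if (lev == "ind") spec@indLevel else spec@pairLevel
    act <- activeFactors(spec, sel)
    if (length(act)) {
      for (j in seq_along(act)) for (i in j:length(act)) {
        nat <- if (i == j) paste0(lev, ".var.", fl[act[i]]) else
          paste0(lev, ".cov.", fl[act[j]], ".", fl[act[i]])
        add(paste0("L.", lev, ".", i, ".", j), nat, paste0("chol.", lev))
      }
    }
  }
  for (i in seq_len(nT))
    add(paste0("log.res.var.", tr[i]), paste0("res.var.", tr[i]), "resVar")
  if (nT == 2L && spec@residCross)
    add("atanh.res.cor", "res.cov", "resCov")
  do.call(rbind, rows)
}

#' Number of free parameters of a specification
#'
#' @param spec a [DcsmSpec-class].
#' @return integer count of free parameters.
#' @export
nFreeParams <- function(spec) nrow(paramTemplate(spec))

# Lower-triangular Cholesky-like square root tolerant of PSD-but-
# singular input (eigenvalue clipping at 0).
safeCholLower <- function(S) {
  out <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  R <- e$vectors %*% diag(sqrt(ev), length(ev))
  # reduce to lower-triangular via QR of the transpose
  qrf <- qr(t(R))
  Lt <- qr.R(qrf)
  L <- t(Lt)
  # fix signs so the diagonal is non-negative
  s <- sign(diag(L)); s[s == 0] <- 1
  L %*% diag(s, ncol(L))
}

# phi (unconstrained) -> DcsmParams
unpackParams <- function(phi, spec, template = paramTemplate(spec)) {
  stopifnot(length(phi) == nrow(template))
  names(phi) <- template$phi
  tr <- spec@traits
  nT <- length(tr)
  g <- function(nm) if (nm %in% names(phi)) unname(phi[[nm]]) else 0
  muI <- muS <- beta <- sexI <- sexS <- c(0, 0)
  for (i in seq_len(nT)) {
    muI[i] <- g(paste0("mean.I.", tr[i]))
    muS[i] <- g(paste0("mean.S.", tr[i]))
    beta[i] <- g(paste0("beta.", tr[i]))
    sexI[i] <- g(paste0("sex.I.", tr[i]))
    sexS[i] <- g(paste0("sex.S.", tr[i]))
  }
  gamma <- c(0, 0)
  if (nT == 2L) {
    gamma[1] <- g(paste0("gamma.", tr[2], ".to.", tr[1]))
    gamma[2] <- g(paste0("gamma.", tr[1], ".to.", tr[2]))
  }
  buildSigma <- function(lev, sel) {
    act <- activeFactors(spec, sel)
    S4 <- matrix(0, 4, 4)
    if (!length(act)) return(S4)
    m <- length(act)
    C <- matrix(0, m, m)
    for (j in seq_len(m)) for (i in j:m)
      C[i, j] <- g(paste0("L.", lev, ".", i, ".", j))
    S <- C %*% t(C)
    S4[act, act] <- S
    S4
  }
  sigmaInd <- buildSigma("ind", spec@indLevel)
  sigmaPair <- buildSigma("pair", spec@pairLevel)
  resVar <- c(1, 1)
  for (i in seq_len(nT)) resVar[i] <- exp(g(paste0("log.res.var.", tr[i])))
  resCov <- 0
  if (nT == 2L && spec@residCross)
    resCov <- tanh(g("atanh.res.cor")) * sqrt(prod(resVar[1:2]))
  dcsmParams(muI = muI, muS = muS, beta = beta, gamma = gamma,
             sexI = sexI, sexS = sexS, sigmaInd = sigmaInd,
             sigmaPair = sigmaPair, resVar = resVar, resCov = resCov)
}

# DcsmParams -> phi (used for start values and warm starts)
packParams <- function(params, spec, template = paramTemplate(spec)) {
  tr <- spec@traits
  nT <- length(tr)
  phi <- setNames(numeric(nrow(template)), template$phi)
  set <- function(nm, v) if (nm %in% names(phi)) phi[[nm]] <<- v
  for (i in seq_len(nT)) {
    set(paste0("mean.I.", tr[i]), params@muI[i])
    set(paste0("mean.S.", tr[i]), params@muS[i])
    set(paste0("beta.", tr[i]), params@beta[i])
    set(paste0("sex.I.", tr[i]), params@sexI[i])
    set(paste0("sex.S.", tr[i]), params@sexS[i])
  }
  if (nT == 2L) {
    set(paste0("gamma.", tr[2], ".to.", tr[1]), params@gamma[["to1"]])
    set(paste0("gamma.", tr[1], ".to.", tr[2]), params@gamma[["to2"]])
  }
  for (lev in c("ind", "pair")) {
    sel <- if (lev == "ind") spec@indLevel else spec@pairLevel
    act <- activeFactors(spec, sel)
    if (length(act)) {
      S <- (if (lev == "ind") params@sigmaInd else params@sigmaPair)[act, act,
                                                                     drop = FALSE]
      C <- safeCholLower(S)
      for (j in seq_along(act)) for (i in j:length(act))
        set(paste0("L.", lev, ".", i, ".", j), C[i, j])
    }
  }
  for (i in seq_len(nT))
    set(paste0("log.res.var.", tr[i]), log(params@resVar[i]))
  if (nT == 2L && spec@residCross) {
    r <- params@resCov / sqrt(prod(params@resVar[1:2]))
    set("atanh.res.cor", atanh(max(min(r, 0.999), -0.999)))
  }
  phi
}

# Natural-scale vector of the free parameters (the quantities a results
# table reports: means, dynamics, sex effects, variances/covariances,
# residuals).
naturalParams <- function(params, spec, template = paramTemplate(spec)) {
  tr <- spec@traits
  nT <- length(tr)
  fl <- factorLabels(spec)
  out <- setNames(numeric(nrow(template)), template$natural)
  set <- function(nm, v) if (nm %in% names(out)) out[[nm]] <<- v
  for (i in seq_len(nT)) {
    set(paste0("mean.I.", tr[i]), params@muI[i])
    set(paste0("mean.S.", tr[i]), params@muS[i])
    set(paste0("beta.", tr[i]), params@beta[i])
    set(paste0("sex.I.", tr[i]), params@sexI[i])
    set(paste0("sex.S.", tr[i]), params@sexS[i])
  }
  if (nT == 2L) {
    set(paste0("gamma.", tr[2], ".to.", tr[1]), params@gamma[["to1"]])
    set(paste0("gamma.", tr[1], ".to.", tr[2]), params@gamma[["to2"]])
  }
  for (lev in c("ind", "pair")) {
    sel <- if (lev == "ind") spec@indLevel else spec@pairLevel
    act <- activeFactors(spec, sel)
    S <- if (lev == "ind") params@sigmaInd else params@sigmaPair
    for (j in seq_along(act)) for (i in j:length(act)) {
      nm <- if (i == j) paste0(lev, ".var.", fl[act[i]]) else
        paste0(lev, ".cov.", fl[act[j]], ".", fl[act[i]])
      set(nm, S[act[i], act[j]])
    }
  }
  for (i in seq_len(nT)) set(paste0("res.var.", tr[i]), params@resVar[i])
  if (nT == 2L && spec@residCross) set("res.cov", params@resCov)
  out
}

#' Nearest positive semi-definite repair by eigenvalue clipping
#'
#' Published covariance tables rounded to two decimals are often not
#' jointly PSD, especially when variance components sit near the zero
#' boundary. This clips eigenvalues below a small floor (a fraction of
#' the leading eigenvalue) and reconstructs a symmetric PSD matrix.
#'
#' @param S symmetric matrix.
#' @param floorFrac eigenvalue floor as a fraction of the leading
#'   eigenvalue. Default 1e-4.
#' @return a PSD matrix close to \code{S}.
#' @export
nearPsd <- function(S, floorFrac = 1e-4) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  fl <- floorFrac * max(e$values, 0)
  ev <- pmax(e$values, fl)
  out <- e$vectors %*% diag(ev, length(ev)) %*% t(e$vectors)
  (out + t(out)) / 2
}

# Central-difference gradient and Jacobian.
numGradient <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    g[i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  g
}

numJacobian <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    J[, i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  rownames(J) <- names(f0)
  J
}
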