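# Descriptive and graphical outputs: model-implied trajectories,
# vector fields with a 95% data ellipse, and baseline correlations.

#' Model-implied mean trajectories
#'
#' Population-average latent mean per bin, averaging the sex-specific
#' curves with weights (1 - sexMix, sexMix). Shares the loading code
#' path with [impliedMoments()], so the curve equals the mean component
#' of the implied moments bin by bin.
#'
#' @param x a [DcsmFit-class] (must be converged) or a
#'   [DcsmSpec-class] together with \code{params}.
#' @param params a [DcsmParams-class]; required when \code{x} is a spec.
#' @param sexMix proportion of women in the averaged curve, in [0, 1].
#' @return data.frame with columns trait, bin, age, value.
#' @export
trajectoryCurve <- function(x, params = NULL, sexMix = 0) {
  if (is(x, "DcsmFit")) {
    if (!x@converged) stop("trajectoryCurve requires a converged fit")
    spec <- x@spec
    params <- x@params
  } else {
    spec <- x
    stopifnot(is(spec, "DcsmSpec"), is(params, "DcsmParams"))
  }
  stopifnot(sexMix >= 0, sexMix <= 1)
  nT <- length(spec@traits)
  nb <- nBins(spec)
  L <- buildLatentLoadings(spec, params)
  m <- (1 - sexMix) * (L %*% factorMeans(spec, params, 0)) +
    sexMix * (L %*% factorMeans(spec, params, 1))
  data.frame(trait = rep(spec@traits, each = nb),
             bin = rep(0:(nb - 1L), nT),
             age = binAge(spec@grid, rep(0:(nb - 1L), nT)),
             value = as.numeric(m))
}

#' Vector field of expected one-step changes
#'
#' Evaluates the fitted change equations on a lattice of (clock, FI)
#' values: the expected FI change at state (c, f) is
#' muS_FI + beta_FI * f + gamma_to1 * (paceScale * c), and analogously
#' for the clock (reported back on the original clock scale). Arrows are
#' exact evaluations of the fitted equations, not numerical differences.
#' The 95% ellipse comes from the sample mean and covariance of the
#' observed baseline (clock, FI) pairs at the chi-square(2) 95% radius.
#'
#' @param fit a converged bivariate [DcsmFit-class].
#' @param data the [PairDataset-class] supplying baseline points for the
#'   ellipse.
#' @param clockGrid lattice of clock values on the original scale
#'   (default 0.7-1.4 by 0.05, a pace-of-aging range).
#' @param fiGrid lattice of FI values (default 0-45 by 2.5).
#' @param paceScale internal clock rescaling (default 10 when the
#'   dataset's pace trait was rescaled, else 1).
#' @param sexMix proportion of women entering the slope means.
#' @return list of class \code{VectorField}: \code{arrows} data.frame
#'   (clock, fi, dClock, dFi), \code{ellipse} (center, radii, angle,
#'   polygon), \code{n} baseline points used.
#' @export
vectorField <- function(fit, data,
                        clockGrid = seq(0.7, 1.4, by = 0.05),
                        fiGrid = seq(0, 45, by = 2.5),
                        paceScale = if (data@paceRescaled) 10 else 1,
                        sexMix = 0) {
  stopifnot(is(fit, "DcsmFit"))
  if (length(fit@spec@traits) != 2L)
    stop("vectorField requires a bivariate fit")
  if (!fit@converged) stop("vectorField requires a converged fit")
  p <- fit@params
  muS <- p@muS + sexMix * p@sexS
  g <- expand.grid(clock = clockGrid, fi = fiGrid)
  clockModel <- paceScale * g$clock   # model (possibly x10) scale
  dFi <- muS[1] + p@beta[1] * g$fi + p@gamma[["to1"]] * clockModel
  dClockModel <- muS[2] + p@beta[2] * clockModel + p@gamma[["to2"]] * g$fi
  arrows <- data.frame(clock = g$clock, fi = g$fi,
                       dClock = dClockModel / paceScale, dFi = dFi)

  base <- baselineTable(data)
  cc <- complete.cases(base[, data@traits])
  n <- sum(cc)
  ellipse <- NULL
  if (n >= 3L) {
    pts <- cbind(clock = base[[data@traits[2]]][cc] / paceScale,
                 fi = base[[data@traits[1]]][cc])
    ctr <- colMeans(pts)
    S <- cov(pts)
    e <- eigen(S, symmetric = TRUE)
    r <- sqrt(qchisq(0.95, df = 2))
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- cbind(cos(th), sin(th)) %*%
      diag(r * sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
    ellipse <- list(center = ctr,
                    radii = r * sqrt(pmax(e$values, 0)),
                    angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                    polygon = data.frame(clock = ctr[1] + circ[, 1],
                                         fi = ctr[2] + circ[, 2]))
  }
  structure(list(arrows = arrows, ellipse = ellipse, n = n,
                 paceScale = paceScale),
            class = "VectorField")
}

# Per-person baseline (first observed visit) values, one row per person.
baselineTable <- function(data) {
  long <- exportLong(data)
  long <- long[order(long$person_id, long$age), , drop = FALSE]
  long[!duplicated(long$person_id), , drop = FALSE]
}

#' Baseline correlations between the two traits
#'
#' Pearson correlation between the traits at each person's first
#' observed visit, raw and adjusted for chronological age (both traits
#' residualized on exact age, residuals correlated). Pairwise-complete
#' cases.
#'
#' @param data a bivariate [PairDataset-class].
#' @return list: \code{r} raw correlation, \code{rAgeAdjusted} partial
#'   correlation given age, \code{n} complete baseline cases.
#' @export
baselineCorrelations <- function(data) {
  stopifnot(is(data, "PairDataset"))
  if (length(data@traits) != 2L)
    stop("baselineCorrelations requires two traits")
  base <- baselineTable(data)
  v1 <- base[[data@traits[1]]]
  v2 <- base[[data@traits[2]]]
  cc <- complete.cases(v1, v2, base$age)
  n <- sum(cc)
  if (n < 3L) stop("fewer than 3 complete baseline cases")
  r <- cor(v1[cc], v2[cc])
  r1 <- resid(lm(v1[cc] ~ base$age[cc]))
  r2 <- resid(lm(v2[cc] ~ base$age[cc]))
  list(r = r, rAgeAdjusted = cor(r1, r2), n = n)
}

#' Plot model-implied trajectories
#'
#' @param curve output of [trajectoryCurve()].
#' @param data optional [PairDataset-class] whose observed values are
#'   drawn as background points.
#' @return a ggplot object, faceted by trait.
#' @export
plotTrajectories <- function(curve, data = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = age, y = value))
  if (!is.null(data)) {
    obs <- data@observations
    obs$age <- binAge(data@grid, obs$bin)
    p <- p + ggplot2::geom_point(
      data = data.frame(age = obs$age, value = obs$value,
                        trait = obs$trait),
      alpha = 0.2, size = 0.6, colour = "grey50")
  }
  p + ggplot2::geom_line(linewidth = 1.1) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Trait value") +
    ggplot2::theme_minimal()
}

#' Plot a vector field with its 95% data ellipse
#'
#' @param vf output of [vectorField()].
#' @param arrowScale multiplier applied to arrow lengths for display.
#' @return a ggplot object.
#' @export
plotVectorField <- function(vf, arrowScale = 1) {
  a <- vf$arrows
  p <- ggplot2::ggplot(a, ggplot2::aes(x = clock, y = fi)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = clock + arrowScale * dClock,
                   yend = fi + arrowScale * dFi),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 0.3, colour = "steelblue") +
    ggplot2::labs(x = "Clock (original scale)", y = "Frailty index (%)") +
    ggplot2::theme_minimal()
  if (!is.null(vf$ellipse))
    p <- p + ggplot2::geom_path(data = vf$ellipse$polygon,
                                linetype = "dashed")
  p
}
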