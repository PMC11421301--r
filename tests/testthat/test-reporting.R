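# Trajectory curves, vector fields, and baseline correlations.

mkFit <- function(spec, params, converged = TRUE) {
  tpl <- dcsm:::paramTemplate(spec)
  est <- dcsm:::naturalParams(params, spec, tpl)
  new("DcsmFit", spec = spec, params = params, estimates = est,
      se = est + NA_real_, loglik = 0, nFree = nrow(tpl),
      converged = converged, nEval = 0L, details = list())
}

test_that("trajectoryCurve equals the mean component of impliedMoments", {
  toy <- toyBivariate(nBins = 6L)
  for (sex in 0:1) {
    tc <- trajectoryCurve(toy$spec, toy$params, sexMix = sex)
    mom <- impliedMoments(toy$spec, toy$params, sexes = c(sex, sex))
    expect_equal(tc$value, mom@mean[1:12], tolerance = 1e-12)
  }
  # and the mixed curve is the weighted average of the two
  t0 <- trajectoryCurve(toy$spec, toy$params, sexMix = 0)
  t1 <- trajectoryCurve(toy$spec, toy$params, sexMix = 1)
  tm <- trajectoryCurve(toy$spec, toy$params, sexMix = 0.3)
  expect_equal(tm$value, 0.7 * t0$value + 0.3 * t1$value, tolerance = 1e-12)
})

test_that("beta = 0 gives a straight line; sex effects shift the whole curve", {
  sp <- dcsmSpec("fi", proportional = FALSE, grid = ageGrid(nBins = 8L))
  p <- dcsmParams(muI = 5, muS = 0.8, sexI = 2.39, sexS = -0.36)
  tc <- trajectoryCurve(sp, p, sexMix = 0)
  expect_equal(diff(tc$value), rep(0.8, 7))
  # women's curve: intercept +2.39, slope 0.8 - 0.36
  tw <- trajectoryCurve(sp, p, sexMix = 1)
  expect_equal(tw$value - tc$value, 2.39 + (0:7) * (-0.36), tolerance = 1e-12)
})

test_that("vector field arrows are exact evaluations of the change equations", {
  m <- presetModel("pace")
  fit <- mkFit(m$spec, m$params)
  ds <- simulateDataset(m$spec, m$params, studyDesign(nIndividuals = 80L),
                        seed = 30)
  vf <- vectorField(fit, ds, paceScale = 10)
  a <- vf$arrows
  p <- m$params
  expect_equal(a$dFi,
               p@muS[1] + p@beta[1] * a$fi + p@gamma[["to1"]] * 10 * a$clock,
               tolerance = 1e-12)
  # no coupling into the clock: along vertical lines (fixed clock) the
  # clock arrow component is constant
  expect_equal(a$dClock, rep((p@muS[2]) / 10, nrow(a)) +
                 p@beta[2] * a$clock, tolerance = 1e-12)
  # positive coupling: at fixed FI the FI change grows with the clock
  f15 <- a[a$fi == 15, ]
  expect_true(all(diff(f15$dFi[order(f15$clock)]) > 0))

  # all dynamics zero -> all arrows vanish
  p0 <- dcsmParams(resVar = c(1, 1))
  fit0 <- mkFit(m$spec, p0)
  vf0 <- vectorField(fit0, ds, paceScale = 10)
  expect_true(all(vf0$arrows$dFi == 0) && all(vf0$arrows$dClock == 0))

  # univariate or unconverged fits are rejected
  u <- presetModel("fiUnivariate")
  expect_error(vectorField(mkFit(u$spec, u$params), ds), "bivariate")
  expect_error(vectorField(mkFit(m$spec, m$params, converged = FALSE), ds),
               "converged")
})

test_that("the 95% ellipse covers about 95% of matching normal samples", {
  m <- presetModel("pace")
  fit <- mkFit(m$spec, m$params)
  ds <- simulateDataset(m$spec, m$params,
                        studyDesign(nIndividuals = 524L), seed = 44)
  vf <- vectorField(fit, ds, paceScale = 10)
  ell <- vf$ellipse
  expect_false(is.null(ell))
  # draw a large sample from the normal with the ellipse's moments and
  # count the fraction inside (Mahalanobis radius at chi-square(2) 95%)
  base <- dcsm:::baselineTable(ds)
  pts <- cbind(base$clock / 10, base$fi)
  pts <- pts[stats::complete.cases(pts), ]
  ctr <- colMeans(pts)
  S <- cov(pts)
  set.seed(1)
  Z <- matrix(rnorm(2 * 20000), ncol = 2) %*% chol(S)
  md <- rowSums((Z %*% solve(S)) * Z)
  expect_lt(abs(mean(md <= qchisq(0.95, 2)) - 0.95), 0.01)
  # the observed points themselves land inside at roughly that rate
  d2 <- mahalanobis(pts, ctr, S)
  expect_lt(abs(mean(d2 <= qchisq(0.95, 2)) - 0.95), 0.04)
})

test_that("baseline correlations: identity, age-driven, and analytic cases", {
  # clock identical to fi -> r = 1
  rec <- data.frame(person_id = sprintf("p%02d", 1:30),
                    pair_id = sprintf("f%02d", 1:30), sex = 0L,
                    age = runif(30, 50, 88), fi = rnorm(30, 10, 3))
  rec$clock <- rec$fi
  ds <- buildPairDataset(rec, traits = c(fi = "fi", clock = "clock"))
  bc <- baselineCorrelations(ds)
  expect_equal(bc$r, 1, tolerance = 1e-12)
  expect_equal(bc$n, 30L)

  # traits driven by age plus independent noise: the raw correlation is
  # strong but the age-adjusted one collapses towards zero
  set.seed(11)
  n2 <- 200L
  rec2 <- data.frame(person_id = sprintf("q%03d", 1:n2),
                     pair_id = sprintf("g%03d", 1:n2), sex = 0L,
                     age = runif(n2, 50, 88))
  rec2$fi <- 2 + 0.3 * rec2$age + rnorm(n2, sd = 0.8)
  rec2$clock <- -1 + 0.5 * rec2$age + rnorm(n2, sd = 0.8)
  ds2 <- buildPairDataset(rec2, traits = c(fi = "fi", clock = "clock"))
  bc2 <- baselineCorrelations(ds2)
  expect_gt(bc2$r, 0.8)
  expect_lt(abs(bc2$rAgeAdjusted), 3 / sqrt(n2))

  # too few complete cases
  rec3 <- rec[1:2, ]
  ds3 <- buildPairDataset(rec3, traits = c(fi = "fi", clock = "clock"))
  expect_error(baselineCorrelations(ds3), "fewer than 3")

  # synthetic data with known factor structure: everyone enters at the
  # first bin, so the baseline correlation has an analytic counterpart
  m <- presetModel("pcclock")
  d <- studyDesign(nIndividuals = 2000L, pairFraction = 0, sexRatio = 0,
                   waveCountProbs = c(1, rep(0, 5)),
                   entryAgeRange = c(50, 51.9))
  dsx <- simulateDataset(m$spec, m$params, d, seed = 9)
  mom <- impliedMoments(m$spec, m$params, sexes = c(0, 0))
  nb <- nBins(m$spec)
  rTheory <- mom@cov[1, nb + 1] / sqrt(mom@cov[1, 1] * mom@cov[nb + 1, nb + 1])
  bcx <- baselineCorrelations(dsx)
  expect_lt(abs(bcx$r - rTheory), 3 / sqrt(bcx$n))
})

test_that("plot builders return ggplot objects", {
  m <- presetModel("pace")
  fit <- mkFit(m$spec, m$params)
  ds <- simulateDataset(m$spec, m$params, studyDesign(nIndividuals = 40L),
                        seed = 3)
  expect_s3_class(plotTrajectories(trajectoryCurve(fit), ds), "ggplot")
  expect_s3_class(plotVectorField(vectorField(fit, ds, paceScale = 10)),
                  "ggplot")
})
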