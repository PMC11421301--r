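# FIML maximization, standard errors, likelihood ratio machinery, and
# the selection ladders.

test_that("free-parameter counts follow the specification switches", {
  pace <- presetModel("pace")$spec
  pc <- presetModel("pcclock")$spec
  # pace: 4 means + beta + gamma + 4 sex + 10 ind chol + 6 pair chol
  #       + 2 res var + res cov
  expect_equal(nFreeParams(pace), 29L)
  expect_equal(nFreeParams(pc), 32L)
  uni <- presetModel("fiUnivariate")$spec
  expect_equal(nFreeParams(uni), 12L)
  # a bidirectional vs no-coupling contrast frees exactly 2 parameters
  bid <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, FALSE),
                  coupling = c(TRUE, TRUE))
  none <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, FALSE),
                   coupling = c(FALSE, FALSE))
  expect_equal(nFreeParams(bid) - nFreeParams(none), 2L)
})

test_that("a saturated-mean toy reproduces the analytic maximum likelihood", {
  sp <- dcsmSpec("fi", proportional = FALSE, indLevel = "none",
                 pairLevel = "none", sexEffects = FALSE,
                 grid = ageGrid(nBins = 2L))
  set.seed(3)
  n <- 40L
  rec <- data.frame(person_id = rep(sprintf("p%02d", 1:n), each = 2),
                    pair_id = rep(sprintf("f%02d", 1:n), each = 2),
                    sex = 0L, age = rep(c(50.5, 52.5), n),
                    fi = rnorm(2 * n, rep(c(5, 7), n), 2))
  ds <- buildPairDataset(rec, grid = sp@grid, traits = c(fi = "fi"))
  fit <- fitDcsm(sp, ds)
  expect_true(fit@converged)
  # analytic MLE: sample means per bin; pooled (MLE, /2n) residual variance
  y0 <- rec$fi[rec$age < 52]
  y1 <- rec$fi[rec$age > 52]
  s2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) / (2 * n)
  expect_equal(unname(fit@estimates["mean.I.fi"]), mean(y0), tolerance = 1e-5)
  expect_equal(unname(fit@estimates["mean.S.fi"]), mean(y1) - mean(y0),
               tolerance = 1e-5)
  expect_equal(unname(fit@estimates["res.var.fi"]), s2, tolerance = 1e-4)
  # and the textbook SE of the bin-0 mean
  expect_equal(unname(fit@se["mean.I.fi"]), sqrt(s2 / n), tolerance = 1e-3)
})

test_that("likelihood ratio arithmetic: df, flooring, p-values, nesting guard", {
  full <- presetModel("pace")$spec
  nested <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, FALSE),
                     coupling = c(FALSE, FALSE),
                     pairLevel = c("full", "intercept"))
  mkFit <- function(spec, ll) {
    tpl <- dcsm:::paramTemplate(spec)
    est <- setNames(numeric(nrow(tpl)), tpl$natural)
    new("DcsmFit", spec = spec, params = dcsmParams(), estimates = est,
        se = est + NA_real_, loglik = ll, nFree = nrow(tpl),
        converged = TRUE, nEval = 1L, details = list())
  }
  # identical log-likelihoods: statistic 0, p = 1
  lrt <- likelihoodRatioTest(mkFit(full, -100), mkFit(nested, -100))
  expect_equal(lrt@statistic, 0)
  expect_equal(lrt@pValue, 1)
  expect_equal(lrt@df, 1L)
  # chi-square tail identity at the 5% critical value, df = 1
  lrt2 <- likelihoodRatioTest(mkFit(full, -100), mkFit(nested, -100 - 3.8415 / 2))
  expect_equal(lrt2@pValue, 0.05, tolerance = 1e-3)
  # slightly negative statistics are floored with a warning
  expect_warning(
    lrt3 <- likelihoodRatioTest(mkFit(full, -100.0000005), mkFit(nested, -100)),
    "floored")
  expect_equal(lrt3@statistic, 0)
  # non-nested specs are rejected
  other <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, TRUE),
                    coupling = c(FALSE, FALSE),
                    pairLevel = c("full", "intercept"))
  expect_error(likelihoodRatioTest(mkFit(nested, -1), mkFit(other, -2)),
               "not nested")
})

test_that("the objective is invariant to square-root reparameterization", {
  toy <- toyBivariate(nBins = 4L)
  ds <- simulateDataset(toy$spec, toy$params,
                        studyDesign(nIndividuals = 80L), seed = 21)
  tpl <- dcsm:::paramTemplate(toy$spec)
  phi <- dcsm:::packParams(toy$params, toy$spec, tpl)
  prep <- dcsm:::prepareFimlData(ds, toy$spec)
  ll <- dcsm:::fimlLoglikValue(toy$spec,
                               dcsm:::unpackParams(phi, toy$spec, tpl), prep)[1]
  # flip the sign of a whole Cholesky column: a different valid square
  # root of the same covariance matrix
  phi2 <- phi
  cols <- grep("^L\\.ind\\.[0-9]\\.2$", names(phi2))
  phi2[cols] <- -phi2[cols]
  p2 <- dcsm:::unpackParams(phi2, toy$spec, tpl)
  expect_equal(dcsm:::fimlLoglikValue(toy$spec, p2, prep)[1], ll,
               tolerance = 1e-12)
  expect_equal(dcsm:::naturalParams(p2, toy$spec, tpl),
               dcsm:::naturalParams(dcsm:::unpackParams(phi, toy$spec, tpl),
                                    toy$spec, tpl),
               tolerance = 1e-12)
})

test_that("a null coupling is recovered within sampling error", {
  m <- presetModel("pace")
  p0 <- m$params
  p0@gamma[["to1"]] <- 0
  # keep the FI trajectory in a realistic range without the coupling input
  p0@muS[1] <- -0.4
  ds <- simulateDataset(m$spec, p0, halfDesign(), seed = 31)
  fit <- fitDcsm(m$spec, ds)
  expect_true(fit@converged)
  g <- fit@estimates["gamma.clock.to.fi"]
  se <- fit@se["gamma.clock.to.fi"]
  expect_true(is.finite(se) && se > 0)
  expect_lt(abs(g), 3 * se)
})

test_that("reported SEs track the replicate SD for mean-structure parameters", {
  m <- presetModel("fiUnivariate")
  rec <- recoveryExperiment(m$spec, m$params, halfDesign(), nReps = 10L,
                            seed = 7, computeSE = TRUE)
  expect_gte(rec$nUsed, 8L)
  s <- rec$summary
  meanPars <- grep("^(mean|beta|sex)", s$parameter)
  # variance components near the zero boundary have skewed sampling
  # distributions; the SE/SD comparison is meaningful for the interior
  # (mean-structure) parameters
  expect_true(all(abs(s$meanSE[meanPars] / s$empSD[meanPars] - 1) < 0.5))
  # and the replicate means recover the generating values
  expect_true(all(abs(s$bias[meanPars]) < 4 * s$mcSE[meanPars]))
})

test_that("univariate selection retains a real proportional effect", {
  m <- presetModel("fiUnivariate")
  ds <- simulateDataset(m$spec, m$params, studyDesign(), seed = 13)
  sel <- univariateSelection(ds, "fi", computeSE = FALSE)
  expect_equal(sel$retained, "full")
  expect_lt(sel$lrt@pValue, 0.05)
  expect_gte(sel$fits$full@loglik, sel$fits$linear@loglik)
  expect_error(univariateSelection(ds, "clock"))
})

test_that("bivariate selection identifies a strong unidirectional coupling", {
  # strong-coupling scenario for a sharp selection check (the slope mean
  # is offset so the mean trajectory stays in a realistic range)
  m <- presetModel("pace")
  p <- m$params
  p@gamma[["to1"]] <- 2.5
  p@muS[1] <- p@muS[1] - (2.5 - 1.19) * p@muI[2]
  picks <- character(3)
  for (r in 1:3) {
    ds <- simulateDataset(m$spec, p, halfDesign(), seed = 100 + r)
    sel <- bivariateSelection(ds, proportional = c(TRUE, FALSE),
                              pairLevel = c("full", "intercept"),
                              computeSE = FALSE)
    picks[r] <- sel$selected[1]
  }
  expect_gte(sum(picks == "to1"), 2L)   # majority of replicates
})
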