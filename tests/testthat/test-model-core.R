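# Forward-recursion loadings, implied moments, and the FIML objective.

test_that("with beta = gamma = 0 the loadings collapse to a linear growth curve", {
  sp <- dcsmSpec(c("fi", "clock"), proportional = FALSE,
                 grid = ageGrid(nBins = 6L))
  L <- buildLatentLoadings(sp, dcsmParams())
  nb <- 6L
  for (t in 0:(nb - 1L)) {
    expect_equal(unname(L[t + 1L, ]), c(1, t, 0, 0))          # fi row
    expect_equal(unname(L[nb + t + 1L, ]), c(0, 0, 1, t))     # clock row
  }
})

test_that("univariate proportional recursion matches a step-by-step oracle", {
  m <- presetModel("fiUnivariate")
  tc <- trajectoryCurve(m$spec, m$params, sexMix = 0)
  # independent oracle: iterate f <- (1 + 0.15) f - 0.69 from 6.01
  f <- 6.01
  oracle <- f
  for (t in 1:19) {
    f <- 1.15 * f - 0.69
    oracle <- c(oracle, f)
  }
  expect_equal(tc$value, oracle, tolerance = 1e-12)
  expect_equal(tc$value[tc$bin == 5], 7.436014, tolerance = 1e-6)
})

test_that("raising the clock intercept propagates monotonically through coupling", {
  toy <- toyBivariate(nBins = 8L)
  p0 <- toy$params
  curves0 <- trajectoryCurve(toy$spec, p0)
  p1 <- p0
  p1@muI[2] <- p1@muI[2] + 0.5
  curves1 <- trajectoryCurve(toy$spec, p1)
  dFi <- curves1$value[curves1$trait == "fi"] -
    curves0$value[curves0$trait == "fi"]
  expect_equal(dFi[1], 0)                       # bin 0 loads on intercepts only
  expect_true(all(diff(dFi) > 0))               # strictly growing influence
})

test_that("implied covariance honours the pair/individual/residual structure", {
  toy <- toyBivariate(nBins = 3L)
  sp <- toy$spec
  p <- toy$params
  nb <- 3L
  half <- 2L * nb

  # pair variance zero -> cross-twin block exactly zero
  p0 <- p
  p0@sigmaPair <- matrix(0, 4, 4)
  mom <- impliedMoments(sp, p0)
  expect_equal(mom@cov[1:half, half + 1:half], matrix(0, half, half))

  # all factor variances zero -> residual-only block structure
  p1 <- p0
  p1@sigmaInd <- matrix(0, 4, 4)
  mom1 <- impliedMoments(sp, p1)
  W <- mom1@cov[1:half, 1:half]
  expect_equal(diag(W), rep(p@resVar[1:2], each = nb))
  expect_equal(W[1, nb + 1], p@resCov)     # fi/clock, same twin, same bin
  expect_equal(W[1, nb + 2], 0)            # different bins uncorrelated
  expect_equal(W[1, 2], 0)

  # individual variance zero -> co-twin latent parts perfectly shared
  p2 <- p
  p2@sigmaInd <- matrix(0, 4, 4)
  mom2 <- impliedMoments(sp, p2)
  within <- mom2@cov[1:half, 1:half] - dcsm:::residualMatrix(sp, p2)
  across <- mom2@cov[1:half, half + 1:half]
  expect_equal(within, across, tolerance = 1e-12)

  # exchangeability: swapping twin sexes permutes the mean blocks
  mA <- impliedMoments(sp, p, sexes = c(1, 0))
  mB <- impliedMoments(sp, p, sexes = c(0, 1))
  expect_equal(mA@mean[1:half], mB@mean[half + 1:half])
  expect_equal(mA@mean[half + 1:half], mB@mean[1:half])

  # PSD within tolerance
  ev <- eigen(mom@cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8)
})

test_that("FIML equals the dense multivariate-normal density on complete data", {
  toy <- toyBivariate(nBins = 3L)
  Y <- simulatePairMatrix(toy$spec, toy$params, 2, sexes = c(1, 0), seed = 7)
  ds <- pairMatrixToDataset(Y, toy$spec, sexes = c(1, 0))
  mom <- impliedMoments(toy$spec, toy$params, sexes = c(1, 0))
  oracle <- sum(apply(Y, 1, denseMvnLoglik, mu = mom@mean, S = mom@cov))
  expect_equal(fimlLoglik(toy$spec, toy$params, ds), oracle,
               tolerance = 1e-10)
})

test_that("an all-missing person leaves the log-likelihood unchanged", {
  toy <- toyBivariate(nBins = 3L)
  Y <- simulatePairMatrix(toy$spec, toy$params, 3, seed = 2)
  ds <- pairMatrixToDataset(Y, toy$spec)
  ll <- fimlLoglik(toy$spec, toy$params, ds)
  # append a person with no observations at all
  per <- rbind(ds@persons,
               data.frame(personId = "ghost", pairId = "fghost",
                          member = 1L, sex = 0L, zygosity = "unknown"))
  ds2 <- new("PairDataset", grid = ds@grid, persons = per,
             observations = ds@observations, traits = ds@traits,
             paceRescaled = FALSE, paceTrait = NA_character_)
  expect_equal(fimlLoglik(toy$spec, toy$params, ds2), ll, tolerance = 1e-12)
})

test_that("the likelihood is invariant to pair order and twin labels", {
  toy <- toyBivariate(nBins = 3L)
  Y <- simulatePairMatrix(toy$spec, toy$params, 5, seed = 9)
  ds <- pairMatrixToDataset(Y, toy$spec)
  ll <- fimlLoglik(toy$spec, toy$params, ds)

  # permute pair order
  ord <- c(3, 1, 5, 2, 4)
  per <- ds@persons
  per$pairId <- factor(per$pairId, levels = unique(per$pairId)[ord])
  per <- per[order(per$pairId, per$member), ]
  per$pairId <- as.character(per$pairId)
  ds2 <- new("PairDataset", grid = ds@grid, persons = per,
             observations = ds@observations, traits = ds@traits,
             paceRescaled = FALSE, paceTrait = NA_character_)
  expect_equal(fimlLoglik(toy$spec, toy$params, ds2), ll, tolerance = 1e-12)

  # relabel twin A/B within every pair (sexes equal across twins here)
  per3 <- ds@persons
  per3$member <- 3L - per3$member
  per3 <- per3[order(per3$pairId, per3$member), ]
  ds3 <- new("PairDataset", grid = ds@grid, persons = per3,
             observations = ds@observations, traits = ds@traits,
             paceRescaled = FALSE, paceTrait = NA_character_)
  expect_equal(fimlLoglik(toy$spec, toy$params, ds3), ll, tolerance = 1e-10)
})

test_that("zero dynamics reduce the model to an independently coded growth curve", {
  # independently coded bivariate linear latent growth curve likelihood
  toy <- toyBivariate(nBins = 4L)
  sp <- dcsmSpec(c("fi", "clock"), proportional = FALSE,
                 coupling = FALSE, pairLevel = c("full", "intercept"),
                 grid = ageGrid(nBins = 4L))
  p <- toy$params
  p@beta <- c(0, 0)
  p@gamma[] <- 0
  Y <- simulatePairMatrix(sp, p, 6, sexes = c(1, 1), seed = 4)
  ds <- pairMatrixToDataset(Y, sp, sexes = c(1, 1))

  nb <- 4L
  Lgc <- cbind(1, 0:(nb - 1L))                   # growth-curve loadings
  L2 <- rbind(cbind(Lgc, matrix(0, nb, 2)), cbind(matrix(0, nb, 2), Lgc))
  act <- c(1, 2, 3)                              # pair level: fi full + clock int
  Sp4 <- p@sigmaPair
  R <- diag(rep(p@resVar[1:2], each = nb))
  R[cbind(1:nb, nb + 1:nb)] <- R[cbind(nb + 1:nb, 1:nb)] <- p@resCov
  within <- L2 %*% p@sigmaInd %*% t(L2) + R
  across <- L2 %*% Sp4 %*% t(L2)
  G <- rbind(cbind(within + across, across), cbind(across, within + across))
  fm <- c(p@muI[1] + p@sexI[1], p@muS[1] + p@sexS[1],
          p@muI[2] + p@sexI[2], p@muS[2] + p@sexS[2])
  mu <- rep(as.numeric(L2 %*% fm), 2)
  oracle <- sum(apply(Y, 1, denseMvnLoglik, mu = mu, S = G))
  expect_equal(fimlLoglik(sp, p, ds), oracle, tolerance = 1e-8)
})

test_that("a singular pattern covariance names the offending pair", {
  sp <- dcsmSpec("fi", proportional = FALSE, indLevel = "none",
                 pairLevel = "none", grid = ageGrid(nBins = 2L))
  p <- dcsmParams(muI = 5, resVar = c(0, 1))    # zero residual: singular
  rec <- data.frame(person_id = "a", pair_id = "fa", sex = 0L,
                    age = 50.5, fi = 5)
  ds <- buildPairDataset(rec, grid = sp@grid, traits = c(fi = "fi"))
  expect_error(fimlLoglik(sp, p, ds), "singular.*fa")
})
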