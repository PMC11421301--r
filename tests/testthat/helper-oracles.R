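# Independent oracles and fixture builders used across test files.

# Textbook multivariate-normal log-density (solve/determinant based, a
# code path independent of the package's per-pair Cholesky kernel).
denseMvnLoglik <- function(y, mu, S) {
  k <- length(mu)
  d <- y - mu
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            as.numeric(t(d) %*% solve(S) %*% d))
}

# Turn a complete pair matrix (rows = pairs, columns = the pair layout
# of impliedMoments) into a PairDataset, twin 1 with sex sexes[1].
pairMatrixToDataset <- function(Y, spec, sexes = c(0, 0)) {
  lay <- momentLayout(spec)
  n <- nrow(Y)
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(person_id = sprintf("p%04d_%d", i, lay$twin),
               pair_id = sprintf("f%04d", i),
               sex = sexes[lay$twin],
               age = spec@grid@startAge + spec@grid@binWidth * lay$bin + 0.01,
               trait = lay$trait, value = Y[i, lay$row],
               stringsAsFactors = FALSE)
  }))
  wide <- stats::reshape(rec, idvar = c("person_id", "pair_id", "sex", "age"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("value.", "", names(wide), fixed = TRUE)
  buildPairDataset(wide, grid = spec@grid,
                   traits = setNames(spec@traits, spec@traits))
}

# Small bivariate toy spec on a 3-bin grid (pace-like parameters).
toyBivariate <- function(nBins = 3L) {
  m <- presetModel("pace")
  spec <- dcsmSpec(c("fi", "clock"), proportional = c(TRUE, FALSE),
                   coupling = c(TRUE, FALSE),
                   pairLevel = c("full", "intercept"),
                   grid = ageGrid(nBins = nBins))
  list(spec = spec, params = m$params)
}

# Reduced synthetic design for calibration runs (half-size cohort; the
# type-I error of the likelihood ratio ladder does not depend on n).
halfDesign <- function() studyDesign(nIndividuals = 262L)
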