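# Age binning, frailty index computation, and assembly of long-format
# records into pair-structured datasets.

#' Assign ages to grid bins
#'
#' Bins are half-open: an age belongs to bin t when
#' \code{start + w*t <= age < start + w*(t+1)}; boundary ages fall in the
#' lower bin. Ages outside the grid (e.g. 90 and above on the default
#' grid, where late-life data are sparse and excluded) map to NA.
#'
#' @param age numeric vector of ages in years; must be finite.
#' @param grid an [AgeGrid-class].
#' @return integer vector of 0-based bin indices, NA where unassignable.
#' @examples
#' assignAgeBin(c(50, 68.2, 89.99, 90, 42), ageGrid())
#' @export
assignAgeBin <- function(age, grid = ageGrid()) {
  if (!is.numeric(age) || any(!is.finite(age)))
    stop("age must be finite numeric")
  t <- floor((age - grid@startAge) / grid@binWidth)
  t[t < 0 | t >= grid@nBins] <- NA
  as.integer(t)
}

#' Compute the frailty index from deficit items
#'
#' The deficit-accumulation frailty index: the sum of the deficit scores
#' divided by the number of items considered (non-missing), expressed as
#' a percentage 0-100. Items may be binary or ordinal in [0, 1]; missing
#' items reduce the denominator. A record with no available item has an
#' undefined FI and raises an error.
#'
#' @param items numeric vector of deficit scores in [0, 1] (NA =
#'   unavailable), or a matrix / data.frame with one record per row.
#' @param nItems expected item count (default 42); input with a
#'   different number of items is rejected to guard against truncated
#'   records. Use NULL to skip the check.
#' @return FI percentage(s) in [0, 100].
#' @examples
#' computeFrailtyIndex(c(rep(1, 21), rep(0, 21)))  # 50
#' computeFrailtyIndex(c(rep(1, 4), rep(0, 36), NA, NA))  # 100*4/40 = 10
#' @export
computeFrailtyIndex <- function(items, nItems = 42L) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1L)
  if (!is.null(nItems) && ncol(items) != nItems)
    stop(sprintf("expected %d deficit items per record, got %d",
                 nItems, ncol(items)))
  if (any(items < 0 | items > 1, na.rm = TRUE))
    stop("deficit items must lie in [0, 1]")
  avail <- rowSums(!is.na(items))
  if (any(avail == 0L))
    stop(sprintf("FI undefined: no available items in record(s) %s",
                 paste(which(avail == 0L), collapse = ", ")))
  fi <- 100 * rowSums(items, na.rm = TRUE) / avail
  if (nrow(items) == 1L) fi[[1L]] else fi
}

#' Build a pair-structured dataset from long-format records
#'
#' Places one row per person-visit onto the age grid and groups persons
#' into twin pairs. Visits at unassignable ages are dropped (count
#' reported via a message). When two visits of one person land in the
#' same bin, the chronologically earlier non-missing value is kept per
#' trait and a warning is issued. A pace-of-aging trait can be
#' multiplied by 10 on import (the scale on which these models are fit).
#'
#' @param records data.frame in long format, one row per person-visit.
#' @param grid an [AgeGrid-class].
#' @param traits named character vector mapping canonical trait names to
#'   column names, e.g. \code{c(fi = "fi", clock = "pace")}; length 1 or
#'   2. Canonical order matters: the first trait is trait 1 in model
#'   specs.
#' @param columns named character vector mapping the required id columns;
#'   defaults \code{c(person = "person_id", pair = "pair_id",
#'   sex = "sex", age = "age", zygosity = "zygosity")}. A missing
#'   zygosity column is tolerated (recorded as "unknown").
#' @param rescalePace multiply the pace trait by 10? Default FALSE.
#' @param paceTrait canonical name of the pace trait (default the second
#'   trait) — only used when \code{rescalePace} is TRUE.
#' @return A [PairDataset-class].
#' @export
buildPairDataset <- function(records, grid = ageGrid(), traits,
                             columns = c(person = "person_id",
                                         pair = "pair_id", sex = "sex",
                                         age = "age",
                                         zygosity = "zygosity"),
                             rescalePace = FALSE, paceTrait = NULL) {
  stopifnot(is.data.frame(records), length(traits) %in% 1:2)
  if (is.null(names(traits))) names(traits) <- traits
  def <- c(person = "person_id", pair = "pair_id", sex = "sex",
           age = "age", zygosity = "zygosity")
  def[names(columns)] <- columns
  columns <- def
  need <- c(columns[c("person", "pair", "sex", "age")], traits)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))

  personId <- as.character(records[[columns["person"]]])
  pairId <- as.character(records[[columns["pair"]]])
  sex <- as.integer(records[[columns["sex"]]])
  if (any(!sex %in% c(0L, 1L)))
    stop("sex must be coded 0 (man) / 1 (woman)")
  age <- as.numeric(records[[columns["age"]]])
  zyg <- if (columns["zygosity"] %in% names(records))
    as.character(records[[columns["zygosity"]]]) else
    rep("unknown", nrow(records))

  # a person must appear under a single pair id (and sex)
  pmap <- unique(data.frame(personId, pairId, sex, zyg,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(pmap$personId))
    stop("person(s) appear under more than one pairId/sex/zygosity: ",
         paste(unique(pmap$personId[duplicated(pmap$personId)]),
               collapse = ", "))
  if (any(table(pmap$pairId) > 2L))
    stop("pairId(s) with more than two persons")

  bin <- assignAgeBin(age, grid)
  nDropped <- sum(is.na(bin))
  if (nDropped > 0L)
    message(nDropped, " observation row(s) outside the age grid dropped")
  keep <- !is.na(bin)

  # long over traits
  obs <- do.call(rbind, lapply(names(traits), function(tn) {
    v <- as.numeric(records[[traits[[tn]]]])
    data.frame(personId = personId[keep], bin = bin[keep], age = age[keep],
               trait = tn, value = v[keep], stringsAsFactors = FALSE)
  }))
  obs <- obs[!is.na(obs$value), , drop = FALSE]

  # keep-first rule within (person, bin, trait): earliest raw age wins
  ord <- order(obs$personId, obs$trait, obs$bin, obs$age)
  obs <- obs[ord, , drop = FALSE]
  dup <- duplicated(obs[, c("personId", "bin", "trait")])
  if (any(dup)) {
    warning(sum(dup), " within-bin duplicate observation(s) dropped ",
            "(earliest visit kept)")
    obs <- obs[!dup, , drop = FALSE]
  }

  if (isTRUE(rescalePace)) {
    if (is.null(paceTrait)) paceTrait <- names(traits)[length(traits)]
    if (!paceTrait %in% names(traits))
      stop("paceTrait must be one of the canonical trait names")
    obs$value[obs$trait == paceTrait] <- 10 * obs$value[obs$trait == paceTrait]
  } else {
    paceTrait <- NA_character_
  }

  # member index within pair, ordered by personId for determinism
  pmap <- pmap[order(pmap$pairId, pmap$personId), , drop = FALSE]
  pmap$member <- as.integer(stats::ave(seq_len(nrow(pmap)), pmap$pairId,
                                       FUN = seq_along))
  persons <- data.frame(personId = pmap$personId, pairId = pmap$pairId,
                        member = pmap$member, sex = pmap$sex,
                        zygosity = pmap$zyg, stringsAsFactors = FALSE)
  rownames(persons) <- NULL
  rownames(obs) <- NULL

  new("PairDataset", grid = grid, persons = persons, observations = obs,
      traits = names(traits), paceRescaled = isTRUE(rescalePace),
      paceTrait = paceTrait)
}

#' Export a dataset to canonical long format
#'
#' One row per person-visit (person, pair, sex, zygosity, raw age of the
#' kept visit) with one column per trait. Values are exported on the
#' stored (possibly x10 pace) scale, so rebuilding with
#' \code{rescalePace = FALSE} reproduces the dataset exactly.
#'
#' @param dataset a [PairDataset-class].
#' @return data.frame in long format.
#' @export
exportLong <- function(dataset) {
  stopifnot(is(dataset, "PairDataset"))
  o <- dataset@observations
  if (!nrow(o)) {
    out <- dataset@persons[0, ]
    return(out)
  }
  key <- unique(o[, c("personId", "bin", "age")])
  for (tn in dataset@traits) {
    ot <- o[o$trait == tn, c("personId", "bin", "value")]
    names(ot)[3] <- tn
    key <- merge(key, ot, by = c("personId", "bin"), all.x = TRUE)
  }
  out <- merge(dataset@persons, key, by = "personId")
  out <- out[order(out$pairId, out$personId, out$bin), , drop = FALSE]
  data.frame(person_id = out$personId, pair_id = out$pairId,
             sex = out$sex, zygosity = out$zygosity, age = out$age,
             out[, dataset@traits, drop = FALSE],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a dataset
#'
#' @param dataset a [PairDataset-class].
#' @return A JSON-serializable list: persons, pairs, singletons,
#'   observation counts overall, per trait and per bin.
#' @export
datasetSummary <- function(dataset) {
  stopifnot(is(dataset, "PairDataset"))
  tb <- table(dataset@persons$pairId)
  perBin <- table(factor(dataset@observations$bin,
                         levels = 0:(nBins(dataset) - 1L)))
  list(nPersons = nrow(dataset@persons),
       nPairs = length(tb),
       nSingletons = sum(tb == 1L),
       nObservations = nrow(dataset@observations),
       observationsPerTrait = as.list(
         table(factor(dataset@observations$trait, levels = dataset@traits))),
       observationsPerBin = as.integer(perBin),
       traits = dataset@traits,
       paceRescaled = dataset@paceRescaled)
}
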