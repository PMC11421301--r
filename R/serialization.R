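# YAML/JSON round-tripping of model specifications and parameters, so
# fixtures and fitted configurations are self-documenting text files.

specToList <- function(spec) {
  list(traits = as.list(spec@traits),
       proportional = as.list(unname(spec@proportional)),
       coupling = as.list(unname(spec@coupling)),
       indLevel = as.list(unname(spec@indLevel)),
       pairLevel = as.list(unname(spec@pairLevel)),
       residCross = spec@residCross,
       sexEffects = spec@sexEffects,
       grid = list(startAge = spec@grid@startAge,
                   binWidth = spec@grid@binWidth,
                   nBins = spec@grid@nBins))
}

listToSpec <- function(x) {
  dcsmSpec(traits = unlist(x$traits),
           proportional = unlist(x$proportional),
           coupling = unlist(x$coupling),
           indLevel = unlist(x$indLevel),
           pairLevel = unlist(x$pairLevel),
           residCross = isTRUE(x$residCross),
           sexEffects = if (is.null(x$sexEffects)) TRUE else
             isTRUE(x$sexEffects),
           grid = ageGrid(x$grid$startAge, x$grid$binWidth, x$grid$nBins))
}

paramsToList <- function(params) {
  list(muI = params@muI, muS = params@muS, beta = params@beta,
       gamma = unname(params@gamma), sexI = params@sexI,
       sexS = params@sexS,
       sigmaInd = apply(params@sigmaInd, 1, as.numeric, simplify = FALSE),
       sigmaPair = apply(params@sigmaPair, 1, as.numeric, simplify = FALSE),
       resVar = params@resVar, resCov = params@resCov)
}

listToParams <- function(x) {
  dcsmParams(muI = unlist(x$muI), muS = unlist(x$muS),
             beta = unlist(x$beta), gamma = unlist(x$gamma),
             sexI = unlist(x$sexI), sexS = unlist(x$sexS),
             sigmaInd = do.call(rbind, lapply(x$sigmaInd, unlist)),
             sigmaPair = do.call(rbind, lapply(x$sigmaPair, unlist)),
             resVar = unlist(x$resVar), resCov = x$resCov)
}

#' Write a model configuration to YAML or JSON
#'
#' @param spec a [DcsmSpec-class].
#' @param params a [DcsmParams-class] (optional).
#' @param path output file; format chosen by extension (.yaml/.yml or
#'   .json).
#' @return the path, invisibly.
#' @export
writeDcsmConfig <- function(spec, params = NULL, path) {
  x <- list(spec = specToList(spec))
  if (!is.null(params)) x$params <- paramsToList(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

#' Read a model configuration written by [writeDcsmConfig()]
#'
#' @param path YAML or JSON file.
#' @return list with \code{spec} and (if present) \code{params}.
#' @export
readDcsmConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path)
  else stop("unsupported config extension: ", ext)
  out <- list(spec = listToSpec(x$spec))
  if (!is.null(x$params)) out$params <- listToParams(x$params)
  out
}
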