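#' Serialize / deserialize a calibrated PathwayModel
#'
#' Models are stored as JSON with a `format_version` field and full numeric
#' precision, so write followed by read reproduces the model exactly.
#'
#' @param model a [PathwayModel-class].
#' @param path file path (conventionally `*.json`).
#' @return `writePathwayModel()`: the path, invisibly;
#'   `readPathwayModel()`: the restored [PathwayModel-class].
#' @export
writePathwayModel <- function(model, path) {
  stopifnot(is(model, "PathwayModel"))
  obj <- list(
    format_version = model@formatVersion,
    pathway_name = model@pathwayName,
    prior_active = model@priorActive,
    log2_odds_cap = model@log2OddsCap,
    normalization = as.list(model@normalization),
    genes = model@genes,
    probesets = model@probesets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writePathwayModel
#' @export
readPathwayModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version))
    stop("not a pathway model file (no format_version field): ", path)
  m <- newPathwayModel(
    genes = as.data.frame(obj$genes, stringsAsFactors = FALSE),
    probesets = as.data.frame(obj$probesets, stringsAsFactors = FALSE),
    priorActive = obj$prior_active,
    normalization = c(lo = obj$normalization$lo, hi = obj$normalization$hi),
    pathwayName = obj$pathway_name,
    log2OddsCap = obj$log2_odds_cap)
  m@formatVersion <- obj$format_version
  m
}
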