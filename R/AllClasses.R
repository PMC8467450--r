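#' PathwayModel: a calibrated three-layer pathway-activity network
#'
#' Holds the full parameterization of the Bayesian network used to score
#' pathway activity: the prior on the latent activity node, one conditional
#' probability table (CPT) per target gene giving the probability that the
#' gene is transcribed when the pathway is active or inactive, two-state
#' Gaussian emission parameters per probeset, and the log2-odds anchors of
#' the 0-100 score normalization.
#'
#' @slot pathwayName single character, e.g. `"NFkB"`.
#' @slot priorActive prior probability that the pathway is active, in (0,1).
#' @slot genes data.frame with columns `symbol`, `direction` (`"up"` or
#'   `"down"`), `pTxActive`, `pTxInactive`.
#' @slot probesets data.frame with columns `probesetId`, `symbol`, `muLow`,
#'   `muHigh`, `sigma` (log2-intensity units; `muLow`/`muHigh` are the
#'   expected intensities when the gene is untranscribed / transcribed).
#' @slot normalization named numeric `c(lo = , hi = )`: log2-odds values
#'   mapped to scores 0 and 100.
#' @slot log2OddsCap symmetric cap on reported log2-odds (default 20).
#' @slot formatVersion serialization format version string.
#'
#' @seealso [newPathwayModel()], [defaultModel()], [calibrateModel()]
#' @export
setClass("PathwayModel",
  representation(
    pathwayName   = "character",
    priorActive   = "numeric",
    genes         = "data.frame",
    probesets     = "data.frame",
    normalization = "numeric",
    log2OddsCap   = "numeric",
    formatVersion = "character"
  )
)

setValidity("PathwayModel", function(object) {
  msg <- character()
  g <- object@genes
  p <- object@probesets
  if (length(object@priorActive) != 1L ||
      !is.finite(object@priorActive) ||
      object@priorActive <= 0 || object@priorActive >= 1)
    msg <- c(msg, "priorActive must be a single probability in (0, 1)")
  needG <- c("symbol", "direction", "pTxActive", "pTxInactive")
  needP <- c("probesetId", "symbol", "muLow", "muHigh", "sigma")
  if (!all(needG %in% names(g)))
    return(paste("genes must have columns:", paste(needG, collapse = ", ")))
  if (!all(needP %in% names(p)))
    return(paste("probesets must have columns:", paste(needP, collapse = ", ")))
  if (anyDuplicated(g$symbol))
    msg <- c(msg, "gene symbols must be unique")
  if (anyDuplicated(p$probesetId))
    msg <- c(msg, "probeset ids must be unique")
  if (!all(g$direction %in% c("up", "down")))
    msg <- c(msg, "gene direction must be 'up' or 'down'")
  pr <- c(g$pTxActive, g$pTxInactive)
  if (!all(is.finite(pr)) || any(pr < 0) || any(pr > 1))
    msg <- c(msg, "gene transcription probabilities must lie in [0, 1]")
  up <- g$direction == "up"
  if (any(up & !(g$pTxActive > g$pTxInactive)))
    msg <- c(msg, "up-responsive genes require pTxActive > pTxInactive")
  if (any(!up & !(g$pTxActive < g$pTxInactive)))
    msg <- c(msg, "down-responsive genes require pTxActive < pTxInactive")
  if (!all(p$symbol %in% g$symbol))
    msg <- c(msg, "every probeset must belong to a panel gene")
  if (!all(g$symbol %in% p$symbol))
    msg <- c(msg, "every gene needs at least one probeset")
  if (nrow(p) < nrow(g))
    msg <- c(msg, "total probeset count must be >= gene count")
  if (!all(is.finite(p$sigma)) || any(p$sigma <= 0))
    msg <- c(msg, "probeset sigma must be > 0")
  if (!all(is.finite(c(p$muLow, p$muHigh))))
    msg <- c(msg, "probeset means must be finite")
  nm <- object@normalization
  if (length(nm) != 2L || !all(c("lo", "hi") %in% names(nm)) ||
      !all(is.finite(nm)) || nm[["hi"]] <= nm[["lo"]])
    msg <- c(msg, "normalization must be c(lo =, hi =) with hi > lo")
  if (length(object@log2OddsCap) != 1L || object@log2OddsCap <= 0)
    msg <- c(msg, "log2OddsCap must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayModel
#'
#' Low-level constructor; most users will use [defaultModel()] or
#' [calibrateModel()].
#'
#' @param genes data.frame with columns `symbol`, `direction`, `pTxActive`,
#'   `pTxInactive`.
#' @param probesets data.frame with columns `probesetId`, `symbol`, `muLow`,
#'   `muHigh`, `sigma`.
#' @param priorActive prior probability of the active state.
#' @param normalization named numeric `c(lo =, hi =)` log2-odds anchors.
#' @param pathwayName pathway label.
#' @param log2OddsCap cap on reported log2-odds.
#' @return a validated [PathwayModel-class] object.
#' @export
newPathwayModel <- function(genes, probesets, priorActive = 0.5,
                            normalization = c(lo = -20, hi = 20),
                            pathwayName = "NFkB", log2OddsCap = 20) {
  new("PathwayModel",
      pathwayName = pathwayName,
      priorActive = priorActive,
      genes = as.data.frame(genes, stringsAsFactors = FALSE),
      probesets = as.data.frame(probesets, stringsAsFactors = FALSE),
      normalization = normalization,
      log2OddsCap = log2OddsCap,
      formatVersion = "1.0")
}

#' CalibrationSet: labelled reference profiles for calibration
#'
#' A probeset-by-sample log2-intensity matrix together with a ground-truth
#' activity label (`"active"` / `"inactive"`) per sample.
#'
#' @slot exprs numeric matrix, probesets x samples, with dimnames.
#' @slot labels character vector, one of `"active"`/`"inactive"` per column.
#' @seealso [simulateCalibrationSet()], [calibrateModel()]
#' @export
setClass("CalibrationSet",
  representation(exprs = "matrix", labels = "character")
)

setValidity("CalibrationSet", function(object) {
  msg <- character()
  if (is.null(rownames(object@exprs)) || is.null(colnames(object@exprs)))
    msg <- c(msg, "exprs must have probeset rownames and sample colnames")
  if (length(object@labels) != ncol(object@exprs))
    msg <- c(msg, "one label per sample required")
  if (!all(object@labels %in% c("active", "inactive")))
    msg <- c(msg, "labels must be 'active' or 'inactive'")
  if (!any(object@labels == "active") || !any(object@labels == "inactive"))
    msg <- c(msg, "at least one sample of each label required")
  if (length(msg)) msg else TRUE
})

#' @describeIn CalibrationSet-class constructor.
#' @param exprs probeset x sample matrix of log2 intensities.
#' @param labels `"active"`/`"inactive"` per sample.
#' @export
CalibrationSet <- function(exprs, labels) {
  new("CalibrationSet", exprs = exprs, labels = as.character(labels))
}

# ---- accessors ------------------------------------------------------------

#' @describeIn PathwayModel-class pathway label.
#' @param object,x a `PathwayModel` or `CalibrationSet`.
#' @export
setGeneric("pathwayName", function(object) standardGeneric("pathwayName"))
#' @export
setMethod("pathwayName", "PathwayModel", function(object) object@pathwayName)

#' @describeIn PathwayModel-class prior probability of the active state.
#' @export
setGeneric("priorActive", function(object) standardGeneric("priorActive"))
#' @export
setMethod("priorActive", "PathwayModel", function(object) object@priorActive)

#' @describeIn PathwayModel-class gene-layer CPT table.
#' @export
setGeneric("panelGenes", function(object) standardGeneric("panelGenes"))
#' @export
setMethod("panelGenes", "PathwayModel", function(object) object@genes)

#' @describeIn PathwayModel-class probeset emission table.
#' @export
setGeneric("panelProbesets", function(object) standardGeneric("panelProbesets"))
#' @export
setMethod("panelProbesets", "PathwayModel", function(object) object@probesets)

#' @describeIn PathwayModel-class log2-odds anchors of the 0-100 score map.
#' @export
setGeneric("scoreNormalization",
           function(object) standardGeneric("scoreNormalization"))
#' @export
setMethod("scoreNormalization", "PathwayModel",
          function(object) object@normalization)

#' @describeIn CalibrationSet-class sample labels.
#' @export
setGeneric("calibrationLabels",
           function(object) standardGeneric("calibrationLabels"))
#' @export
setMethod("calibrationLabels", "CalibrationSet", function(object) object@labels)

#' @describeIn CalibrationSet-class intensity matrix.
#' @export
setGeneric("calibrationExprs",
           function(object) standardGeneric("calibrationExprs"))
#' @export
setMethod("calibrationExprs", "CalibrationSet", function(object) object@exprs)

setMethod("show", "PathwayModel", function(object) {
  cat("PathwayModel '", object@pathwayName, "'\n", sep = "")
  cat("  ", nrow(object@probesets), " probesets representing ",
      nrow(object@genes), " target genes\n", sep = "")
  cat("  prior P(active) = ", format(object@priorActive), "\n", sep = "")
  nm <- object@normalization
  cat("  score anchors: log2-odds [", format(nm[["lo"]]), ", ",
      format(nm[["hi"]]), "] -> [0, 100]\n", sep = "")
})

setMethod("show", "CalibrationSet", function(object) {
  tab <- table(object@labels)
  cat("CalibrationSet: ", ncol(object@exprs), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      nrow(object@exprs), " probesets\n", sep = "")
})
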