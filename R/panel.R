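#' Default NF-kB target-gene panel
#'
#' A literature-derived panel of 16 canonical, up-responsive NF-kB target
#' genes (IkB feedback, TNF-response, adhesion, cytokine and pro-survival
#' targets), each mapped to one or two synthetic probeset identifiers
#' (`<SYMBOL>_s<k>_at`). These ids are synthetic: the probeset composition
#' of commercial activity assays is not public, so the shipped panel
#' reproduces the method, not any proprietary parameterization. Users can
#' supply their own panel via [readPanel()].
#'
#' @return data.frame with columns `symbol`, `direction`, `probesets`
#'   (comma-separated probeset ids), `pTxActive`, `pTxInactive` (NA = use
#'   the calibration defaults).
#' @export
defaultPanel <- function() {
  two <- c("NFKBIA", "TNFAIP3", "BIRC3", "CCL2", "CXCL8", "ICAM1",
           "IL6", "TNF")
  one <- c("TRAF1", "BCL2A1", "BCL2L1", "PLAU", "PTGS2", "VCAM1",
           "SOD2", "CD40")
  syms <- c(two, one)
  probesets <- c(
    vapply(two, function(s)
      paste0(s, "_s", 1:2, "_at", collapse = ","), character(1)),
    vapply(one, function(s) paste0(s, "_s1_at"), character(1)))
  data.frame(symbol = syms, direction = "up", probesets = unname(probesets),
             pTxActive = NA_real_, pTxInactive = NA_real_,
             stringsAsFactors = FALSE)
}

#' Default, uncalibrated pathway model
#'
#' Builds a [PathwayModel-class] from a panel using fixed emission
#' parameters: untranscribed mean `muLow`, transcribed mean
#' `muLow + effectSize`, common `sigma`. Useful as the generative model for
#' the synthetic-data functions and as a starting point before
#' [calibrateModel()]. The score anchors default to the log2-odds cap range
#' `[-20, 20]`.
#'
#' @param panel panel data.frame (default [defaultPanel()]).
#' @param muLow untranscribed log2-intensity mean (default 5).
#' @param effectSize transcribed-minus-untranscribed shift (default 3).
#' @param sigma emission standard deviation (default 0.5).
#' @param priorActive prior probability of the active state (default 0.5).
#' @param cptActive,cptInactive gene-layer CPT defaults for up-responsive
#'   genes (0.9 / 0.1), mirrored for down-responsive genes.
#' @return a [PathwayModel-class].
#' @export
defaultModel <- function(panel = defaultPanel(), muLow = 5, effectSize = 3,
                         sigma = 0.5, priorActive = 0.5,
                         cptActive = 0.9, cptInactive = 0.1) {
  panel <- .checkPanel(panel)
  genes <- data.frame(
    symbol = panel$symbol,
    direction = panel$direction,
    pTxActive = ifelse(panel$direction == "up", cptActive, cptInactive),
    pTxInactive = ifelse(panel$direction == "up", cptInactive, cptActive),
    stringsAsFactors = FALSE)
  if (!is.null(panel$pTxActive)) {
    ov <- !is.na(panel$pTxActive); genes$pTxActive[ov] <- panel$pTxActive[ov]
  }
  if (!is.null(panel$pTxInactive)) {
    ov <- !is.na(panel$pTxInactive); genes$pTxInactive[ov] <- panel$pTxInactive[ov]
  }
  ids <- lapply(strsplit(panel$probesets, ",", fixed = TRUE), trimws)
  probesets <- data.frame(
    probesetId = unlist(ids),
    symbol = rep(panel$symbol, lengths(ids)),
    muLow = muLow, muHigh = muLow + effectSize, sigma = sigma,
    stringsAsFactors = FALSE)
  newPathwayModel(genes, probesets, priorActive = priorActive)
}

#' The six pro-survival BCL-2 family genes tracked around relapse
#'
#' `BCL2A1` (BFL-1), `BCL2L1` (BCL-XL) and `BCL2` are direct NF-kB target
#' genes; `BCL2L10` (BCL-B), `MCL1` and `BCL2L2` (BCL-W) are
#' NF-kB-independent.
#'
#' @return character vector of the six gene symbols, NF-kB-regulated first.
#' @export
bcl2FamilyGenes <- function() {
  c("BCL2A1", "BCL2L1", "BCL2", "BCL2L10", "MCL1", "BCL2L2")
}

#' @rdname bcl2FamilyGenes
#' @return `nfkbRegulatedBcl2()`: the three NF-kB-regulated members.
#' @export
nfkbRegulatedBcl2 <- function() c("BCL2A1", "BCL2L1", "BCL2")

#' Synthetic probesets interrogating the BCL-2 family genes
#'
#' The simulator emits one dedicated probeset per family gene
#' (`<SYMBOL>_f1_at`), distinct from any same-gene probeset in the activity
#' panel, so fold-change analyses can be run on individual probeset
#' intensities.
#'
#' @return named character vector, gene symbol -> probeset id.
#' @export
bcl2FamilyProbesets <- function() {
  g <- bcl2FamilyGenes()
  setNames(paste0(g, "_f1_at"), g)
}

#' Read / write a panel file
#'
#' Panel files are tab-delimited with columns `symbol`, `direction`,
#' `probesets` (comma-separated ids), `pTxActive`, `pTxInactive`
#' (`NA` = calibration defaults). [writePanel()] followed by [readPanel()]
#' is bit-exact.
#'
#' @param path file path.
#' @return `readPanel()`: panel data.frame.
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  panel$pTxActive <- as.numeric(panel$pTxActive)
  panel$pTxInactive <- as.numeric(panel$pTxInactive)
  .checkPanel(panel)
}

#' @rdname readPanel
#' @param panel panel data.frame.
#' @return `writePanel()`: the path, invisibly.
#' @export
writePanel <- function(panel, path) {
  panel <- .checkPanel(panel)
  fmt <- function(x) ifelse(is.na(x), "NA",
                            formatC(x, digits = 17, format = "g"))
  out <- panel
  out$pTxActive <- fmt(panel$pTxActive)
  out$pTxInactive <- fmt(panel$pTxInactive)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
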