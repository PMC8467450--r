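# Exact inference in the three-layer activity network.
#
# The structure is a tree: target genes are conditionally independent given
# the pathway node, and probesets are conditionally independent given their
# gene's transcription state, so the gene layer marginalizes out gene by
# gene and the posterior is exact.

# Natural-log likelihood of the evidence under each pathway state.
# mat: probesets x samples matrix ordered as model@probesets.
# Returns list(active =, inactive =) of per-sample log-likelihood vectors.
.stateLogLik <- function(model, mat) {
  ps <- model@probesets
  g  <- model@genes
  ll1 <- dnorm(mat, mean = ps$muHigh, sd = ps$sigma, log = TRUE)  # transcribed
  ll0 <- dnorm(mat, mean = ps$muLow,  sd = ps$sigma, log = TRUE)  # untranscribed
  idx <- split(seq_len(nrow(ps)), factor(ps$symbol, levels = g$symbol))
  out <- list(active = 0, inactive = 0)
  for (k in seq_len(nrow(g))) {
    rows <- idx[[k]]
    a1 <- colSums(ll1[rows, , drop = FALSE])
    a0 <- colSums(ll0[rows, , drop = FALSE])
    pA <- g$pTxActive[k]
    pI <- g$pTxInactive[k]
    out$active   <- out$active   + .lse2(log(pA) + a1, log1p(-pA) + a0)
    out$inactive <- out$inactive + .lse2(log(pI) + a1, log1p(-pI) + a0)
  }
  out
}

# Core scorer for a probeset x sample matrix covering all model probesets.
.scoreCore <- function(model, mat) {
  ps <- model@probesets
  missing <- setdiff(ps$probesetId, rownames(mat))
  if (length(missing))
    stop("missing evidence: model probesets absent from the profile(s): ",
         paste(missing, collapse = ", "))
  mat <- mat[ps$probesetId, , drop = FALSE]
  if (!all(is.finite(mat)))
    stop("non-finite intensity values in the profile(s)")
  ll <- .stateLogLik(model, mat)
  prior <- model@priorActive
  logOddsNat <- (log(prior) - log1p(-prior)) + ll$active - ll$inactive
  posterior <- plogis(logOddsNat)
  cap <- model@log2OddsCap
  log2Odds <- pmin(pmax(logOddsNat / log(2), -cap), cap)
  data.frame(
    sample_id = colnames(mat),
    posterior = posterior,
    log2_odds = log2Odds,
    score = normalizeScore(log2Odds, model@normalization),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer pathway activity for a single expression profile
#'
#' Computes the exact posterior probability that the pathway is active given
#' the probeset intensities, by marginalizing the per-gene transcription
#' states (genes are conditionally independent given the pathway node,
#' probesets given their gene). The posterior is reported together with its
#' log2-odds (capped at the model's `log2OddsCap`) and the normalized 0-100
#' activity score.
#'
#' @param model a [PathwayModel-class].
#' @param profile named numeric vector of log2 intensities; must contain
#'   every model probeset. Missing probesets raise an error (no imputation).
#' @param sampleId identifier used in the returned row.
#' @return one-row data.frame with columns `sample_id`, `posterior`,
#'   `log2_odds`, `score`.
#' @examples
#' m <- defaultModel()
#' x <- setNames(panelProbesets(m)$muHigh, panelProbesets(m)$probesetId)
#' inferActivity(m, x)   # fully induced profile scores at the top anchor
#' @export
inferActivity <- function(model, profile, sampleId = "sample") {
  stopifnot(is(model, "PathwayModel"))
  if (is.null(names(profile)))
    stop("'profile' must be a named probeset -> intensity vector")
  mat <- matrix(as.numeric(profile), ncol = 1,
                dimnames = list(names(profile), sampleId))
  .scoreCore(model, mat)
}

#' Score every sample of an expression matrix
#'
#' Batch application of [inferActivity()]: each column is scored
#' independently and results are returned in column order.
#'
#' @param model a [PathwayModel-class].
#' @param x probeset x sample numeric matrix or a
#'   [SummarizedExperiment::SummarizedExperiment]; every model probeset must
#'   be present as a row.
#' @return data.frame with one row per sample: `sample_id`, `posterior`,
#'   `log2_odds`, `score`.
#' @export
scoreMatrix <- function(model, x) {
  stopifnot(is(model, "PathwayModel"))
  .scoreCore(model, .asExprs(x))
}

#' Map log2-odds to the 0-100 activity score
#'
#' Affine map sending `norm["lo"]` to 0 and `norm["hi"]` to 100, clipped to
#' the interval; monotone non-decreasing.
#'
#' @param log2Odds numeric vector of log2-odds values.
#' @param norm named numeric `c(lo =, hi =)` with `hi > lo`.
#' @return numeric vector of scores in `[0, 100]`.
#' @export
normalizeScore <- function(log2Odds, norm) {
  if (length(norm) != 2L || !all(c("lo", "hi") %in% names(norm)))
    stop("'norm' must be a named vector c(lo =, hi =)")
  lo <- norm[["lo"]]; hi <- norm[["hi"]]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("invalid score normalization: 'hi' must exceed 'lo'")
  pmin(pmax(100 * (log2Odds - lo) / (hi - lo), 0), 100)
}

#' Calibrate a pathway model on labelled reference profiles
#'
#' Estimates the two-state Gaussian emission parameters of every panel
#' probeset from profiles with known pathway-activity labels, and sets the
#' score-normalization anchors to the minimum and maximum log2-odds observed
#' on the training samples, so the training set spans the 0-100 scale.
#'
#' For an up-responsive gene the transcribed-state mean `muHigh` is the mean
#' intensity over active-labelled samples and `muLow` the mean over
#' inactive-labelled samples (swapped for down-responsive genes). The
#' emission standard deviation is pooled across the two label groups and
#' floored at `sigmaFloor`; a zero-variance probeset triggers a warning, not
#' an error. If a calibrated up-responsive probeset ends up with
#' `muHigh < muLow` the two means are swapped with a warning. Gene-layer
#' CPTs are set to `cptActive`/`cptInactive` (mirrored for down-responsive
#' genes) unless the panel provides per-gene overrides.
#'
#' @param panel panel data.frame as returned by [defaultPanel()] or
#'   [readPanel()]: columns `symbol`, `direction`, `probesets`
#'   (comma-separated probeset ids), optional `pTxActive`, `pTxInactive`
#'   overrides (NA = use defaults).
#' @param training a [CalibrationSet-class] with at least two samples per
#'   label; every panel probeset must be present.
#' @param pseudocount shrinkage weight pulling each label-conditional mean
#'   toward the pooled probeset mean (`(n*mean + k*pooled)/(n + k)`);
#'   default 0 (no shrinkage).
#' @param priorActive prior probability of the active state for the
#'   returned model.
#' @param sigmaFloor minimum emission standard deviation (log2 units).
#' @param cptActive,cptInactive default gene-layer transcription
#'   probabilities for up-responsive genes (mirrored for down-responsive).
#' @return a calibrated [PathwayModel-class].
#' @export
calibrateModel <- function(panel, training, pseudocount = 0,
                           priorActive = 0.5, sigmaFloor = 0.05,
                           cptActive = 0.9, cptInactive = 0.1) {
  stopifnot(is(training, "CalibrationSet"))
  panel <- .checkPanel(panel)
  exprs <- training@exprs
  labels <- training@labels
  nA <- sum(labels == "active")
  nI <- sum(labels == "inactive")
  if (nA < 2L || nI < 2L)
    stop("calibration requires at least 2 samples per label (got ",
         nA, " active, ", nI, " inactive)")

  psIds <- unlist(strsplit(panel$probesets, ",", fixed = TRUE))
  psIds <- trimws(psIds)
  missing <- setdiff(psIds, rownames(exprs))
  if (length(missing))
    stop("panel probesets absent from the training profiles: ",
         paste(missing, collapse = ", "))

  genes <- data.frame(
    symbol = panel$symbol,
    direction = panel$direction,
    pTxActive = ifelse(panel$direction == "up", cptActive, cptInactive),
    pTxInactive = ifelse(panel$direction == "up", cptInactive, cptActive),
    stringsAsFactors = FALSE)
  if (!is.null(panel$pTxActive)) {
    ov <- !is.na(panel$pTxActive)
    genes$pTxActive[ov] <- panel$pTxActive[ov]
  }
  if (!is.null(panel$pTxInactive)) {
    ov <- !is.na(panel$pTxInactive)
    genes$pTxInactive[ov] <- panel$pTxInactive[ov]
  }

  act <- exprs[, labels == "active", drop = FALSE]
  ina <- exprs[, labels == "inactive", drop = FALSE]
  rows <- lapply(seq_len(nrow(panel)), function(k) {
    ids <- trimws(strsplit(panel$probesets[k], ",", fixed = TRUE)[[1]])
    mA <- rowMeans(act[ids, , drop = FALSE])
    mI <- rowMeans(ina[ids, , drop = FALSE])
    if (pseudocount > 0) {
      pooled <- rowMeans(exprs[ids, , drop = FALSE])
      mA <- (nA * mA + pseudocount * pooled) / (nA + pseudocount)
      mI <- (nI * mI + pseudocount * pooled) / (nI + pseudocount)
    }
    vA <- apply(act[ids, , drop = FALSE], 1, var)
    vI <- apply(ina[ids, , drop = FALSE], 1, var)
    sig <- sqrt(((nA - 1) * vA + (nI - 1) * vI) / (nA + nI - 2))
    if (any(sig < sigmaFloor)) {
      warning("zero or near-zero intensity variance for probeset(s) ",
              paste(ids[sig < sigmaFloor], collapse = ", "),
              "; sigma floored at ", sigmaFloor)
      sig <- pmax(sig, sigmaFloor)
    }
    up <- panel$direction[k] == "up"
    muHigh <- if (up) mA else mI
    muLow  <- if (up) mI else mA
    if (up && any(muHigh < muLow)) {
      bad <- muHigh < muLow
      warning("up-responsive probeset(s) ", paste(ids[bad], collapse = ", "),
              " calibrated with muHigh < muLow; means swapped")
      tmp <- muHigh[bad]; muHigh[bad] <- muLow[bad]; muLow[bad] <- tmp
    }
    data.frame(probesetId = ids, symbol = panel$symbol[k],
               muLow = unname(muLow), muHigh = unname(muHigh),
               sigma = unname(sig), stringsAsFactors = FALSE)
  })
  probesets <- do.call(rbind, rows)

  model <- newPathwayModel(genes, probesets, priorActive = priorActive)
  lo2 <- .scoreCore(model, exprs[probesets$probesetId, , drop = FALSE])$log2_odds
  lo <- min(lo2); hi <- max(lo2)
  if (hi <= lo)
    stop("degenerate calibration: all training samples yield the same ",
         "log2-odds; cannot anchor the 0-100 score")
  model@normalization <- c(lo = lo, hi = hi)
  validObject(model)
  model
}

.checkPanel <- function(panel) {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  need <- c("symbol", "direction", "probesets")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(panel$symbol))
    stop("duplicate gene symbols in panel")
  if (!all(panel$direction %in% c("up", "down")))
    stop("panel direction must be 'up' or 'down'")
  ids <- trimws(unlist(strsplit(panel$probesets, ",", fixed = TRUE)))
  if (anyDuplicated(ids))
    stop("a probeset may belong to only one panel gene")
  panel
}
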