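# Ground-truth synthetic study generators.
#
# Intensities are generated directly on the log2 scale with additive
# Gaussian noise; the generative path for a panel probeset is
#   intensity = muLow + effectSize * 1[gene transcribed] + patient offset
#               + N(0, noiseSd)
# with the gene's transcription state drawn from the model CPT given the
# sample's latent pathway state. Background genes and the six BCL-2 family
# genes are pure noise around fixed baselines (optionally, the three
# NF-kB-regulated family members can be coupled to the pathway state).

.bcl2Baselines <- c(BCL2A1 = 6, BCL2L1 = 8, BCL2 = 7,
                    BCL2L10 = 5, MCL1 = 9, BCL2L2 = 7)

#' Specify a cross-sectional synthetic cohort
#'
#' @param nSamples number of samples (>= 0).
#' @param activityRate probability that a sample's latent pathway state is
#'   active; ignored when `states` is given.
#' @param states optional explicit 0/1 latent states, length `nSamples`.
#' @param effectSize log2-intensity shift added to a probeset when its gene
#'   is transcribed (default 3).
#' @param noiseSd additive Gaussian noise sd, log2 units (default 0.5).
#' @param nBackgroundGenes number of pure-noise non-target genes
#'   (default 50).
#' @param backgroundMean baseline log2 intensity of background genes
#'   (default 6).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return a validated spec (class `CohortSpec`).
#' @export
cohortSpec <- function(nSamples, activityRate = 0.5, states = NULL,
                       effectSize = 3, noiseSd = 0.5,
                       nBackgroundGenes = 50, backgroundMean = 6, seed) {
  stopifnot(nSamples >= 0, noiseSd >= 0, effectSize >= 0,
            activityRate >= 0, activityRate <= 1, nBackgroundGenes >= 0)
  if (!is.null(states)) {
    stopifnot(length(states) == nSamples, all(states %in% c(0, 1)))
  }
  structure(list(nSamples = as.integer(nSamples),
                 activityRate = activityRate, states = states,
                 effectSize = effectSize, noiseSd = noiseSd,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 backgroundMean = backgroundMean, seed = seed),
            class = "CohortSpec")
}

#' Specify a paired longitudinal synthetic study
#'
#' Emulates a total-therapy design: every patient is sampled at each
#' timepoint; at the relapse timepoints the latent activation probability is
#' increased by `activityShiftAtRelapse`, and a fixed fraction of patients
#' carry a `foldChangeMagnitude`-fold BCL2A1 upregulation. The upregulated
#' patient count is `round(bcl2a1UpregulatedFraction * nPatients)` so the
#' realized fraction is exact, and per-patient baseline offsets
#' (sd `patientSd`) make the paired design informative.
#'
#' @param nPatients number of patients (>= 1).
#' @param timepoints ordered unique timepoint labels.
#' @param relapseTimepoints subset of `timepoints` at/after relapse.
#' @param activityRate baseline latent activation probability (default 0.3).
#' @param activityShiftAtRelapse additive increase of the activation
#'   probability at relapse timepoints (default 0.6; clipped into [0, 1]).
#' @param bcl2a1UpregulatedFraction fraction of patients with BCL2A1
#'   upregulation at relapse (default 0.625).
#' @param foldChangeMagnitude linear fold change applied to BCL2A1 in
#'   upregulated patients at relapse timepoints (default 4).
#' @param effectSize,noiseSd,nBackgroundGenes,backgroundMean,seed as in
#'   [cohortSpec()].
#' @param patientSd sd of the per-patient baseline intensity offset
#'   (default 0.3 log2 units).
#' @param coupleBcl2 if TRUE, the NF-kB-regulated family members (BCL2A1,
#'   BCL2L1, BCL2) follow the panel generative path (transcription driven by
#'   the latent state) instead of being pathway-independent background.
#' @return a validated spec (class `LongitudinalSpec`).
#' @export
longitudinalSpec <- function(nPatients,
                             timepoints = c("diagnosis", "induction_1",
                                            "induction_2", "maintenance"),
                             relapseTimepoints = c("induction_2",
                                                   "maintenance"),
                             activityRate = 0.3,
                             activityShiftAtRelapse = 0.6,
                             bcl2a1UpregulatedFraction = 0.625,
                             foldChangeMagnitude = 4,
                             effectSize = 3, noiseSd = 0.5,
                             patientSd = 0.3, nBackgroundGenes = 50,
                             backgroundMean = 6, coupleBcl2 = FALSE, seed) {
  stopifnot(nPatients >= 1, noiseSd >= 0, effectSize >= 0, patientSd >= 0,
            bcl2a1UpregulatedFraction >= 0, bcl2a1UpregulatedFraction <= 1,
            foldChangeMagnitude > 0, activityShiftAtRelapse >= 0)
  if (anyDuplicated(timepoints))
    stop("duplicate timepoint labels: ",
         paste(unique(timepoints[duplicated(timepoints)]), collapse = ", "))
  if (!all(relapseTimepoints %in% timepoints))
    stop("relapseTimepoints must be a subset of timepoints")
  structure(list(nPatients = as.integer(nPatients),
                 timepoints = timepoints,
                 relapseTimepoints = relapseTimepoints,
                 activityRate = activityRate,
                 activityShiftAtRelapse = activityShiftAtRelapse,
                 bcl2a1UpregulatedFraction = bcl2a1UpregulatedFraction,
                 foldChangeMagnitude = foldChangeMagnitude,
                 effectSize = effectSize, noiseSd = noiseSd,
                 patientSd = patientSd,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 backgroundMean = backgroundMean,
                 coupleBcl2 = coupleBcl2, seed = seed),
            class = "LongitudinalSpec")
}

# Draw gene transcription states and panel probeset intensities for given
# latent states. Returns list(panelMat, transcription).
.drawPanelBlock <- function(model, states, effectSize, noiseSd, sampleIds) {
  g <- model@genes
  ps <- model@probesets
  n <- length(states)
  tx <- matrix(0L, nrow = nrow(g), ncol = n,
               dimnames = list(g$symbol, sampleIds))
  for (k in seq_len(nrow(g))) {
    p <- ifelse(states == 1L, g$pTxActive[k], g$pTxInactive[k])
    tx[k, ] <- rbinom(n, 1L, p)
  }
  mat <- ps$muLow +
    effectSize * tx[ps$symbol, , drop = FALSE] +
    matrix(rnorm(nrow(ps) * n, 0, noiseSd), nrow = nrow(ps))
  dimnames(mat) <- list(ps$probesetId, sampleIds)
  list(panelMat = mat, transcription = tx)
}

.backgroundBlock <- function(nGenes, n, mean, noiseSd, sampleIds) {
  if (nGenes == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = n,
                  dimnames = list(character(0), sampleIds)))
  ids <- sprintf("BG%04d_at", seq_len(nGenes))
  matrix(mean + rnorm(nGenes * n, 0, noiseSd), nrow = nGenes,
         dimnames = list(ids, sampleIds))
}

.assembleSE <- function(panelMat, bgMat, famMat, model, colDat) {
  mat <- rbind(panelMat, bgMat, famMat)
  symbol <- c(model@probesets$symbol,
              sub("_at$", "", rownames(bgMat)),
              bcl2FamilyGenes()[match(rownames(famMat),
                                      bcl2FamilyProbesets())])
  SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = DataFrame(symbol = symbol, row.names = rownames(mat)),
    colData = colDat)
}

#' Simulate a cross-sectional cohort with known ground truth
#'
#' Each sample's latent pathway state is drawn with probability
#' `activityRate` (or taken from `spec$states`), gene transcription states
#' are drawn from the model CPTs, and probeset intensities follow the
#' generative path described in [cohortSpec()]. Background genes and the
#' six BCL-2 family genes are emitted as pure noise rows. Row metadata
#' carries the probeset-to-symbol map.
#'
#' @param model a [PathwayModel-class] supplying the panel and CPTs.
#' @param spec a [cohortSpec()].
#' @return list with `experiment` (a
#'   [SummarizedExperiment::SummarizedExperiment]; colData columns `cohort`,
#'   `label`) and `truth` (list: `state` named 0/1 per sample,
#'   `transcription` gene x sample 0/1 matrix).
#' @export
simulateCohort <- function(model, spec) {
  stopifnot(is(model, "PathwayModel"), inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, {
    n <- spec$nSamples
    sampleIds <- sprintf("S%03d", seq_len(n))
    states <- if (!is.null(spec$states)) as.integer(spec$states)
              else rbinom(n, 1L, spec$activityRate)
    blk <- .drawPanelBlock(model, states, spec$effectSize, spec$noiseSd,
                           sampleIds)
    bg <- .backgroundBlock(spec$nBackgroundGenes, n, spec$backgroundMean,
                           spec$noiseSd, sampleIds)
    famIds <- bcl2FamilyProbesets()
    fam <- matrix(.bcl2Baselines[bcl2FamilyGenes()] +
                    rnorm(length(famIds) * n, 0, spec$noiseSd),
                  nrow = length(famIds),
                  dimnames = list(unname(famIds), sampleIds))
    colDat <- DataFrame(
      cohort = rep("cohort", n),
      label = ifelse(states == 1L, "active", "inactive"),
      row.names = sampleIds)
    se <- .assembleSE(blk$panelMat, bg, fam, model, colDat)
    list(experiment = se,
         truth = list(state = setNames(states, sampleIds),
                      transcription = blk$transcription))
  })
}

#' Simulate labelled calibration profiles
#'
#' Generates idealized two-level reference profiles with ground-truth
#' labels: in an active-labelled sample every up-responsive panel gene is
#' transcribed (and every down-responsive gene untranscribed), and vice
#' versa, so with `noiseSd = 0` active and inactive profiles sit exactly at
#' `muLow + effectSize` and `muLow`. This deterministic transcription layer
#' is what makes the calibration loop closed: [calibrateModel()] on the
#' output reproduces the generator means.
#'
#' @param model a [PathwayModel-class].
#' @param nActive,nInactive samples per label (each >= 1).
#' @param noiseSd additive Gaussian noise sd (log2 units).
#' @param seed integer seed.
#' @param effectSize transcribed-state intensity shift (default 3).
#' @return a [CalibrationSet-class].
#' @export
simulateCalibrationSet <- function(model, nActive, nInactive, noiseSd = 0.2,
                                   seed, effectSize = 3) {
  stopifnot(is(model, "PathwayModel"))
  if (nActive < 1L || nInactive < 1L)
    stop("nActive and nInactive must each be >= 1")
  .withSeed(seed, {
    n <- nActive + nInactive
    states <- c(rep(1L, nActive), rep(0L, nInactive))
    sampleIds <- sprintf("C%03d", seq_len(n))
    ps <- model@probesets
    g <- model@genes
    # deterministic transcription given the label
    txOn <- outer(g$direction == "up", states == 1L, "==") * 1L
    rownames(txOn) <- g$symbol
    mat <- ps$muLow + effectSize * txOn[ps$symbol, , drop = FALSE] +
      matrix(rnorm(nrow(ps) * n, 0, noiseSd), nrow = nrow(ps))
    dimnames(mat) <- list(ps$probesetId, sampleIds)
    CalibrationSet(mat, ifelse(states == 1L, "active", "inactive"))
  })
}

#' Simulate a paired longitudinal study with known ground truth
#'
#' Every patient contributes one sample per timepoint. The latent
#' activation probability is `activityRate` at pre-relapse timepoints and
#' `activityRate + activityShiftAtRelapse` (clipped to 1) at relapse
#' timepoints. A fixed number of patients
#' (`round(bcl2a1UpregulatedFraction * nPatients)`) have the BCL2A1 family
#' probeset multiplied by `foldChangeMagnitude` (i.e. shifted by its log2)
#' at relapse timepoints. Per-patient baseline offsets are added to every
#' row of that patient's samples.
#'
#' @param model a [PathwayModel-class].
#' @param spec a [longitudinalSpec()].
#' @return list with `experiment` (colData columns `cohort`, `patient_id`,
#'   `timepoint`, `label`) and `truth` (list: `state` per sample,
#'   `transcription` gene x sample, `bcl2a1Upregulated` named logical per
#'   patient, `patientEffect` named numeric, `relapseTimepoints`).
#' @export
simulateLongitudinalStudy <- function(model, spec) {
  stopifnot(is(model, "PathwayModel"), inherits(spec, "LongitudinalSpec"))
  .withSeed(spec$seed, {
    patients <- sprintf("P%02d", seq_len(spec$nPatients))
    grid <- expand.grid(timepoint = spec$timepoints, patient = patients,
                        stringsAsFactors = FALSE)[, c("patient", "timepoint")]
    sampleIds <- paste(grid$patient, grid$timepoint, sep = "_")
    n <- nrow(grid)
    atRelapse <- grid$timepoint %in% spec$relapseTimepoints
    pAct <- pmin(1, pmax(0, spec$activityRate +
                           spec$activityShiftAtRelapse * atRelapse))
    states <- rbinom(n, 1L, pAct)

    nUp <- round(spec$bcl2a1UpregulatedFraction * spec$nPatients)
    upPatients <- if (nUp > 0) sample(patients, nUp) else character(0)
    bcl2a1Up <- setNames(patients %in% upPatients, patients)
    patientEffect <- setNames(rnorm(spec$nPatients, 0, spec$patientSd),
                              patients)

    blk <- .drawPanelBlock(model, states, spec$effectSize, spec$noiseSd,
                           sampleIds)
    bg <- .backgroundBlock(spec$nBackgroundGenes, n, spec$backgroundMean,
                           spec$noiseSd, sampleIds)
    famIds <- bcl2FamilyProbesets()
    famGenes <- bcl2FamilyGenes()
    fam <- matrix(.bcl2Baselines[famGenes] +
                    rnorm(length(famIds) * n, 0, spec$noiseSd),
                  nrow = length(famIds),
                  dimnames = list(unname(famIds), sampleIds))
    if (spec$coupleBcl2) {
      # NF-kB-regulated members follow the pathway: re-use the panel CPT
      # defaults of the model's first up-responsive gene layer.
      for (sym in intersect(nfkbRegulatedBcl2(), famGenes)) {
        p <- ifelse(states == 1L, 0.9, 0.1)
        t <- rbinom(n, 1L, p)
        fam[famIds[[sym]], ] <- .bcl2Baselines[[sym]] +
          spec$effectSize * t + rnorm(n, 0, spec$noiseSd)
      }
    }
    flagged <- bcl2a1Up[grid$patient] & atRelapse
    fam[famIds[["BCL2A1"]], flagged] <-
      fam[famIds[["BCL2A1"]], flagged] + log2(spec$foldChangeMagnitude)

    offs <- patientEffect[grid$patient]
    panelMat <- sweep(blk$panelMat, 2, offs, "+")
    bg <- sweep(bg, 2, offs, "+")
    fam <- sweep(fam, 2, offs, "+")

    colDat <- DataFrame(
      cohort = rep("longitudinal", n),
      patient_id = grid$patient,
      timepoint = grid$timepoint,
      label = ifelse(states == 1L, "active", "inactive"),
      row.names = sampleIds)
    se <- .assembleSE(panelMat, bg, fam, model, colDat)
    list(experiment = se,
         truth = list(state = setNames(states, sampleIds),
                      transcription = blk$transcription,
                      bcl2a1Upregulated = bcl2a1Up,
                      patientEffect = patientEffect,
                      relapseTimepoints = spec$relapseTimepoints))
  })
}
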