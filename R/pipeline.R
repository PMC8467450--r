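# Config-driven end-to-end run: simulate (or load) -> calibrate -> score ->
# fold change -> differential correlation. Every output file carries a
# provenance header (tool version, seed, config hash) and the whole chain
# is deterministic under a fixed seed.

.configSchema <- list(
  top = c("seed", "panel", "simulate", "input", "calibration",
          "foldchange", "correlate"),
  simulate = c("n_patients", "timepoints", "relapse_timepoints",
               "activity_rate", "activity_shift_at_relapse",
               "bcl2a1_upregulated_fraction", "fold_change_magnitude",
               "effect_size", "noise_sd", "patient_sd",
               "n_background_genes", "couple_bcl2"),
  input = c("matrix", "annotations", "dialect"),
  calibration = c("n_active", "n_inactive", "noise_sd"),
  foldchange = c("threshold", "baseline_timepoint", "followup_timepoint",
                 "genes"),
  correlate = c("anchor", "targets"))

.validateConfig <- function(config) {
  checkKeys <- function(keys, allowed, where) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  checkKeys(names(config), .configSchema$top, "top level")
  for (sec in intersect(names(config),
                        c("simulate", "input", "calibration",
                          "foldchange", "correlate")))
    checkKeys(names(config[[sec]]), .configSchema[[sec]], sec)
  if (!is.null(config$simulate) && !is.null(config$input))
    stop("config may specify either 'simulate' or 'input', not both")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config must specify a 'simulate' or 'input' section")
  if (!is.null(config$input)) {
    for (f in c("matrix", "annotations")) {
      if (is.null(config$input[[f]]))
        stop("input section requires a '", f, "' path")
      if (!file.exists(config$input[[f]]))
        stop("input ", f, " file does not exist: ", config$input[[f]])
    }
  }
  if (!is.null(config$panel) && !file.exists(config$panel))
    stop("panel file does not exist: ", config$panel)
  invisible(config)
}

#' Run the full analysis chain from a config file
#'
#' Stages: generate a synthetic longitudinal study (or load a matrix +
#' annotations), calibrate a pathway model on simulated labelled reference
#' profiles, score every sample, classify paired BCL-2 family fold changes,
#' and correlate differential BCL2A1 expression with the pathway's target
#' genes. The config is YAML; unknown keys are rejected so typos fail fast,
#' and referenced paths are validated before any computation. Outputs
#' (`matrix.tsv`, `annotations.tsv`, `model.json`, `scores.tsv`,
#' `foldchange.tsv`, `correlation.tsv`) are written under `outDir`, each
#' with a `# pathsta <version>; seed=...; config_md5=...` provenance
#' header; re-running with the same config and seed reproduces them
#' byte-identically.
#'
#' @param configPath path to the YAML run configuration (see
#'   `system.file("extdata", "demo_config.yaml", package = "pathsta")`).
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding the config's `seed`.
#' @param verbose log stage timings and record counts via `message()`.
#' @return invisibly, a list with the in-memory stage results (`model`,
#'   `scores`, `foldChange`, `correlation`, `outputs`).
#' @export
runPipeline <- function(configPath, outDir, seed = NULL, verbose = TRUE) {
  if (!file.exists(configPath))
    stop("config file not found: ", configPath)
  config <- yaml::read_yaml(configPath)
  .validateConfig(config)
  seed <- if (!is.null(seed)) seed else config$seed
  if (is.null(seed)) stop("no seed in config and none supplied")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("pathsta %s; seed=%d; config_md5=%s",
                  as.character(packageVersion("pathsta")),
                  as.integer(seed), unname(md5sum(configPath)))
  say <- function(stage, t0, what)
    if (verbose) message(sprintf("[%s] %s (%.2fs)", stage, what,
                                 as.numeric(Sys.time()) - t0))
  panel <- if (!is.null(config$panel)) readPanel(config$panel)
           else defaultPanel()
  model0 <- defaultModel(panel)
  outputs <- character(0)

  # ---- stage 1: data -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sim <- config$simulate
  if (!is.null(sim)) {
    args <- list(seed = seed)
    map <- c(n_patients = "nPatients", timepoints = "timepoints",
             relapse_timepoints = "relapseTimepoints",
             activity_rate = "activityRate",
             activity_shift_at_relapse = "activityShiftAtRelapse",
             bcl2a1_upregulated_fraction = "bcl2a1UpregulatedFraction",
             fold_change_magnitude = "foldChangeMagnitude",
             effect_size = "effectSize", noise_sd = "noiseSd",
             patient_sd = "patientSd",
             n_background_genes = "nBackgroundGenes",
             couple_bcl2 = "coupleBcl2")
    for (k in names(sim)) args[[map[[k]]]] <- unlist(sim[[k]])
    spec <- do.call(longitudinalSpec, args)
    study <- simulateLongitudinalStudy(model0, spec)
    se <- study$experiment
    timepoints <- spec$timepoints
  } else {
    se <- readExpressionMatrix(config$input$matrix,
                               dialect = config$input$dialect %||% "plain_tsv",
                               annotations = config$input$annotations)
    timepoints <- unique(colData(se)$timepoint)
  }
  mPath <- file.path(outDir, "matrix.tsv")
  aPath <- file.path(outDir, "annotations.tsv")
  writeExpressionMatrix(se, mPath, header = prov)
  writeSampleAnnotations(se, aPath, header = prov)
  outputs <- c(outputs, mPath, aPath)
  say("data", t0, sprintf("%d probesets x %d samples", nrow(se), ncol(se)))

  # ---- stage 2: calibrate -------------------------------------------
  t0 <- as.numeric(Sys.time())
  cal <- config$calibration
  training <- simulateCalibrationSet(
    model0,
    nActive = cal$n_active %||% 10L,
    nInactive = cal$n_inactive %||% 10L,
    noiseSd = cal$noise_sd %||% 0.2,
    seed = seed + 1L)
  model <- calibrateModel(panel, training)
  modelPath <- file.path(outDir, "model.json")
  writePathwayModel(model, modelPath)
  outputs <- c(outputs, modelPath)
  say("calibrate", t0, sprintf("%d training samples",
                               ncol(calibrationExprs(training))))

  # ---- stage 3: score -----------------------------------------------
  t0 <- as.numeric(Sys.time())
  scores <- scoreMatrix(model, se)
  sPath <- file.path(outDir, "scores.tsv")
  writeScores(scores, sPath, header = prov)
  outputs <- c(outputs, sPath)
  say("score", t0, sprintf("%d samples scored", nrow(scores)))

  # ---- stage 4: fold change -----------------------------------------
  fc <- config$foldchange
  foldChange <- NULL
  correlation <- NULL
  if (!is.null(fc) || !is.null(config$simulate)) {
    t0 <- as.numeric(Sys.time())
    fc <- fc %||% list()
    baseTp <- fc$baseline_timepoint %||% timepoints[1]
    follTp <- fc$followup_timepoint %||%
      (if (length(timepoints) >= 3) timepoints[3] else
         timepoints[length(timepoints)])
    design <- pairedDesignFromAnnotations(se, baseTp, follTp)
    genes <- unlist(fc$genes) %||% bcl2FamilyGenes()
    gene <- mapProbesets(se, rule = "specific",
                         genes = genes,
                         specific = bcl2FamilyProbesets()[genes])
    ratios <- pairedFoldChange(gene, design, genes)
    foldChange <- classifyFoldChanges(ratios, fc$threshold %||% 2.0)
    fPath <- file.path(outDir, "foldchange.tsv")
    con <- file(fPath, "w")
    writeLines(paste0("# ", prov), con)
    fcTab <- data.frame(gene = names(foldChange$percentages),
                        pct_over_threshold =
                          unname(foldChange$percentages))
    write.table(fcTab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    outputs <- c(outputs, fPath)
    say("foldchange", t0,
        sprintf("%d patients x %d genes", nrow(ratios), ncol(ratios)))

    # ---- stage 5: differential correlation -------------------------
    t0 <- as.numeric(Sys.time())
    cr <- config$correlate %||% list()
    anchor <- cr$anchor %||% "BCL2A1"
    targets <- unlist(cr$targets) %||%
      setdiff(panel$symbol, anchor)
    geneAll <- mapProbesets(se, rule = "max_mean",
                            genes = unique(c(anchor, targets)))
    correlation <- differentialCorrelation(geneAll, design, anchor, targets)
    cPath <- file.path(outDir, "correlation.tsv")
    con <- file(cPath, "w")
    writeLines(paste0("# ", prov), con)
    write.table(correlation, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    outputs <- c(outputs, cPath)
    say("correlate", t0, sprintf("%d target genes", nrow(correlation)))
  }

  invisible(list(model = model, scores = scores, foldChange = foldChange,
                 correlation = correlation, outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
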