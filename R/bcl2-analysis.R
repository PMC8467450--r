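# Paired relapse analyses of the pro-survival BCL-2 family: per-patient
# >2-fold classification and differential correlation of BCL2A1 with the
# pathway's target genes.

#' Build a paired baseline/follow-up design
#'
#' @param patients patient identifiers.
#' @param baseline,followup sample ids, one per patient; every sample id
#'   may appear in exactly one pair.
#' @return data.frame of class `PairedDesign` with columns `patient_id`,
#'   `baseline`, `followup`.
#' @export
pairedDesign <- function(patients, baseline, followup) {
  stopifnot(length(patients) == length(baseline),
            length(patients) == length(followup))
  ids <- c(baseline, followup)
  if (anyDuplicated(ids))
    stop("each sample id may appear in exactly one pair; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(patients))
    stop("duplicate patient ids in design")
  structure(data.frame(patient_id = patients, baseline = baseline,
                       followup = followup, stringsAsFactors = FALSE),
            class = c("PairedDesign", "data.frame"))
}

#' @rdname pairedDesign
#' @param ann sample annotations: a data.frame with `sample_id`,
#'   `patient_id`, `timepoint` columns, or a SummarizedExperiment whose
#'   colData carries `patient_id`/`timepoint`.
#' @param baselineTimepoint,followupTimepoint the two timepoints to pair;
#'   patients lacking either timepoint are dropped.
#' @export
pairedDesignFromAnnotations <- function(ann, baselineTimepoint,
                                        followupTimepoint) {
  if (is(ann, "SummarizedExperiment"))
    ann <- cbind(sample_id = colnames(ann),
                 as.data.frame(colData(ann), stringsAsFactors = FALSE))
  need <- c("sample_id", "patient_id", "timepoint")
  if (!all(need %in% names(ann)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  b <- ann[ann$timepoint == baselineTimepoint, ]
  f <- ann[ann$timepoint == followupTimepoint, ]
  common <- intersect(b$patient_id, f$patient_id)
  if (!length(common))
    stop("no patient has both timepoints '", baselineTimepoint, "' and '",
         followupTimepoint, "'")
  pairedDesign(common,
               b$sample_id[match(common, b$patient_id)],
               f$sample_id[match(common, f$patient_id)])
}

.checkDesign <- function(mat, design, genes = NULL) {
  if (!inherits(design, "PairedDesign"))
    stop("'design' must be a PairedDesign")
  missing <- setdiff(c(design$baseline, design$followup), colnames(mat))
  if (length(missing))
    stop("design sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(mat))
    if (length(absent))
      stop("gene row(s) absent from the matrix: ",
           paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' Paired per-patient fold changes
#'
#' For each patient and gene, the linear-scale expression ratio between the
#' follow-up and baseline sample: `2^(followup_log2 - baseline_log2)`.
#' Input is a gene-level log2 matrix (see [mapProbesets()]).
#'
#' @param geneMatrix gene x sample matrix or SummarizedExperiment
#'   (log2 scale).
#' @param design a [pairedDesign()].
#' @param genes genes to analyze (default: the six BCL-2 family genes).
#' @return numeric matrix, patients x genes, of linear fold changes.
#' @export
pairedFoldChange <- function(geneMatrix, design,
                             genes = bcl2FamilyGenes()) {
  mat <- .asExprs(geneMatrix)
  .checkDesign(mat, design, genes)
  fu <- mat[genes, design$followup, drop = FALSE]
  bl <- mat[genes, design$baseline, drop = FALSE]
  ratios <- t(2^(fu - bl))
  dimnames(ratios) <- list(design$patient_id, genes)
  ratios
}

#' Classify paired fold changes against a threshold
#'
#' Flags each (patient, gene) ratio strictly greater than `threshold` and
#' reports per-gene percentages of flagged patients. For reporting, genes
#' are partitioned into the NF-kB-regulated pro-survival members
#' (BCL2A1, BCL2L1, BCL2) and the NF-kB-independent members
#' (BCL2L10, MCL1, BCL2L2).
#'
#' @param ratios patients x genes matrix from [pairedFoldChange()];
#'   all values must be finite and positive.
#' @param threshold fold-change threshold (default 2; strict `>`).
#' @return object of class `FoldChangeResult`: list with `ratios`, `flags`
#'   (logical matrix), `percentages` (named numeric,
#'   `100 * flagged / patients`), `threshold`, `nPatients`, `grouping`
#'   (list `nfkbRegulated`, `nfkbIndependent`).
#' @export
classifyFoldChanges <- function(ratios, threshold = 2.0) {
  if (!is.matrix(ratios) || !nrow(ratios))
    stop("'ratios' must be a non-empty patients x genes matrix")
  if (!all(is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be finite and positive")
  flags <- ratios > threshold
  pct <- 100 * colSums(flags) / nrow(ratios)
  genes <- colnames(ratios)
  structure(list(
    ratios = ratios, flags = flags, percentages = pct,
    threshold = threshold, nPatients = nrow(ratios),
    grouping = list(nfkbRegulated = intersect(genes, nfkbRegulatedBcl2()),
                    nfkbIndependent = setdiff(
                      intersect(genes, bcl2FamilyGenes()),
                      nfkbRegulatedBcl2()))),
    class = "FoldChangeResult")
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat("Paired fold-change classification (>", x$threshold, "-fold), ",
      x$nPatients, " patients\n", sep = "")
  for (grp in names(x$grouping)) {
    g <- x$grouping[[grp]]
    if (!length(g)) next
    cat(" ", grp, ":\n")
    for (s in g)
      cat(sprintf("    %-8s %5.1f%%\n", s, x$percentages[[s]]))
  }
  other <- setdiff(names(x$percentages), unlist(x$grouping))
  for (s in other)
    cat(sprintf("  %-8s %5.1f%%\n", s, x$percentages[[s]]))
  invisible(x)
}

#' Differential correlation with an anchor gene
#'
#' Computes, per patient, the paired log2 difference
#' (follow-up - baseline) for the anchor gene and for each target gene,
#' then regresses each target's difference on the anchor's. Reported per
#' target: Pearson correlation coefficient R, the two-sided regression
#' p-value, and the slope. Paired differencing removes per-patient baseline
#' offsets. No multiple-testing correction is applied across the panel;
#' interpret the per-gene p-values accordingly.
#'
#' @param geneMatrix gene x sample log2 matrix or SummarizedExperiment.
#' @param design a [pairedDesign()] with at least 3 patients.
#' @param anchorGene anchor gene symbol (e.g. `"BCL2A1"`).
#' @param targetGenes target gene symbols.
#' @param alpha significance threshold reported in the result
#'   (default 0.05).
#' @return data.frame of class `DifferentialCorrelationResult`, one row per
#'   target, columns `gene`, `R`, `p`, `slope`, `significant`, ordered by
#'   decreasing R (heatmap order).
#' @export
differentialCorrelation <- function(geneMatrix, design, anchorGene,
                                    targetGenes, alpha = 0.05) {
  mat <- .asExprs(geneMatrix)
  .checkDesign(mat, design, c(anchorGene, targetGenes))
  if (nrow(design) < 3L)
    stop("differential correlation requires at least 3 patients")
  dAnchor <- mat[anchorGene, design$followup] -
             mat[anchorGene, design$baseline]
  if (sd(dAnchor) == 0)
    stop("zero variance in the anchor gene's paired differences; ",
         "correlation undefined")
  rows <- lapply(targetGenes, function(g) {
    dT <- mat[g, design$followup] - mat[g, design$baseline]
    if (sd(dT) == 0)
      return(data.frame(gene = g, R = 0, p = 1, slope = 0))
    fit <- lm(dT ~ dAnchor)
    sm <- summary(fit)$coefficients
    data.frame(gene = g, R = cor(dAnchor, dT),
               p = unname(sm["dAnchor", "Pr(>|t|)"]),
               slope = unname(coef(fit)[["dAnchor"]]))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out <- out[order(-out$R), ]
  rownames(out) <- NULL
  attr(out, "anchorGene") <- anchorGene
  attr(out, "alpha") <- alpha
  class(out) <- c("DifferentialCorrelationResult", "data.frame")
  out
}

#' Compare one gene's expression across molecular clusters
#'
#' Delegates to [compareGroups()] on the gene's expression values grouped
#' by cluster label (one-way ANOVA, Tukey HSD).
#'
#' @param geneMatrix gene x sample log2 matrix or SummarizedExperiment.
#' @param clusterLabels cluster label per sample (named by sample id, or in
#'   matrix column order).
#' @param gene gene symbol to compare.
#' @return a `GroupComparisonResult` (see [compareGroups()]).
#' @export
clusterExpressionCompare <- function(geneMatrix, clusterLabels, gene) {
  mat <- .asExprs(geneMatrix)
  if (!gene %in% rownames(mat))
    stop("gene row absent from the matrix: ", gene)
  vals <- mat[gene, ]
  if (!is.null(names(clusterLabels)))
    clusterLabels <- clusterLabels[colnames(mat)]
  if (length(clusterLabels) != ncol(mat))
    stop("one cluster label per sample required")
  compareGroups(split(unname(vals), as.character(clusterLabels)))
}
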