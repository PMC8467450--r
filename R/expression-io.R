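# Tab-delimited expression-matrix I/O (plain TSV and the GEO series-matrix
# text dialect), sample annotations, score tables, and the pre-scoring QC
# gate.

.parseTable <- function(lines, path, lineOffset = 0L) {
  if (!length(lines)) stop("empty expression table in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) gsub('^"|"$', "", f))
  header <- fields[[1]]
  nCol <- length(header)
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != nCol)) {
    bad <- which(widths != nCol)[1]
    stop("parse error in ", path, " line ", bad + 1L + lineOffset,
         ": expected ", nCol, " fields, got ", widths[bad])
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate probeset ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(body), ncol = nCol - 1L,
                 dimnames = list(ids, sampleIds))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & !(raw %in% c("NA", "", "null"))
    if (any(bad))
      stop("parse error in ", path, " line ", i + 1L + lineOffset,
           ": unparseable value '", raw[which(bad)[1]], "'")
    vals[i, ] <- num
  }
  vals
}

#' Read an expression matrix
#'
#' Two dialects are supported. `plain_tsv`: a header row of sample ids
#' (first column holds probeset ids), one row per probeset; lines starting
#' with `#` are treated as comments. `series_matrix`: the GEO series-matrix
#' text format; `!`-prefixed metadata lines are skipped and the table
#' between the `!series_matrix_table_begin`/`_end` markers is read (quoted
#' identifiers are unquoted). Parse problems report the offending line
#' number.
#'
#' @param path input file.
#' @param dialect `"plain_tsv"` (default) or `"series_matrix"`.
#' @param annotations optional sample-annotation data.frame (or path to an
#'   annotations TSV) attached as colData; see [readSampleAnnotations()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("plain_tsv", "series_matrix"),
                                 annotations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "plain_tsv") {
    keep <- !startsWith(lines, "#") & nzchar(lines)
    offset <- if (length(lines) && startsWith(lines[1], "#"))
      which(keep)[1] - 1L else 0L
    vals <- .parseTable(lines[keep], path, lineOffset = offset)
  } else {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      stop("no series-matrix table markers found in ", path)
    vals <- .parseTable(lines[(beg + 1L):(end - 1L)], path,
                        lineOffset = beg)
  }
  se <- SummarizedExperiment(assays = list(exprs = vals))
  if (!is.null(annotations)) se <- attachAnnotations(se, annotations)
  se
}

#' Write an expression matrix as plain TSV
#'
#' The written file round-trips through [readExpressionMatrix()] with
#' value-identical results (17 significant digits).
#'
#' @param x matrix or SummarizedExperiment.
#' @param path output file.
#' @param idColumn name of the first (probeset id) column.
#' @param header optional character vector of `#`-prefixed provenance lines
#'   written before the table.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "probeset_id",
                                  header = NULL) {
  mat <- .asExprs(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(idColumn, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write / attach sample annotations
#'
#' Annotations are tab-delimited with a `sample_id` column and any of
#' `cohort`, `patient_id`, `timepoint`, `label`.
#'
#' @param path annotations TSV.
#' @return `readSampleAnnotations()`: data.frame.
#' @export
readSampleAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(ann))
    stop("annotations must have a 'sample_id' column")
  ann
}

#' @rdname readSampleAnnotations
#' @param se a SummarizedExperiment.
#' @param ann annotations data.frame or path; rows are matched to samples
#'   by `sample_id` and must reference existing samples only.
#' @return `attachAnnotations()`: the SummarizedExperiment with colData set.
#' @export
attachAnnotations <- function(se, ann) {
  if (is.character(ann)) ann <- readSampleAnnotations(ann)
  unknown <- setdiff(ann$sample_id, colnames(se))
  if (length(unknown))
    stop("annotations reference unknown sample ids: ",
         paste(unknown, collapse = ", "))
  idx <- match(colnames(se), ann$sample_id)
  cd <- ann[idx, setdiff(names(ann), "sample_id"), drop = FALSE]
  rownames(cd) <- colnames(se)
  colData(se) <- DataFrame(cd)
  se
}

#' @rdname readSampleAnnotations
#' @param x a SummarizedExperiment whose colData to write.
#' @param header optional `#`-prefixed provenance lines.
#' @return `writeSampleAnnotations()`: the path, invisibly.
#' @export
writeSampleAnnotations <- function(x, path, header = NULL) {
  ann <- cbind(sample_id = colnames(x),
               as.data.frame(colData(x), stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(ann, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control gate before scoring
#'
#' Drops samples whose fraction of missing values exceeds
#' `maxMissingFraction`; any missing value remaining after dropping is an
#' error (values are never imputed). Samples whose median intensity falls
#' outside `intensityRange` are flagged; a median above 100 is flagged as a
#' suspected non-log2 scale. Array-level QC (RNA degradation metrics etc.)
#' is out of scope.
#'
#' @param x matrix or SummarizedExperiment.
#' @param maxMissingFraction per-sample missingness threshold (default 0.1).
#' @param intensityRange plausible range for per-sample median log2
#'   intensity (default `c(2, 16)`).
#' @return list with `experiment` (surviving samples, values untouched) and
#'   `report` (list: `dropped`, `flagged` data.frame, `nInput`, `nKept`).
#' @export
qcMatrix <- function(x, maxMissingFraction = 0.1, intensityRange = c(2, 16)) {
  se <- if (is(x, "SummarizedExperiment")) x else
    SummarizedExperiment(assays = list(exprs = .asExprs(x)))
  mat <- assay(se, 1L)
  missFrac <- colMeans(is.na(mat))
  dropped <- colnames(mat)[missFrac > maxMissingFraction]
  if (length(dropped) == ncol(mat))
    stop("QC dropped all samples (missing-value fraction > ",
         maxMissingFraction, " in every sample)")
  keep <- setdiff(colnames(mat), dropped)
  se <- se[, keep]
  mat <- assay(se, 1L)
  if (anyNA(mat)) {
    bad <- colnames(mat)[colSums(is.na(mat)) > 0]
    stop("missing values remain after QC in sample(s) ",
         paste(bad, collapse = ", "),
         "; values are rejected, not imputed")
  }
  med <- apply(mat, 2, median)
  out <- med < intensityRange[1] | med > intensityRange[2]
  flagged <- data.frame(
    sample_id = colnames(mat)[out],
    median = unname(med[out]),
    reason = ifelse(med[out] > 100, "suspected non-log2 scale",
                    "median intensity outside expected range"),
    stringsAsFactors = FALSE)
  report <- list(dropped = dropped, flagged = flagged,
                 nInput = length(missFrac), nKept = ncol(mat))
  list(experiment = se, report = report)
}

#' Collapse probesets to gene-level expression
#'
#' @param x probeset-level matrix or SummarizedExperiment.
#' @param annotation probeset -> gene symbol map: a named character vector,
#'   a data.frame with columns `probesetId`/`symbol` (a `probeset_id`
#'   column is also accepted), or NULL to use `rowData(x)$symbol`.
#' @param rule `"max_mean"` picks, per gene, the probeset with the highest
#'   mean intensity across samples; `"specific"` uses the probeset given in
#'   `specific`.
#' @param genes genes to return (default: all annotated genes present).
#' @param specific named character vector gene -> probeset id (for
#'   `rule = "specific"`).
#' @return gene-by-sample matrix (or SummarizedExperiment if one was
#'   supplied, with colData preserved).
#' @export
mapProbesets <- function(x, annotation = NULL,
                         rule = c("max_mean", "specific"),
                         genes = NULL, specific = NULL) {
  rule <- match.arg(rule)
  mat <- .asExprs(x)
  if (is.null(annotation)) {
    if (is(x, "SummarizedExperiment") && "symbol" %in% names(rowData(x)))
      annotation <- setNames(rowData(x)$symbol, rownames(x))
    else stop("no probeset annotation supplied and none found in rowData")
  }
  if (is.data.frame(annotation)) {
    idCol <- intersect(c("probesetId", "probeset_id"), names(annotation))[1]
    if (is.na(idCol) || !"symbol" %in% names(annotation))
      stop("annotation data.frame needs probesetId/probeset_id and symbol")
    annotation <- setNames(annotation$symbol, annotation[[idCol]])
  }
  if (anyDuplicated(names(annotation)))
    stop("a probeset may map to at most one gene symbol")
  annotation <- annotation[names(annotation) %in% rownames(mat)]
  if (is.null(genes)) genes <- unique(annotation)

  pick <- character(length(genes))
  names(pick) <- genes
  if (rule == "specific") {
    if (is.null(specific)) stop("rule 'specific' requires 'specific'")
    for (g in genes) {
      if (is.na(specific[g]))
        stop("no specific probeset supplied for gene ", g)
      if (!specific[[g]] %in% rownames(mat))
        stop("specific probeset '", specific[[g]], "' for gene ", g,
             " absent from the matrix")
      pick[g] <- specific[[g]]
    }
  } else {
    for (g in genes) {
      ids <- names(annotation)[annotation == g]
      if (!length(ids)) stop("gene ", g, " has no probeset in the matrix")
      means <- rowMeans(mat[ids, , drop = FALSE])
      pick[g] <- ids[which.max(means)]
    }
  }
  out <- mat[pick, , drop = FALSE]
  rownames(out) <- genes
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment(
      assays = list(exprs = out),
      rowData = DataFrame(probesetId = unname(pick), row.names = genes),
      colData = colData(x))
  } else out
}

#' Write a scores table
#'
#' Tab-delimited with columns `sample_id`, `posterior`, `log2_odds`,
#' `score`.
#'
#' @param scores data.frame from [scoreMatrix()].
#' @param path output file.
#' @param header optional `#`-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
writeScores <- function(scores, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  out <- scores
  for (cc in c("posterior", "log2_odds", "score"))
    out[[cc]] <- formatC(scores[[cc]], digits = 17, format = "g")
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
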