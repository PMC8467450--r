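# Matrix I/O dialects, QC gate, probeset-to-gene collapsing.

writeTmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("plain TSV fixture parses with exact shape and values", {
  path <- writeTmp(c("probeset_id\ts1\ts2",
                     "a_at\t1.5\t2.25",
                     "b_at\t3\t4",
                     "c_at\t-0.5\t6.125"))
  se <- readExpressionMatrix(path)
  expect_identical(dim(se), c(3L, 2L))
  expect_identical(SummarizedExperiment::assay(se, 1)["c_at", "s2"], 6.125)
})

test_that("write then read round-trips values exactly for both containers", {
  m <- defaultModel()
  sim <- simulateCohort(m, cohortSpec(6, seed = 44))
  path <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(sim$experiment, path)
  back <- readExpressionMatrix(path)
  expect_identical(SummarizedExperiment::assay(back, 1),
                   SummarizedExperiment::assay(sim$experiment, 1))
})

test_that("series-matrix dialect skips metadata and honours the markers", {
  path <- system.file("extdata", "synthetic_series_matrix_example.txt",
                      package = "pathsta")
  se <- readExpressionMatrix(path, dialect = "series_matrix")
  expect_identical(dim(se), c(4L, 3L))
  expect_identical(colnames(se), c("SYN001", "SYN002", "SYN003"))
  expect_identical(SummarizedExperiment::assay(se, 1)["BCL2A1_f1_at", "SYN003"],
                   7.84)
})

test_that("parse errors carry line numbers and offending content", {
  ragged <- writeTmp(c("probeset_id\ts1\ts2", "a_at\t1\t2", "b_at\t3"))
  expect_error(readExpressionMatrix(ragged), "line 3.*expected 3.*got 2")
  junk <- writeTmp(c("probeset_id\ts1", "a_at\t1", "b_at\tx7"))
  expect_error(readExpressionMatrix(junk), "line 3.*unparseable.*x7")
  dupRow <- writeTmp(c("probeset_id\ts1", "a_at\t1", "a_at\t2"))
  expect_error(readExpressionMatrix(dupRow), "duplicate probeset ids")
  dupCol <- writeTmp(c("probeset_id\ts1\ts1", "a_at\t1\t2"))
  expect_error(readExpressionMatrix(dupCol), "duplicate sample ids")
})

test_that("QC passes a clean matrix untouched and reports nothing", {
  mat <- matrix(rnorm(40, 7), 10, 4,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  res <- qcMatrix(mat)
  expect_identical(SummarizedExperiment::assay(res$experiment, 1), mat)
  expect_length(res$report$dropped, 0)
  expect_identical(nrow(res$report$flagged), 0L)
})

test_that("QC drops a half-missing sample at threshold 0.1 and names it", {
  mat <- matrix(7, 10, 3,
                dimnames = list(paste0("p", 1:10), c("ok1", "bad", "ok2")))
  mat[1:5, "bad"] <- NA
  res <- qcMatrix(mat, maxMissingFraction = 0.1)
  expect_identical(res$report$dropped, "bad")
  expect_identical(colnames(res$experiment), c("ok1", "ok2"))
  # values that survive are untouched (subset relation)
  expect_identical(SummarizedExperiment::assay(res$experiment, 1),
                   mat[, c("ok1", "ok2")])
})

test_that("QC rejects residual missing values instead of imputing", {
  mat <- matrix(7, 10, 2, dimnames = list(paste0("p", 1:10), c("a", "b")))
  mat[1, "a"] <- NA
  expect_error(qcMatrix(mat, maxMissingFraction = 0.5), "not imputed")
  matAllBad <- matrix(NA_real_, 4, 2,
                      dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_error(qcMatrix(matAllBad), "all samples")
})

test_that("a linear-scale matrix is flagged as suspected non-log2", {
  mat <- matrix(3000, 5, 2, dimnames = list(paste0("p", 1:5), c("a", "b")))
  res <- qcMatrix(mat)
  expect_identical(res$report$flagged$reason,
                   rep("suspected non-log2 scale", 2))
})

test_that("mapProbesets max_mean picks the highest-mean probeset per gene", {
  mat <- rbind(g1_a = c(6, 6), g1_b = c(9, 9), g2_a = c(4, 5))
  colnames(mat) <- c("s1", "s2")
  ann <- c(g1_a = "G1", g1_b = "G1", g2_a = "G2")
  out <- mapProbesets(mat, ann, rule = "max_mean")
  expect_identical(unname(out["G1", ]), c(9, 9))     # argmax row
  expect_identical(unname(out["G2", ]), c(4, 5))     # singleton unchanged
  expect_error(mapProbesets(mat, ann, genes = c("G1", "G3")), "G3")
  expect_error(
    mapProbesets(mat, ann, rule = "specific", genes = "G1",
                 specific = c(G1 = "nope_at")),
    "absent from the matrix")
})

test_that("annotations attach by sample id and reject unknown samples", {
  m <- defaultModel()
  sim <- simulateCohort(m, cohortSpec(4, seed = 3))
  path <- tempfile(fileext = ".tsv")
  writeSampleAnnotations(sim$experiment, path)
  ann <- readSampleAnnotations(path)
  expect_setequal(ann$sample_id, colnames(sim$experiment))
  ann$sample_id[1] <- "GHOST"
  expect_error(attachAnnotations(sim$experiment, ann), "GHOST")
})
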