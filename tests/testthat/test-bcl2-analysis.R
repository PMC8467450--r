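# Paired fold-change classification and differential correlation of the
# BCL-2 family transcripts.

toyGeneMatrix <- function() {
  # 3 genes x 4 samples (2 patients x 2 timepoints), log2 scale
  mat <- rbind(BCL2A1 = c(5.0, 6.0, 7.0, 7.0),
               MCL1   = c(9.0, 9.0, 8.0, 9.5),
               BCL2   = c(7.0, 7.5, 6.0, 5.0))
  colnames(mat) <- c("p1_t1", "p1_t3", "p2_t1", "p2_t3")
  mat
}

test_that("paired fold change is 2^(followup - baseline)", {
  d <- pairedDesign(c("p1", "p2"), c("p1_t1", "p2_t1"), c("p1_t3", "p2_t3"))
  r <- pairedFoldChange(toyGeneMatrix(), d, c("BCL2A1", "MCL1", "BCL2"))
  expect_equal(r["p1", "BCL2A1"], 2.0)    # one doubling
  expect_equal(r["p2", "BCL2A1"], 1.0)    # identity
  expect_equal(r["p2", "MCL1"], 2^1.5)
  expect_equal(r["p1", "BCL2"], 2^0.5)
  # identity design: every ratio is exactly 1
  dSame <- pairedDesign(c("p1", "p2"), c("p1_t1", "p2_t1"),
                        c("p1_t1x", "p2_t1x"))
  m2 <- toyGeneMatrix()
  m2 <- cbind(m2, p1_t1x = m2[, "p1_t1"], p2_t1x = m2[, "p2_t1"])
  expect_equal(unname(pairedFoldChange(m2, dSame, rownames(m2))),
               matrix(1, 2, 3))
})

test_that("fold-change inputs are validated", {
  d <- pairedDesign("p1", "p1_t1", "p1_t3")
  expect_error(pairedFoldChange(toyGeneMatrix()[, 1:2], d, "GHOST"),
               "GHOST")
  dBad <- pairedDesign("p9", "nope_a", "nope_b")
  expect_error(pairedFoldChange(toyGeneMatrix(), dBad, "BCL2A1"),
               "absent from the matrix")
  expect_error(pairedDesign(c("p1", "p2"), c("s1", "s2"), c("s1", "s3")),
               "exactly one pair")
})

test_that("classification uses strict > and exact percentages", {
  ratios <- matrix(c(3, 3, 3, 3, 3, 1, 1, 1,        # 5/8 above 2
                     rep(1.2, 8)),                  # none above 2
                   nrow = 8, dimnames = list(paste0("p", 1:8),
                                             c("BCL2A1", "MCL1")))
  res <- classifyFoldChanges(ratios)
  expect_equal(unname(res$percentages["BCL2A1"]), 62.5)
  expect_equal(unname(res$percentages["MCL1"]), 0)
  expect_identical(res$grouping$nfkbRegulated, "BCL2A1")
  expect_identical(res$grouping$nfkbIndependent, "MCL1")
  # boundary: exactly 2.0 is not "> 2-fold"
  res2 <- classifyFoldChanges(matrix(2.0, 4, 1,
                                     dimnames = list(NULL, "BCL2")))
  expect_equal(unname(res2$percentages), 0)
  # invariant to patient and gene order
  res3 <- classifyFoldChanges(ratios[sample(8), 2:1])
  expect_equal(res3$percentages[colnames(ratios)], res$percentages)
  expect_error(classifyFoldChanges(ratios[0, , drop = FALSE]), "non-empty")
  expect_error(classifyFoldChanges(-ratios), "positive")
})

test_that("the synthetic relapse study closes the generative loop at 62.5% / 0%", {
  m <- defaultModel()
  st <- simulateLongitudinalStudy(
    m, longitudinalSpec(8, bcl2a1UpregulatedFraction = 0.625,
                        foldChangeMagnitude = 4, noiseSd = 0.1, seed = 11))
  d <- pairedDesignFromAnnotations(st$experiment, "diagnosis", "induction_2")
  gm <- mapProbesets(st$experiment, rule = "specific",
                     genes = bcl2FamilyGenes(),
                     specific = bcl2FamilyProbesets())
  res <- classifyFoldChanges(pairedFoldChange(gm, d))
  expect_equal(unname(res$percentages["BCL2A1"]), 62.5)
  expect_equal(unname(res$percentages["MCL1"]), 0)
  # flags identify exactly the ground-truth upregulated patients
  expect_identical(unname(res$flags[names(st$truth$bcl2a1Upregulated),
                                    "BCL2A1"]),
                   unname(st$truth$bcl2a1Upregulated))
  # ratios recover the generator multiplier within noise tolerance
  up <- names(which(st$truth$bcl2a1Upregulated))
  expect_equal(unname(res$ratios[up, "BCL2A1"]), rep(4, length(up)),
               tolerance = 0.5)
})

test_that("differential correlation matches the closed-form Pearson formula", {
  # fixed 8-patient paired toy
  base <- c(5.1, 6.3, 4.8, 5.9, 6.1, 5.5, 4.9, 6.0)
  dA <- c(0.9, -0.4, 1.8, 0.2, -1.1, 0.7, 1.3, -0.6)
  dT <- c(1.2, -0.1, 1.5, 0.6, -0.8, 0.3, 1.9, -0.9)
  mat <- rbind(ANCHOR = c(base, base + dA), TARGET = c(base * 0.8, base * 0.8 + dT))
  colnames(mat) <- c(paste0("p", 1:8, "_t1"), paste0("p", 1:8, "_t3"))
  d <- pairedDesign(paste0("p", 1:8), paste0("p", 1:8, "_t1"),
                    paste0("p", 1:8, "_t3"))
  res <- differentialCorrelation(mat, d, "ANCHOR", "TARGET")
  # independent closed-form Pearson R and least-squares slope
  rExp <- sum((dA - mean(dA)) * (dT - mean(dT))) /
    sqrt(sum((dA - mean(dA))^2) * sum((dT - mean(dT))^2))
  slopeExp <- sum((dA - mean(dA)) * (dT - mean(dT))) / sum((dA - mean(dA))^2)
  expect_equal(res$R, rExp, tolerance = 1e-12)
  expect_equal(res$slope, slopeExp, tolerance = 1e-12)
  tExp <- rExp * sqrt(6 / (1 - rExp^2))
  expect_equal(res$p, 2 * pt(abs(tExp), 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("self-correlation gives R = 1 and orthogonal contrasts give R = 0", {
  dA <- c(1, -1, 2, -2, 0.5, -0.5)
  mat <- rbind(A = c(rep(5, 6), 5 + dA),
               SAME = c(rep(6, 6), 6 + dA),
               ORTH = c(rep(7, 6), 7 + c(1, 1, -1, -1, 0, 0)))
  # ORTH deltas constructed mean-centered and orthogonal to dA
  stopifnot(abs(sum(dA * c(1, 1, -1, -1, 0, 0))) < 1e-12)
  colnames(mat) <- c(paste0("p", 1:6, "_a"), paste0("p", 1:6, "_b"))
  d <- pairedDesign(paste0("p", 1:6), paste0("p", 1:6, "_a"),
                    paste0("p", 1:6, "_b"))
  res <- suppressWarnings(differentialCorrelation(mat, d, "A",
                                                  c("SAME", "ORTH")))
  expect_equal(res$R[res$gene == "SAME"], 1, tolerance = 1e-9)
  expect_equal(res$slope[res$gene == "SAME"], 1, tolerance = 1e-9)
  expect_equal(res$R[res$gene == "ORTH"], 0, tolerance = 1e-12)
})

test_that("R is invariant to per-patient baseline constants", {
  m <- defaultModel()
  st <- simulateLongitudinalStudy(m, longitudinalSpec(10, seed = 3,
                                                      coupleBcl2 = TRUE))
  d <- pairedDesignFromAnnotations(st$experiment, "diagnosis", "induction_2")
  gm <- mapProbesets(st$experiment)
  res <- differentialCorrelation(gm, d, "BCL2A1", c("NFKBIA", "TNFAIP3"))
  mat <- SummarizedExperiment::assay(gm, 1)
  shift <- setNames(rnorm(nrow(d), 5), d$patient_id)
  mat2 <- mat
  mat2[, d$baseline] <- sweep(mat[, d$baseline], 2, shift, "+")
  mat2[, d$followup] <- sweep(mat[, d$followup], 2, shift, "+")
  res2 <- differentialCorrelation(mat2, d, "BCL2A1", c("NFKBIA", "TNFAIP3"))
  expect_equal(res2$R, res$R, tolerance = 1e-10)
})

test_that("degenerate anchors and tiny designs are rejected", {
  mat <- rbind(A = rep(5, 6), B = rnorm(6))
  colnames(mat) <- c("p1_a", "p2_a", "p3_a", "p1_b", "p2_b", "p3_b")
  d <- pairedDesign(c("p1", "p2", "p3"), c("p1_a", "p2_a", "p3_a"),
                    c("p1_b", "p2_b", "p3_b"))
  expect_error(differentialCorrelation(mat, d, "A", "B"), "zero variance")
  d2 <- pairedDesign(c("p1", "p2"), c("p1_a", "p2_a"), c("p1_b", "p2_b"))
  expect_error(differentialCorrelation(mat, d2, "B", "A"),
               "at least 3 patients")
})

test_that("cluster comparison flags only the shifted cluster", {
  withr::local_seed(71)
  mat <- matrix(rnorm(120, 7, 0.3), nrow = 2,
                dimnames = list(c("BCL2A1", "BAK1"), paste0("s", 1:60)))
  clusters <- rep(c("NFKB", "HY", "MS"), each = 20)
  mat["BCL2A1", clusters == "NFKB"] <-
    mat["BCL2A1", clusters == "NFKB"] + 5
  res <- clusterExpressionCompare(mat, setNames(clusters, colnames(mat)),
                                  "BCL2A1")
  vsNfkb <- res$pairwise$group1 == "NFKB" | res$pairwise$group2 == "NFKB"
  expect_true(all(res$pairwise$pAdj[vsNfkb] < 0.001))
  expect_true(all(res$pairwise$pAdj[!vsNfkb] > 0.05))
  # a gene with no shift shows no significant cluster differences
  resNull <- clusterExpressionCompare(mat, setNames(clusters, colnames(mat)),
                                      "BAK1")
  expect_true(all(resNull$pairwise$pAdj > 0.05))
  # identical expression profiles across clusters: all adjusted p = 1
  matConst <- rbind(g1 = rep(c(1, 2, 3, 4, 5), 6), g2 = rnorm(30))
  colnames(matConst) <- paste0("s", 1:30)
  resConst <- clusterExpressionCompare(matConst,
                                       rep(c("a", "b", "c"), each = 10), "g1")
  expect_equal(resConst$pairwise$pAdj, rep(1, 3))
})
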