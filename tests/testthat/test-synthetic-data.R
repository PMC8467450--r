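# Ground-truth generators: determinism, degenerate paths, analytic means.

test_that("identical spec and seed give bit-identical studies", {
  m <- defaultModel()
  a <- simulateCohort(m, cohortSpec(15, seed = 99))
  b <- simulateCohort(m, cohortSpec(15, seed = 99))
  expect_identical(SummarizedExperiment::assay(a$experiment, 1),
                   SummarizedExperiment::assay(b$experiment, 1))
  expect_identical(a$truth, b$truth)
  c <- simulateCohort(m, cohortSpec(15, seed = 100))
  expect_false(identical(SummarizedExperiment::assay(a$experiment, 1),
                         SummarizedExperiment::assay(c$experiment, 1)))
  expect_identical(dim(a$experiment), dim(c$experiment))

  sl <- longitudinalSpec(6, seed = 7)
  x <- simulateLongitudinalStudy(m, sl)
  y <- simulateLongitudinalStudy(m, sl)
  expect_identical(SummarizedExperiment::assay(x$experiment, 1),
                   SummarizedExperiment::assay(y$experiment, 1))
  expect_identical(x$truth, y$truth)
})

test_that("the generators do not disturb the caller's RNG stream", {
  m <- defaultModel()
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulateCohort(m, cohortSpec(5, seed = 1)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("empty cohort yields an empty matrix and empty truth", {
  m <- defaultModel()
  sim <- simulateCohort(m, cohortSpec(0, seed = 1))
  expect_identical(ncol(sim$experiment), 0L)
  expect_length(sim$truth$state, 0)
  expect_identical(ncol(sim$truth$transcription), 0L)
})

test_that("noiseless degenerate CPTs put every panel probeset at muLow + effect", {
  m <- defaultModel(cptActive = 1 - 1e-12, cptInactive = 1e-12)
  sim <- simulateCohort(m, cohortSpec(4, activityRate = 1, noiseSd = 0,
                                      seed = 2))
  ps <- panelProbesets(m)
  mat <- SummarizedExperiment::assay(sim$experiment, 1)[ps$probesetId, ]
  expect_equal(unname(mat), matrix(8, nrow(ps), 4), tolerance = 1e-9)
})

test_that("active/inactive mean separation matches the analytic expectation", {
  m <- defaultModel()   # CPTs 0.9/0.1, effect 3
  spec <- cohortSpec(200, activityRate = 0.5, seed = 7)
  sim <- simulateCohort(m, spec)
  ps <- panelProbesets(m)
  mat <- SummarizedExperiment::assay(sim$experiment, 1)[ps$probesetId, ]
  act <- sim$truth$state == 1
  gap <- mean(mat[, act]) - mean(mat[, !act])
  # E[gap] = effect * (pTxActive - pTxInactive) = 3 * 0.8
  nCell <- nrow(ps) * ncol(mat) / 2
  se3 <- 3 * sqrt(2 * (spec$noiseSd^2 + 3^2 * 0.09) / nCell) # conservative
  expect_lt(abs(gap - 3 * 0.8), se3 + 0.1)
})

test_that("longitudinal study structure and truth dimensions are coherent", {
  m <- defaultModel()
  spec <- longitudinalSpec(5, seed = 13)
  st <- simulateLongitudinalStudy(m, spec)
  cd <- SummarizedExperiment::colData(st$experiment)
  expect_identical(ncol(st$experiment), 5L * 4L)
  expect_identical(sort(unique(cd$patient_id)), sprintf("P%02d", 1:5))
  expect_setequal(unique(cd$timepoint), spec$timepoints)
  expect_length(st$truth$state, ncol(st$experiment))
  expect_length(st$truth$bcl2a1Upregulated, 5)
  expect_identical(sum(st$truth$bcl2a1Upregulated), 3L)  # round(0.625 * 5)
})

test_that("duplicate timepoint labels are rejected", {
  expect_error(longitudinalSpec(4, timepoints = c("a", "b", "a"), seed = 1),
               "duplicate timepoint")
})

test_that("null configuration leaves relapse and diagnosis exchangeable", {
  m <- defaultModel()
  spec <- longitudinalSpec(40, activityShiftAtRelapse = 0,
                           foldChangeMagnitude = 1, seed = 19)
  st <- simulateLongitudinalStudy(m, spec)
  cd <- SummarizedExperiment::colData(st$experiment)
  # latent activation probability identical across timepoints
  byTp <- tapply(st$truth$state, cd$timepoint, mean)
  expect_lt(max(byTp) - min(byTp), 0.35)  # same Bernoulli(0.3) rate
  # BCL2A1 family probeset has no multiplier anywhere
  fam <- SummarizedExperiment::assay(st$experiment, 1)["BCL2A1_f1_at", ]
  off <- st$truth$patientEffect[cd$patient_id]
  expect_lt(abs(mean(fam - off) - 6), 0.2)   # baseline 6, no shift
})

test_that("positive activity shift raises inferred scores at relapse", {
  m <- defaultModel()
  st <- simulateLongitudinalStudy(m, longitudinalSpec(20, seed = 23))
  sc <- scoreMatrix(m, st$experiment)
  pp <- pairedScores(st, sc, "diagnosis", "induction_2")
  expect_gt(median(pp$second), median(pp$first))
  expect_lt(pairedIncreaseP(pp$first, pp$second), 0.05)
})
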