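# Brute-force enumeration oracle for the three-layer network: sums the
# joint probability over the pathway state and every gene-transcription
# configuration (2^(1+G) terms). Deliberately independent of the package's
# tree-structured inference path.
enumPosterior <- function(model, profile) {
  g <- panelGenes(model)
  ps <- panelProbesets(model)
  x <- profile[ps$probesetId]
  G <- nrow(g)
  total <- c(active = 0, inactive = 0)
  for (s in c(1L, 0L)) {
    pState <- if (s == 1L) priorActive(model) else 1 - priorActive(model)
    pTx <- if (s == 1L) g$pTxActive else g$pTxInactive
    acc <- 0
    for (cfg in 0:(2^G - 1L)) {
      t <- as.integer(intToBits(cfg))[seq_len(G)]
      pConfig <- prod(ifelse(t == 1L, pTx, 1 - pTx))
      mu <- ifelse(t[match(ps$symbol, g$symbol)] == 1L, ps$muHigh, ps$muLow)
      acc <- acc + pConfig * prod(dnorm(x, mu, ps$sigma))
    }
    total[[if (s == 1L) "active" else "inactive"]] <- pState * acc
  }
  unname(total[["active"]] / sum(total))
}

# Random small network (<= 4 genes, <= 2 probesets per gene) with mixed
# response directions, for oracle-equivalence property tests.
randomSmallModel <- function() {
  nG <- sample(1:4, 1)
  syms <- paste0("G", seq_len(nG))
  dir <- sample(c("up", "down"), nG, replace = TRUE, prob = c(0.8, 0.2))
  pHi <- runif(nG, 0.55, 0.99)
  pLo <- runif(nG, 0.01, 0.45)
  genes <- data.frame(
    symbol = syms, direction = dir,
    pTxActive = ifelse(dir == "up", pHi, pLo),
    pTxInactive = ifelse(dir == "up", pLo, pHi),
    stringsAsFactors = FALSE)
  nPs <- sample(1:2, nG, replace = TRUE)
  probesets <- data.frame(
    probesetId = unlist(lapply(seq_len(nG), function(i)
      paste0(syms[i], "_p", seq_len(nPs[i])))),
    symbol = rep(syms, nPs),
    muLow = runif(sum(nPs), 3, 7),
    stringsAsFactors = FALSE)
  probesets$muHigh <- probesets$muLow + runif(sum(nPs), 0.3, 4)
  probesets$sigma <- runif(sum(nPs), 0.2, 1.2)
  newPathwayModel(genes, probesets, priorActive = runif(1, 0.2, 0.8))
}

randomProfile <- function(model) {
  ps <- panelProbesets(model)
  setNames(runif(nrow(ps), 2, 10), ps$probesetId)
}

# A tiny fixed two-gene model with hand-set parameters, used where tests
# want fully explicit CPT/emission values.
tinyModel <- function(prior = 0.4) {
  genes <- data.frame(
    symbol = c("GA", "GB"), direction = "up",
    pTxActive = c(0.9, 0.8), pTxInactive = c(0.2, 0.1),
    stringsAsFactors = FALSE)
  probesets <- data.frame(
    probesetId = c("GA_p1", "GB_p1"), symbol = c("GA", "GB"),
    muLow = c(4, 5), muHigh = c(8, 7.5), sigma = c(0.6, 0.4),
    stringsAsFactors = FALSE)
  newPathwayModel(genes, probesets, priorActive = prior)
}

# Paired scores (one row per patient) for two timepoints of a simulated
# longitudinal study; sample ids are <patient>_<timepoint>.
pairedScores <- function(study, scores, tp1, tp2) {
  cd <- SummarizedExperiment::colData(study$experiment)
  s <- setNames(scores$score, scores$sample_id)
  pats <- unique(cd$patient_id)
  data.frame(patient = pats,
             first = unname(s[paste(pats, tp1, sep = "_")]),
             second = unname(s[paste(pats, tp2, sep = "_")]))
}

# One-sided paired increase test; returns the p-value (1 when degenerate).
pairedIncreaseP <- function(first, second) {
  d <- second - first
  if (sd(d) == 0) return(1)
  t.test(second, first, paired = TRUE, alternative = "greater")$p.value
}
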