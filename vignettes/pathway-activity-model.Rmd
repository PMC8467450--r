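---
title: "Quantifying NF-kB pathway activity with a three-layer Bayesian network"
author: "pathsta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NF-kB pathway activity with a three-layer Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsta)
```

## The problem

A tumor's dependence on a signaling pathway is poorly captured by mutation
status or by the expression of pathway components: what matters functionally
is whether the pathway-driving transcription complex is actually
transcribing its target genes. For the NF-kB pathway — constitutively
activated in a subset of multiple myeloma and implicated in therapy
resistance through the pro-survival BCL-2 family — this package estimates
that functional output directly from a transcriptomic profile, sample by
sample, and wires the estimate into the downstream analyses a relapse study
needs: cohort comparisons, per-patient longitudinal trajectories, paired
fold-change classification of the six pro-survival BCL-2 transcripts, and
differential correlation of *BCL2A1* with the pathway's target genes.

## The model

The generative model is a tree-structured Bayesian network with three
layers:

1. a binary latent node $A \in \{\text{active}, \text{inactive}\}$ for the
   transcription-complex activity, with prior $P(A=\text{active}) = \pi$;
2. one binary transcription state $T_g$ per target gene, with a conditional
   probability table $P(T_g = 1 \mid A)$ — for an up-responsive gene the
   transcription probability is higher under the active state, mirrored for
   down-responsive genes;
3. continuous probeset-intensity evidence: each probeset $j$ of gene $g$
   emits a log2 intensity $x_j \sim N(\mu_{j,T_g}, \sigma_j)$, with
   $\mu_{j,1} \ge \mu_{j,0}$ after calibration (transcribed vs
   untranscribed state).

Genes are conditionally independent given $A$, and probesets given $T_g$,
so the posterior is exact and linear in the panel size:

$$P(A=\text{act} \mid x) \propto \pi \prod_g \sum_{t \in \{0,1\}}
  P(T_g = t \mid \text{act}) \prod_{j \in g} N(x_j;\, \mu_{j,t}, \sigma_j).$$

`inferActivity()` evaluates this in log space (log-sum-exp per gene),
reports the posterior, its log2-odds
$\log_2 \frac{p}{1-p}$ capped at $\pm 20$, and an activity **score**: the
affine map of the log2-odds from the normalization anchors
$[\ell_{lo}, \ell_{hi}]$ onto $[0, 100]$, clipped at the ends. The score is
monotone in the posterior, so ranking statements transfer.

The class of models the original pathway-activity literature describes
treats the evidence discretely; this implementation uses two-state Gaussian
class-conditional emissions (soft evidence) because hard intensity
thresholds are brittle on small panels, while the network semantics — and
everything downstream of the posterior — are unchanged. The test suite
checks the inference against a brute-force enumeration of the full joint
distribution on small random networks, so the factorized computation is
verified rather than assumed.

## The panel

The published NF-kB assay uses 50 probesets for 29 target genes, but their
identities and calibrated parameters are proprietary. The shipped default
(`defaultPanel()`, also at `inst/extdata/nfkb_panel_default.tsv`) is
therefore a *literature-derived* set of 16 canonical NF-kB targets
(NFKBIA, TNFAIP3, BIRC3, CCL2, CXCL8, ICAM1, IL6, TNF, TRAF1, BCL2A1,
BCL2L1, PLAU, PTGS2, VCAM1, SOD2, CD40) with one or two synthetic probeset
ids each — it reproduces the method, explicitly not the commercial panel,
and any panel file in the same format can be substituted.

## Calibration

`calibrateModel()` fits the emission layer from reference profiles with
known activity labels (`CalibrationSet`): per probeset, the
label-conditional means become $\mu_{j,1}/\mu_{j,0}$ (orientation decided
by the gene's response direction), with a pooled within-label standard
deviation floored at `sigmaFloor = 0.05` log2 units for numerical
stability; zero-variance probesets warn rather than fail. Gene-layer CPTs
default to 0.9/0.1 (mirrored for down-responsive genes): the source
literature publishes no values, and symmetric defaults keep the prior
interpretable. The prior defaults to an uninformative 0.5. The score
anchors are set to the minimum and maximum log2-odds observed on the
training samples and are *not* re-scaled per study cohort, so scores remain
comparable across cohorts; out-of-range samples clip to 0 or 100. Missing
probesets are always an error — silent imputation would bias scores.

An optional `pseudocount` shrinks the label-conditional means toward the
pooled probeset mean, `(n \cdot \bar{x}_{label} + k \cdot \bar{x})/(n+k)`;
the default $k = 0$ keeps calibration an exact method-of-moments fit.

## The synthetic-data generator

All tests run against generated data with known ground truth; no external
accession is needed. `simulateCohort()` draws each sample's latent state,
then gene transcription states from the model CPTs, then probeset
intensities `muLow + effectSize * T_g + N(0, noiseSd)`; background genes
and the six BCL-2 family genes (dedicated probesets `<SYMBOL>_f1_at`) are
noise around fixed baselines. `simulateLongitudinalStudy()` adds the paired
design: per-patient baseline offsets (sd 0.3 log2 units, which is what
makes paired analyses genuinely better than unpaired), an additive increase
of the latent activation probability at relapse timepoints, and an exact
`round(fraction * nPatients)` subset of patients whose BCL2A1 probeset is
multiplied by a configurable fold change at relapse.
`simulateCalibrationSet()` generates idealized two-level reference
profiles — transcription deterministic given the label — so the
calibration loop closes exactly at zero noise.

Default study conditions, chosen once as realistic for log2 microarray
intensities: effect size 3 (a strong target-gene induction), noise sd 0.5,
baseline activation probability 0.3 rising by 0.6 at relapse (the relapse
increase in the motivating study was consistent across all longitudinal
patients, so the emulated shift is large), 4 timepoints
(diagnosis, first/second induction, maintenance) with relapse at the
second-induction timepoint, fold-change magnitude 4 against the 2-fold
classification threshold, and a 62.5% BCL2A1-upregulated fraction matching
the 5-of-8 granularity of an 8-patient relapse series. By default the
BCL-2 family rows are *independent* of the latent pathway node
(`coupleBcl2 = FALSE`), which gives a clean null for the differential
correlation; setting `coupleBcl2 = TRUE` ties BCL2A1/BCL2L1/BCL2
transcription to the pathway state, as expected for direct NF-kB targets.

What the generator deliberately omits: probe-affinity effects, CEL-level
normalization artifacts (RMA/MAS5), batch structure, and dropout — the
analysis consumes normalized log2 intensities, so array physics adds
nothing testable here. Passing tests therefore demonstrate correctness of
the inference and analysis chain under the stated generative assumptions,
not robustness to raw-array artifacts.

## Downstream statistics

- `summarizeGroup()` reports n, median, quartiles (linear interpolation
  between order statistics; the convention is attached to the output
  because plotting software differs), min and max — the numbers a violin
  plot displays.
- `compareGroups()` is classical equal-variance one-way ANOVA with Tukey
  HSD adjusted pairwise p-values (Tukey–Kramer harmonic-mean adjustment for
  unequal group sizes). The Welch form was considered and not taken: the
  emulated analyses use the classical form, and scores share a common
  scale.
- `longitudinalTrajectories()` orders each patient's scores by the declared
  timepoint order, tolerates missing interior timepoints (ragged panels are
  the norm in longitudinal series), and reports the sign of last − first so
  "consistent increase" is assertable as *all signs positive*.
- `pairedFoldChange()` computes linear ratios $2^{\Delta \log_2}$;
  `classifyFoldChanges()` flags strict `> threshold` (default 2 — exactly
  2-fold is not ">2-fold") and reports per-gene percentages over all
  patients, partitioned into NF-kB-regulated (BCL2A1, BCL2L1, BCL2) and
  NF-kB-independent (BCL2L10, MCL1, BCL2L2) members.
- `differentialCorrelation()` regresses each target gene's paired log2
  difference on the anchor gene's and reports Pearson R, the two-sided
  regression p and the slope. Paired differencing removes per-patient
  baselines (an invariance the tests assert). No multiple-testing
  correction is applied across the target panel — the emulated analysis
  applies none — and the documentation flags this; a zero-variance anchor
  is an error, a zero-variance target returns R = 0.

For fold-change analyses, gene-level values default to *individual*
dedicated probesets (`rule = "specific"` with `bcl2FamilyProbesets()`);
`rule = "max_mean"` (highest mean intensity across samples) is the default
collapse elsewhere, since the probeset choices behind published analyses
are typically unstated.

## Numerical and design notes

- All inference is in natural-log space; per-gene mixtures use a
  log-sum-exp guarded against `-Inf` (degenerate CPTs of 0/1 are legal).
- The log2-odds cap of ±20 bounds the score map when calibration data are
  noiseless; with min/max anchors this maps the training extremes exactly
  to 0 and 100.
- Calibration orientation: for an up-responsive probeset calibrated with
  `muHigh < muLow` the means are swapped with a warning, preserving the
  layer invariant.
- Every generator takes an explicit integer seed, runs under a transient
  RNG state and restores the caller's stream; identical spec + seed is
  bit-identical.
- Problem sizes used by the shipped verification runs (tests and
  `scripts/acceptance.R`): 100 random ≤4-gene networks for the oracle
  check, 10-sample noiseless calibration closure, 100 replicate
  20-patient studies for detection power plus 400 null replicates for
  type-I calibration, the 8-patient fold-change study, and fixed 15- and
  8-point fixtures for the ANOVA/Pearson oracles. These sizes give stable
  rates while keeping a full run in well under a minute.

## Known limitations

- The default panel and all default parameters are *not* the proprietary
  calibrated assay; absolute scores are not comparable to published
  commercial scores, only the method's behavior is reproduced.
- The QC gate (`qcMatrix()`) covers missingness and scale plausibility
  only; array-level QC is out of scope and should happen upstream.
- With strongly informative panels the score distribution is nearly
  bimodal (0/100); the paired t-test on scores is then conservative-ish
  but calibrated at the sizes used (the null-rate check asserts this),
  and a rank-based alternative may be preferable for very small panels.
- One-sided claims about relapse increases use the study's declared relapse
  timepoints; the package does not infer which timepoint constitutes
  relapse.
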