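# pathsta

Single-sample quantification of NF-kB signal-transduction pathway activity
from transcriptomic profiles, with the downstream analyses of a
relapse study built in.

## What it does, and for whom

Whether the NF-kB transcription complex is functionally driving its target
genes in a tumor sample cannot be read off mutation status — the pathway
can be switched on at the receptor level, by intrinsic lesions, or by
cross-talk. For hematology/oncology groups working with expression
profiles of plasma-cell malignancies (and anyone needing single-sample
transcription-factor activity scores), `pathsta` infers, per sample, the
probability that the complex is actively transcribing, from the mRNA
evidence of its target genes.

The model is a tree-structured, three-layer Bayesian network. A binary
latent activity node $A$ with prior $\pi$; per target gene $g$ a binary
transcription state with CPT $P(T_g=1\mid A)$; per probeset $j$ of gene
$g$ Gaussian class-conditional log2-intensity evidence
$x_j \sim N(\mu_{j,T_g},\sigma_j)$. Genes are independent given $A$ and
probesets given $T_g$, so the posterior

$$P(A=\mathrm{act}\mid x)\ \propto\ \pi\prod_g\sum_{t\in\{0,1\}}
P(T_g{=}t\mid \mathrm{act})\prod_{j\in g}N(x_j;\mu_{j,t},\sigma_j)$$

is exact. It is reported as a posterior probability, a log2-odds value
(capped at ±20), and a 0–100 **activity score** — the clipped affine map
of the log2-odds between anchors learned at calibration. Around the
engine: calibration on labelled reference profiles, a ground-truth
synthetic-data generator (cohorts, calibration sets, paired longitudinal
studies), expression-matrix I/O (plain TSV and the GEO series-matrix text
dialect) with a QC gate, one-way ANOVA + Tukey HSD cohort comparisons,
per-patient trajectories, paired >2-fold classification of the six
pro-survival BCL-2 family transcripts, and differential correlation of
*BCL2A1* with the pathway's target genes.

The shipped 16-gene panel is literature-derived with synthetic probeset
ids; it reproduces the method, not any proprietary calibrated assay (see
the methods vignette, `vignettes/pathway-activity-model.Rmd`).

## Worked example

Calibrate a model on labelled reference profiles, score a simulated
8-patient longitudinal study, compare timepoints, and classify BCL-2
family fold changes between diagnosis and the post-relapse timepoint:

```r
library(pathsta)

model    <- defaultModel()
training <- simulateCalibrationSet(model, nActive = 25, nInactive = 25,
                                   noiseSd = 0.2, seed = 101)
fitted   <- calibrateModel(defaultPanel(), training)

study  <- simulateLongitudinalStudy(
  fitted, longitudinalSpec(nPatients = 8, noiseSd = 0.3, seed = 7))
scores <- scoreMatrix(fitted, study$experiment)
head(scores, 4)
#>         sample_id    posterior log2_odds score
#> 1   P01_diagnosis 1.000000e+00        20   100
#> 2 P01_induction_1 3.540706e-12       -20     0
#> 3 P01_induction_2 1.000000e+00        20   100
#> 4 P01_maintenance 1.000000e+00        20   100

cd <- SummarizedExperiment::colData(study$experiment)
compareGroups(split(scores$score, cd$timepoint)[
  c("diagnosis", "induction_1", "induction_2", "maintenance")])
#> One-way ANOVA across 4 groups
#>        group n median q1  q3 min max
#>    diagnosis 8     50  0 100   0 100
#>  induction_1 8      0  0   0   0 100
#>  induction_2 8    100 75 100   0 100
#>  maintenance 8    100 75 100   0 100
#> F(3, 28) = 3.326, p = 0.03384 (alpha = 0.05)
#> ...
```

Each sample's score is the normalized posterior evidence that NF-kB is
transcriptionally active: patient P01 scores 100 at diagnosis, 0 after
first-line induction, and 100 again after relapse. Across the cohort the
relapse timepoints sit at median 100 versus 50 at diagnosis (omnibus
p = 0.034) — the generator's built-in activity shift at relapse, recovered
by inference.

```r
design <- pairedDesignFromAnnotations(study$experiment,
                                      "diagnosis", "induction_2")
gm <- mapProbesets(study$experiment, rule = "specific",
                   genes = bcl2FamilyGenes(),
                   specific = bcl2FamilyProbesets())
classifyFoldChanges(pairedFoldChange(gm, design))
#> Paired fold-change classification (>2-fold), 8 patients
#>   nfkbRegulated :
#>     BCL2A1    62.5%
#>     BCL2L1     0.0%
#>     BCL2      12.5%
#>   nfkbIndependent :
#>     BCL2L10    0.0%
#>     MCL1       0.0%
#>     BCL2L2     0.0%
```

62.5% of patients (5/8) show >2-fold *BCL2A1* upregulation at relapse —
exactly the generator's ground truth (`study$truth$bcl2a1Upregulated`);
the single BCL2 flag is a noise draw, illustrating the false-positive
behavior at 0.3 log2 noise. A config-driven end-to-end run of the same
chain is available as `runPipeline()` (demo config in
`inst/extdata/demo_config.yaml`) and as the thin CLI wrapper
`inst/scripts/pathscore.R`.

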