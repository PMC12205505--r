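# kinorewire

Proteotranscriptomic analysis of **kinome rewiring** under EGFR-inhibitor
treatment: from kinase-level MIB-MS intensity matrices and RNA-seq count
matrices to differential-expression calls, time-course directional
classification, and directional kinase signatures with a full exclusion
audit trail.

The package is written for computational biologists studying adaptive
kinase reprogramming in drug-resistant cancer models — specifically the
setting of an isogenic EGFRvIII-driven glioma line (CEv3) and a panel of
TKI-resistant derivatives profiled by multiplexed inhibitor bead mass
spectrometry (MIB-MS; ~300 kinases quantified per run) under full-serum
(FS) and starved-serum (SS) culture, plus TMT time courses (0/4/24/48 h)
after acute EGFR-inhibitor challenge.

## What it computes

**Differential expression.**
Protein: per-gene linear models with batch covariates and empirical-Bayes
moderated t-statistics — residual variances shrunk as
s̃² = (d₀s₀² + d·s²)/(d₀ + d) with (d₀, s₀²) moment-fit from the log
residual variances; calls at FDR q < 0.05.
RNA: negative-binomial Wald tests with median-of-ratios size factors and
trend-shrunk method-of-moments dispersions; calls at q < 0.05 **and**
|log₂ fold change| > 1. Both use an in-package Benjamini–Hochberg step-up.
Missing MIB-MS intensities are imputed from a left-shifted Gaussian
N(μⱼ − 3σⱼ, (0.3σⱼ)²) per sample (detection-limit MNAR model).

**Temporal classification.** Per line: timepoint medians → per-gene
z-profiles scaled across the captured kinome → 2-cluster K-means
(k-means++ seeding, 10 restarts) with clusters labeled up/down by the sign
of the 48 h − 0 h mean difference; temporal-DE flags are the union of the
per-timepoint comparisons against the 0 h baseline.

**Signatures.**
*BL* (per resistant line): kinases uniquely DE in that line, aggregated
across FS and SS, minus cross-condition unique/shared conflicts and the
exogenous hEGFR construct (every exclusion logged with a reason).
*OL-BL*: kinases shared by ≥2 lines in both conditions with one consistent
direction. *EGFRi*: kinases temporally rewired uniquely in the parental
line after removing cross-line direction conflicts, split up/down.

**Downstream.** Cross-omics Pearson correlation of fold changes,
hypergeometric over-representation analysis, four-parameter-logistic IC50
fits (multi-start Levenberg–Marquardt), and Mantel–Cox log-rank tests with
Kaplan–Meier medians.

A synthetic-data module (`sim_config()`, `simulate_lfq_proteome()`,
`simulate_tmt_timecourse()`, `simulate_rnaseq_counts()`,
`simulate_dose_response()`, `simulate_survival_arms()`) generates
study-scale data with known planted ground truth, so every stage of the
pipeline is testable end to end.

## Worked example

The `analysis/` directory holds the full workflow as numbered drivers.
Running them in order simulates a study cohort, builds both signature
branches, and runs the downstream analyses:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_baseline_signatures.R
Rscript analysis/03_acute_egfri.R
Rscript analysis/04_downstream.R
```

which prints (seed 20260925):

```
LFQ: 300 kinases x 42 samples (10.0% below detection limit)
TMT: 300 kinases x 84 samples, 43 planted acute responders
planted: 30 BL-unique, 15 OL-BL shared, 26 up / 17 down acute
FS: DE kinases per line vs CEv3: E4=16, E5=15, G1=13, G5=16, G8=17, G12=14
BL signature sizes: BL_E4=6, BL_E5=6, BL_G1=5, BL_G5=4, BL_G8=4, BL_G12=5
OL-BL signature: 13 kinases
exclusions logged: 7 (hEGFR, cross-condition-conflict, direction-ambiguous)
BL recovery vs planted truth: precision 0.90, recall 0.90
temporal DE kinases per line: CEv3=55, E4=8, E5=8, G1=5, G5=7, G8=7, G12=7
EGFRi signature: 26 up, 19 down (45 total)
EGFRi recovery vs planted truth: precision 0.96, recall 1.00
EGFRi x baseline signatures: 6 shared kinases in total
cross-omics Pearson r = 0.61 (p = 2.1e-06, n = 50)
parental IC50 = 0.52 uM (hill 1.27)
resistant IC50 = 3.77 uM (hill 1.19)
```

Reading: the acquired-resistance branch recovers the planted per-line
unique kinases at precision/recall 0.90 with hEGFR and cross-condition
conflicts removed and logged; the acute branch recovers all 43 planted
parental-only responders (26 up recovered exactly; the down set carries
two extra genes from false temporal flags — see the methods vignette on
why FDR-controlled unions slightly overshoot); and the acute signature
barely overlaps the baseline signatures (6 kinases), mirroring the
distinctness of acute versus chronic rewiring. Signatures land in
`results/` as GMT files next to TSV exclusion logs and upset tables, each
stamped with a config hash and seed.

In code, the same branch runs are two calls:

```r
library(kinorewire)
cfg  <- sim_config(seed = 1)
lfq  <- simulate_lfq_proteome(cfg)
fs   <- subset_samples(lfq$matrix, lfq$matrix$samples$condition == "FS")
ss   <- subset_samples(lfq$matrix, lfq$matrix$samples$condition == "SS")
run  <- run_baseline_branch(list(FS = fs, SS = ss), run_config())
run$bl          # per-line BL signatures + exclusion log
run$ol_bl       # OL-BL signature
```

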