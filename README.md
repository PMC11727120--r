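# digitalCTC

Analysis pipeline for multiplex **real-time digital PCR** quantification of
circulating tumor cell (CTC) biomarkers in hepatocellular carcinoma (HCC).
The assay this package supports partitions a blood-derived lysate over
~20,000 microwells, monitors three dye channels (FAM, VIC, CY5) at every
thermal cycle, and measures six analytes at once: three surface proteins
read out as antibody-conjugated oligo tags (EpCAM, GPC-3, ASGPR — the
immuno-PCR principle) and three mRNAs (EpCAM, GPC-3, PD-L1). The package
takes the extracted per-well fluorescence traces and carries them through
well calling, absolute quantification, composite scoring, and 2D molecular
profiling. It is written for assay developers and computational biologists
working with partition-based digital PCR readouts.

## What it computes

**Well calling (M-PAM-style).** Every well × channel trace is fit with a
four-parameter logistic on a drifting baseline,
F(c) = F0 + d·c + A / (1 + e^(−k(c − c50))); the Ct is the 10%-amplitude
crossing Ct = c50 − ln(1/f − 1)/k and the growth rate is the normalized
maximum slope k/4. A well is positive only if the fit converges with
r² ≥ 0.98, the amplitude clears 5× its own baseline noise, the Ct falls in
(10, 38), and the rate clears a channel-specific floor.

**Poisson quantification.** With M of N partitions positive, copies per
reaction are

    X = −N · ln(1 − M/N)

with a Wilson-interval-propagated 95% CI. Around it: nonparametric limit
of blank, probit limit of detection (LOD95 = 10^((Φ⁻¹(0.95) − a)/b)), %CV,
standard curves, amplification efficiency, and a 2^−ΔΔCt utility.

**Composite scoring.** Copies → log2(x+1) → per-marker Z-scores → weighted
sum, with weights from the analytic hierarchy process (principal
eigenvector of a reciprocal pairwise comparison matrix, consistency-ratio
checked); plus ridge-stabilized logistic combination and ROC analysis with
a Youden-optimal cutoff.

**2D profiling.** ASGPR-calibrated protein–mRNA coordinates per sample,
a support-vector (poly kernel) P1/P2 region boundary anchored on the
healthy centroid, per-cohort region proportions, treatment efficacy
vectors, and Spearman correlations with permutation p-values.

A seeded simulator (`simulatePlate`, `simulateCohort`,
`simulateDilutionSeries`) generates plates, cohorts and dilution series
with known ground truth, so the full chain is testable end to end.

## Worked example

Simulate a 20,000-well, three-channel protein plate loaded with 500
template molecules per channel, call it, and quantify:

```r
library(digitalCTC)

run   <- simulatePlate(plateSimParams(nWells = 20000, targetCopies = 500,
                                      regions = "protein",
                                      channels = c("FAM", "VIC", "CY5")),
                       seed = 1)
calls <- callPlate(run)
calls
#> PlateCalls: 60000 wells analyzed, 1470 positive
#>   region channel   M     N ct_mean  ct_sd rate_mean rate_sd
#>  protein     CY5 491 20000   25.77 1.1999    0.2539 0.07196
#>  protein     FAM 490 20000   26.83 0.9221    0.3890 0.07455
#>  protein     VIC 489 20000   26.51 0.8946    0.6532 0.16348

quantifyPlate(calls)
#>    region channel        marker   M     N copies ci_low ci_high saturated
#> 1 protein     CY5 ASGPR_protein 491 20000 497.13 455.04  543.06     FALSE
#> 2 protein     FAM EpCAM_protein 490 20000 496.10 454.06  541.99     FALSE
#> 3 protein     VIC  GPC3_protein 489 20000 495.08 453.08  540.92     FALSE
```

With 500 molecules in 20,000 wells the Poisson occupancy law predicts
20000·(1 − e^(−500/20000)) ≈ 494 positive wells; the caller counts
489–491 per channel, and inverting the occupancy returns 495–497 copies —
within 1% of the loaded amount, with the true value inside every CI. The
per-channel Ct and growth-rate means (26.83/26.51/25.77 cycles;
0.39/0.65/0.25 per cycle) reproduce the configured channel distributions.

Score a simulated clinical-style cohort and assess separation:

```r
ce <- simulateCohort(cohortDesign(), seed = 2)   # 24 HD / 31 early / 22 advanced
sr <- scoreCohort(ce)
sr
#> ScoreResult: 77 samples, reference = all
#>   weights: EpCAM_protein=0.167 ... PDL1_mRNA=0.167
#>   AHP consistency ratio: 0
#>   composite score range: -1.39 ..  1.49

rocAnalysis(compositeScores(sr), cohortLabels(ce) != "HD")
#> ROC: AUC = 0.8019; Youden cutoff -0.1393 (sens 0.698, spec 0.917)
```

The composite score separates simulated HCC from healthy donors with
AUC 0.80 under the default (deliberately overlapping) cohort design; the
printed cutoff maximizes Youden's J with ties broken toward specificity.

The full pipeline — simulate → call → quantify → score → profile →
report — runs as one deterministic call:

```r
res <- runPipeline(pipelineConfig(seed = 1), outDir = "out")
```

writing `calls.csv`, `quant.csv`, `scores.csv`, `regions.csv`,
`efficacy_vectors.csv`, a manifest with file checksums, and `report.json`.
A thin command-line wrapper is at `inst/scripts/ctcpipe.R`.

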