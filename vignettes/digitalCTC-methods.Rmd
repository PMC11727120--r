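---
title: "Methods: digital PCR quantification and multi-marker scoring of CTC biomarkers"
author: "digitalCTC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital PCR quantification and multi-marker scoring of CTC biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitalCTC)
```

## The measurement problem

Circulating tumor cells (CTCs) in hepatocellular carcinoma (HCC) are rare
and phenotypically heterogeneous: epithelial–mesenchymal transition can
silence individual surface markers, so single-marker enumeration misses
real tumor cells. The assay this package analyzes measures six analytes at
once on a microwell digital PCR chip: three surface proteins (EpCAM, GPC-3,
ASGPR), each converted to a countable oligonucleotide tag by an
antibody–oligo conjugate (immuno-PCR), and three mRNAs (EpCAM, GPC-3,
PD-L1). The chip partitions each region's lysate into ~20,000 microwells,
thermocycles for 40 cycles, and images every well in three dye channels
(FAM, VIC, CY5) at every cycle. The package consumes the extracted per-well
fluorescence traces and carries them to absolute copy numbers, a composite
diagnostic score, and a 2D protein–mRNA profile per sample.

## Per-well amplification model and calling

Each well × channel trace is modeled as a four-parameter logistic on a
drifting baseline:

$$F(c) = F_0 + d\,c + \frac{A}{1 + e^{-k(c - c_{50})}} + \varepsilon_c,
\qquad \varepsilon_c \sim N(0, \sigma^2).$$

The instrument's own analysis model is not published beyond its criteria
classes (curve shape, Ct, growth rate), so this package fixes a concrete,
fully configurable realization:

* **Smoothing** (`smoothTrace`): centered moving average, default window 5,
  with symmetrically shrinking windows at the edges so linear signals are
  exact fixed points.
* **Fit** (`fitAmplificationCurve`): Levenberg–Marquardt least squares
  (via `minpack.lm`), initialized from the data (F0 = min, A = range,
  c50 = cycle of the largest first difference, k = 0.5). Non-convergence is
  a negative call, never an error, so a plate always yields counts.
* **Ct** (`computeCt`): threshold crossing of the drift-corrected logistic
  at 10% of amplitude, $Ct = c_{50} - \ln(1/f - 1)/k$; at $f = 0.5$ the Ct
  is exactly $c_{50}$.
* **Growth rate** (`computeGrowthRate`): the maximum slope of the
  amplitude-normalized logistic, $k/4$. This scale is what makes the
  channel-level summaries comparable across wells: on it, the three
  channels center at 0.39, 0.66 and 0.25 intensity per cycle.
* **Positivity** (`classifyWell`): conjunctive rule — converged fit,
  $r^2 \ge 0.98$, amplitude at least 5× the well's own baseline noise sd
  (estimated from the residuals of a line fit to the first 8 cycles),
  Ct within (10, 38), and normalized rate at least the channel floor.
  Comparisons are inclusive: a well exactly at a threshold is positive.

**Growth-rate floors.** The per-channel floors default to the channel mean
minus three channel standard deviations (FAM $0.39 - 3{\times}0.07 = 0.18$;
VIC $0.21$; CY5 $0.04$). A floor near half the channel mean — an otherwise
natural choice — would sit less than 2 sd below the CY5 mean and
systematically discard a few percent of genuinely amplifying CY5 wells;
three sigma keeps the rule discriminative against negatives (whose fitted
rates are meaningless) while losing only ~0.1% of true positives per
channel.

**Throughput.** `callPlate` applies a vectorized pre-screen before the
nonlinear fit: a trace that an ordinary straight line already explains to
within 3× its baseline noise sd has no amplification component above the
amplitude floor and is recorded as negative with reason `"amplitude"`.
Only the remaining candidates (all true positives, plus <1% of noise
traces) receive the full 4PL fit, which keeps a 120,000-trace plate under
a minute on one core. `classifyWell` on a single trace always runs the
full fit, so screened negatives may report fewer failure reasons than an
exhaustive evaluation would.

## Poisson absolute quantification

With M of N equal partitions positive, the per-reaction template load is

$$X = -N \ln\!\left(1 - \frac{M}{N}\right),$$

the inverse of Poisson occupancy. The 95% interval comes from the Wilson
score interval on $p = M/N$ pushed through this monotone transform — the
assay itself reports no partition-level interval, so this is the package's
choice, made because Wilson behaves well at the small-$p$ loads typical of
blood samples. A saturated plate (M = N) has no finite estimate and is
reported at $M = N - 0.5$ with a `saturated` flag. Copies are reported per
reaction; any conversion to copies per mL of blood is a user-supplied
`dilutionFactor`, off by default, because the relation between reaction
input and blood volume is protocol-specific.

Assay analytics follow standard clinical-assay practice: the limit of
blank is the nonparametric 95th percentile of replicate blanks with the
rank-interpolation convention $r = 0.5 + p\,n$ (so blanks 1..12 give
exactly 11.9); the limit of detection is probit regression of detected
fraction on log10 concentration, $LOD_{95} = 10^{(\Phi^{-1}(0.95) - a)/b}$,
flagged non-converged when detection saturates or is non-monotone; %CV uses
the n−1 sd; standard curves are OLS of copies on cell count; amplification
efficiency is $(10^{-1/\text{slope}} - 1) \times 100\%$. The
$2^{-\Delta\Delta Ct}$ utility is included only for comparison with
relative quantification.

## Composite digital score

Copies are transformed $\log_2(x+1)$, Z-standardized per marker, weighted,
and summed:

$$\text{score}_i = \sum_{j=1}^{6} w_j \, z_{ij}.$$

Two choices here were genuinely open:

* **Reference population.** The marker heatmap convention standardizes
  within the analyzed batch, so `reference = "all"` is the default;
  `reference = "healthy"` standardizes against the healthy cohort and is
  the right choice for diagnostic scoring of new samples. The reference
  and its statistics are recorded in the `ScoreResult`.
* **Weights.** Weights come from the analytic hierarchy process: the
  principal eigenvector (power iteration, tolerance 1e-10) of a reciprocal
  pairwise comparison matrix, with consistency ratio
  $CR = \frac{(\lambda_{max} - n)/(n - 1)}{RI_n}$ (Saaty indices,
  $RI_6 = 1.24$) and an error above $CR > 0.1$ unless overridden. The
  authors' pairwise judgments are not public, so the shipped default is
  the neutral all-ones matrix (equal weights 1/6); users supply their own
  matrix to encode expert priorities.

Diagnostics are computed both ways the field reports them: directly on the
composite score, and on predicted probabilities from a binary logistic
fit. The logistic solver is Newton–Raphson with a small L2 ridge (1e-6,
intercept unpenalized) so perfectly separable small cohorts return finite
coefficients with a `separation` flag instead of diverging. ROC AUC is the
Mann–Whitney rank statistic (ties half credit); the reported cutoff
maximizes Youden's J, with ties broken toward the higher-specificity
cutoff — a deliberate, documented convention, since a diagnostic score
favors fewer false positives at equal J.

## 2D protein–mRNA profiling

Samples capture different numbers of CTCs, so raw copies are not
comparable across samples. Each sample's EpCAM and GPC-3 protein and mRNA
copies are divided by its ASGPR protein copies plus a pseudocount of 1
(`asgprCalibrate`), using ASGPR — a hepatocyte-lineage marker present on
captured liver-derived cells — as a per-sample cell-load surrogate. The
published description does not print the calibration formula; the
ratio-with-pseudocount is this package's interpretation, configurable, and
stated as such. Classification and efficacy vectors operate in calibrated
linear space; any log scaling is display-only, so displacement vectors
keep their physical meaning.

On the calibrated (mRNA, protein) plane a two-class boundary is trained
(`fitRegionClassifier`): support-vector classification with linear,
polynomial (degree 3, C = 1, the default and the best performer in the
source experiments) or radial kernels via `e1071`, plus a Gaussian naive
Bayes baseline ("GSNB" read as Gaussian naive Bayes). Features are
standardized with training-set mean/sd. Region **P1** is defined as the
boundary side containing the healthy-cohort centroid, **P2** the other
side, so region semantics never depend on arbitrary class coding.
Accuracy/precision/recall/F1 come from stratified 5-fold cross-validation
with seed-controlled fold assignment (k reduced with a warning if a class
is smaller than k).

Treatment response is the **efficacy vector**: the displacement of a
patient's calibrated coordinates from pre- to post-treatment, with
Euclidean magnitude and angle in degrees counterclockwise from +x in
[0, 360); a zero displacement has an undefined angle and is flagged. The
per-patient combined response is the componentwise sum of the EpCAM and
GPC-3 vectors, which makes path additivity
(pre→mid plus mid→post equals pre→post) exact.

Spearman correlations (marker cross-correlations, protein–mRNA
concordance) use the Pearson correlation of mid-ranks with a
permutation p-value (default 9999 permutations, fixed seed, +1
correction).

## The simulator: what it emulates, what it does not

Every stage is validated against seeded generators with known truth:

* `simulatePlate` places `round(λ)` molecules into N wells independently
  and uniformly (multinomial), so the realized load is conserved exactly
  and per-well counts are approximately Poisson(λ/N) — the regime the
  quantifier inverts. Occupied wells get 4PL traces whose Ct and
  normalized rate are drawn from the per-channel normal distributions
  observed on the instrument (Ct 26.83 ± 0.88, 26.46 ± 0.86,
  25.73 ± 1.21; rates 0.39 ± 0.07, 0.66 ± 0.15, 0.25 ± 0.07), with
  amplitude 1 ± 0.05, baseline 0.1, drift 0.001/cycle and read noise
  sd 0.02 in normalized units — values chosen once as representative of a
  well-behaved chip run. Rate and amplitude draws are truncated at small
  positive floors (0.02 and 0.2) since an amplifying well cannot have a
  non-positive rate.
* `simulateCohort` draws six-marker copies per cohort from log-normals
  with a dropout probability that collapses a marker to blank-level
  background (log-normal around 5 copies) — dropouts exercise the LOB
  logic and mirror marker-silent CTC profiles. The default design uses
  cohort sizes 24/31/22 (healthy/early/advanced) and anchors the location
  parameters on representative healthy and advanced-case copy numbers,
  with the early cohort at their geometric mean.
* `simulateDilutionSeries` draws detected counts Binomial(reps,
  Φ(a + b log10 c)), the exact model the probit LOD fit assumes.

Not modeled, deliberately: optics and image formation, partition-volume
variability (wells are treated as equal volume), cross-channel spectral
bleed-through, and multi-molecule Ct advancement (a well's Ct is drawn
from the channel distribution regardless of its molecule count; at the
loads of interest multiply-occupied wells are rare). Passing tests
therefore demonstrate correctness of the analysis chain under ideal
partitioning and clean single-channel signals, not robustness to optical
crosstalk or volume dispersion.

## Problem sizes and numerical choices

The validation suite runs plates at the assay's native size (N = 20,000
wells, 40 cycles; three channels for calling accuracy; 50 seeds at
λ = 1000 for end-to-end recovery), 200 occupancy draws for CI coverage,
10,000-replicate dilution series for LOD recovery, and 500-per-class
cohorts for the designed latent-AUC check — sizes at which the binomial
and Monte-Carlo standard errors are well inside the asserted tolerances.
Key numerical conventions: thresholds compare inclusively; power iteration
stops at 1e-10; the logistic ridge is 1e-6; ROC tie handling is
Mann–Whitney; the LOB is clipped to the observed blank range; saturated
Poisson counts are substituted at M − 0.5 and flagged.

## Known limitations

The calling thresholds are declared defaults, not a claim to reproduce the
instrument vendor's unpublished values; clinical quantities reported with
the original assay (e.g. AUC 0.950 on 99 patients, LOD 3.2 CTCs/mL) derive
from undeposited patient and instrument data and are not reproducible
here — the package instead verifies every computational step against
closed forms and generators with known truth. The steep-channel (VIC)
growth-rate estimates carry a small upward fit bias (~3%) from sampling a
fast transition at integer cycles; Ct estimates are unbiased. The AHP
default weights are neutral; conclusions that depend on marker priorities
require a user-supplied comparison matrix.
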