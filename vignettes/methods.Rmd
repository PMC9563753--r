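---
title: "Methods: from MALDI peak lists to RCC lipid classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MALDI peak lists to RCC lipid classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingodx)
```

`sphingodx` implements a complete screening workflow for sulfatides,
sphingomyelins and sterol sulfates in body fluids and tissues of renal
cell carcinoma (RCC) patients: annotation of negative-mode MALDI Orbitrap
peaks, inclusion-criteria quantitation, nonparametric per-lipid inference,
and ridge-logistic diagnostic modeling. This vignette explains the models
behind each stage, the tunable parameters, and the choices made where the
design was genuinely open.

## 1. Lipid annotation model

Shorthand names are interpreted as a ceramide core with `n` total chain
carbons, `d` double bonds and `k` hydroxyl-type oxygens
(`;Ok`, with `k` between 2 and 4 for sphingolipids), of composition
C~n~H~2n+1−2d~NO~k+1~. Head groups are added as condensation residues:

* **SM**: phosphocholine (C~5~H~14~NO~4~P − H~2~O);
* **SHexCer**: one anhydrohexose C~6~H~10~O~5~ plus SO~3~;
* **SHex2Cer**: two anhydrohexoses plus SO~3~.

Species-level names (`SHexCer 18:1;O2/12:0`) sum base and acyl descriptors
into the sum-level key; each sum-level name is treated as a single
channel, since isomeric species-level signals are not resolved by full
scans. Sterol sulfates (`StS 1` … `StS 11`) are opaque identifiers whose
compositions are not published; they must carry a user-supplied formula or
m/z, and the generator's StS masses are synthetic placeholders (labelled
as such) spaced more than 50 ppm apart.

Ion m/z uses a single-isotope monoisotopic table (¹²C = 12 exactly) and
the class adduct rule: [M−H]⁻ for sulfatides and StS, [M−CH₃]⁻ for SM.
The electron mass (0.549 mDa) is added to the anion: at a resolving power
of 100,000 the peak width near m/z 700 is about 7 mDa, so half a
millidalton is a visible bias, not a rounding detail.

## 2. Ingest

Peak assignment matches each database entry to the observed peak with the
smallest absolute ppm deviation inside a symmetric window
(`tolerance_ppm`, default 5 ppm — a conservative bound for an Orbitrap at
R = 100,000; the upstream vendor tooling's window is not documented, so
the value is configurable). When the windows of two entries overlap on
one peak, the nearer entry keeps it and the loser falls back to its
next-nearest in-window candidate; assignment depends only on m/z, never
intensity, and is invariant to peak order. Five replicate depositions per
sample are reduced by the **median**, with unassigned replicates counted
as 0 — the median, not the mean, because a failed deposition should not
drag the sample value. Samples with fewer than five replicates are
accepted with a warning; no hard replicate requirement is imposed.

## 3. Quantitation

The inclusion flow runs in a fixed order: presence filter → QC-CV filter
→ subject exclusion → floor imputation → normalization.

* **Criterion 1 (presence)**: a lipid is kept iff its intensity exceeds
  the floor (8000, the lowest reproducible intensity) in at least
  `presence_min_fraction` (default 0.5, inclusive) of the samples of
  *both* groups. "Present" is operationalized as intensity > floor, the
  same coding the presence/absence analysis uses; presence is assessed on
  the replicate-aggregated matrix.
* **Criterion 2 (QC CV)**: sd/mean of the raw, unimputed QC intensities
  must be strictly below `qc_cv_max` (default 0.35). The sample standard
  deviation (n−1) is used, standard analytic practice.
* **Criterion 3 (subject exclusion)**: a sample is dropped when strictly
  more than `subject_exclusion_fraction` (default 0.5) of the panel lies
  below the LOQ, or when any internal-standard channel falls below the
  LOQ (high matrix effect). The report carries a reason code per subject.
* **Imputation**: all sub-LOQ cells are set to the floor (8000);
  idempotent, and it guarantees strictly positive values for ratio and
  log-based statistics downstream.
* **Concentrations**: molar mode divides by the class internal standard
  and multiplies by its spiked amount (plasma: 0.1 nmol/mL SHexCer
  18:1;O2/12:0 and 43.3 nmol/mL SM 18:1;O2/12:0; urine: 0.04 nmol/mL
  SHexCer IS and 0.55 nmol/mL deuterated taurocholic acid). Relative mode
  divides by the per-sample class sum (SM, sulfatide = SHexCer +
  SHex2Cer, StS; IS channels excluded) × 100. Downstream statistics
  default to relative mode, which is invariant to per-sample global
  intensity scaling and therefore robust to the large analytical variance
  molar urine/tissue concentrations show.

## 4. Per-lipid inference

The fold change is a Hodges–Lehmann-type estimator: the median of all
n~T~ × n~N~ pairwise ratios. It is exactly scale-equivariant
(FC(c·x, x) = c) and robust to outliers. For paired tissue a paired-ratio
option exists, but the default uses all pairwise ratios, matching the
estimator's definition; fold change and FDR are always reported as
separate columns.

Hypothesis tests are nonparametric throughout (the intensity
distributions are skewed): Mann–Whitney U for independent groups, the
Wilcoxon signed-rank test for tumor/nontumor pairs, Kruskal–Wallis across
stage or grade brackets. Exact distributions are used where enumeration
is cheap — both groups ≤ 8 (Mann–Whitney) or ≤ 15 nonzero pairs
(signed-rank), tie-free — and the normal approximation with tie and
continuity correction elsewhere. Effect sizes are the rank-biserial
r = 2U/(n~x~n~y~) − 1 and epsilon-squared ε² = H/(n − 1). When the
Kruskal–Wallis BH-q passes the gate (default 0.05), Conover–Iman t
statistics on pooled ranks give pairwise p values, themselves
BH-adjusted across pairs — the global FDR policy applied locally, since
no specific post hoc adjustment is prescribed. All per-panel p values are
Benjamini–Hochberg adjusted.

Channels failing criterion 1 go to the presence/absence track: 2×2
Fisher exact tests (conditional-MLE odds ratio) for fluids, exact
binomial McNemar tests on discordant pair counts for tissues. Spearman
screens relate age and BMI to each lipid with pairwise-complete handling
of missing covariates.

Clustering summaries log10-transform and Pareto-scale the selected
channels, then apply Ward's method (`hclust` ward.D2, the Lance–Williams
update on squared Euclidean distances) and export the merge tree as
Newick plus a per-lipid z-score matrix — the tabular inputs of circular
dendrogram/heat-map figures.

Figure-style significance stars combine effect size and FDR
(`significance_stars`): |r| ≥ 0.5 / 0.3 / 0.1 with q < 0.05 map to
***/**/*. These thresholds are a package convention, configurable.

## 5. Classification

Each task (plasma all-cases, plasma T1-2, plasma T3-4, urine all-cases vs
controls) uses 33 relative lipid concentrations plus gender (0/1) and BMI
(missing values imputed by the within-group median). Age is excluded: it
is not balanced between cases and controls, so it would encode cohort
composition rather than biology.

* **Preprocessing**: lipids are log10-transformed; all features are
  Pareto-scaled, (v − mean)/√sd, with statistics from training rows only.
  Pareto scaling damps the dominance of high-variance channels without
  fully whitening. Gender is scaled with the rest for simplicity.
* **Split**: stratified 60/40 with a fixed, logged seed; the training
  minority class is resampled with replacement to balance prevalence;
  test rows are never duplicated.
* **Model**: ridge logistic regression minimizing mean negative
  log-likelihood + λ‖β‖²/2 with an unpenalized intercept, by damped
  Newton/IRLS to gradient norm < 1e-8 (iteration cap 100 guards
  separable data at tiny λ; non-converged λ values are skipped). The mean
  (not summed) likelihood makes λ comparable across cohort sizes. The λ
  grid is 50 values log-spaced over [1e-4, 1e2], spanning the
  null-to-saturated penalty regimes on standardized features; λ maximizes
  the mean out-of-fold AUC over 5 stratified folds, with preprocessing
  refit inside each fold so no held-out row leaks into the statistics.
* **Reporting**: AUC is the Mann–Whitney rank statistic (ties ½) with
  DeLong 95% CIs; confusion metrics at probability 0.5 carry exact
  Clopper–Pearson binomial CIs. Reports serialize to JSON with the seed
  and config captured.

## 6. What the synthetic generator emulates — and what it does not

Subject intensities are log-normal around per-channel baselines (default
between-subject log-sd 0.5, i.e. a biological CV near 55%, typical for
sphingolipid panels), multiplied in cases by a stage-bracket effect: the
T3-4 multiplier defaults to 2.0 (up) or 0.5 (down) and the T1-2
multiplier to its square root, producing the gradual stage trend the
stage analysis expects. The dysregulation directions are fixed a priori:
long-chain SM and hydroxylated sulfatides down, polyunsaturated SHexCer
and lactosylsulfatides up, plus two cortisol-like StS up and two
lithocholic-like StS down in urine. Exact per-lipid magnitudes of the
real cohorts are not published in the main text, so the defaults are
calibrated to direction and trend only.

Around that signal the generator reproduces the acquisition structure:
five depositions at 10% replicate CV, pooled QC samples at 15% CV, LOQ
censoring at 8000 (sub-LOQ replicates are not detected), fixed-abundance
IS channels, designated low-signal subjects (urine default 3 controls +
24 cases, globally attenuated ×0.01 so criterion 3 must flag them), 10%
missing BMI, cases older and more often male than controls, tissue pairs
sharing a subject-level log-normal effect, ±2 ppm uniform mass jitter and
decoy peaks ≥ 50 ppm from every channel.

It does **not** emulate isotope envelopes, matrix clusters, chemical
noise beyond decoys, extraction-recovery differences, response-factor
drift across chain lengths, or inter-batch effects. Passing tests
therefore demonstrate the correctness and calibration of the
computational path under the assumed noise model — not clinical
performance on real cohorts, where analytical variance has heavier tails
and the true effect magnitudes are unknown.

## 7. Numerical choices and degenerate inputs

* Even-count medians are the mean of the central pair everywhere
  (ratios, replicates).
* All-tied groups give p = 1; zero paired differences are dropped, all
  zero → p = 1; zero discordant pairs → McNemar p = 1 with a note.
* Constant features are dropped (with a warning) by the Pareto fit;
  constant covariates in Spearman screens are reported missing with a
  reason, as are screens with fewer than 4 complete pairs.
* QC channels with zero mean are dropped with a message rather than
  producing an undefined CV.
* Ties in peak assignment cannot arise from equal |Δppm| in continuous
  data; if they do, the first (lower-m/z) candidate wins determinately.
* RNG: every generator stage seeds deterministically from the config
  seed (cohort: seed, intensities: seed+1, peaks: seed+2), so identical
  seed + config is byte-identical across runs; derived seeds stay far
  below 2³¹.

## 8. Problem sizes used by the checks

The test suite runs the study at reduced but structurally identical
sizes: oracle equivalence on 1000 random fold-change pairs, 200 score
sets and Ward trees to n = 12; exact-test enumeration to 8/8 and 10
pairs; null calibration on 500 panels × 33 lipids at n = 50/50 with a
BH-FDR check over 150 replicates at 20% true effects; direction recovery
at n = 100/100; classifier null coverage over 100 replicates at n = 120
and a late-stage-like separation check at n = 100/100. The acceptance
script runs the full default cohorts (350 plasma, 170 urine, 77 tissue
pairs) end to end.

## 9. Known limitations

* Sum-level channels conflate isomeric species; a resolved species-level
  analysis would need MS/MS evidence outside this scope.
* The exact train/test partitions of the original cohorts are not
  public, so printed clinical AUCs are seed-dependent quantities here;
  the package reports its own synthetic-cohort values instead.
* PCA and the rendering of volcano/radar/network/dendrogram graphics are
  out of scope; the workflow produces their tabular inputs.
* Positive-mode adducts, isotope-pattern prediction and hexose isomer
  (Gal/Glc) resolution are not implemented.
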