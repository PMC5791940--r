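---
title: "Quantifying intratumoral heterogeneity on FDG-PET and relating it to progression-free survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral heterogeneity on FDG-PET and relating it to progression-free survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pethet)
```

## The problem

Tumors that look identical by size or maximum tracer uptake can differ
sharply in how their metabolism is organized in space. That spatial
disorder — intratumoral metabolic heterogeneity — is a plausible imaging
correlate of clonal diversity, and clonal diversity is a leading explanation
for why targeted therapies such as EGFR tyrosine kinase inhibitors (TKI)
fail early in some mutation-positive non-small cell lung cancer patients.
`pethet` implements a complete pipeline for testing that idea on
pretreatment FDG-PET: segment the lesion, standardize its gray scale,
summarize its texture with local and regional matrix statistics, screen the
resulting parameters, and ask — with optimal-cutoff dichotomization, Cox
models, and Harrell's concordance index — whether heterogeneity predicts
progression-free survival (PFS) on TKI beyond conventional prognostic
factors.

## Image model and segmentation

A `pet_volume` is a 3D grid of standardized uptake values,

$$\mathrm{SUV} = \frac{\text{activity concentration (kBq/mL)}}
{\text{injected dose / body weight (kBq/g)}},$$

the body-weight normalization (rather than lean body mass), with voxel
spacing in mm carried alongside. `compute_suv` applies the conversion when
a volume arrives in raw activity units; scanner decay correction is assumed
to have happened upstream.

Segmentation is a fixed isocontour: the 26-connected component of voxels
with SUV at or above the threshold (default 3.5, inclusive) that contains a
user-placed seed. A fixed absolute threshold suits lesions on low-uptake
background; it is deliberately simple, deterministic, and invariant to the
choice of seed within a component. If the seed itself is below threshold,
the nearest supra-threshold voxel within a small radius (default 3 voxels)
is adopted, so an approximate click inside a hot lesion still works; beyond
that radius the segmentation fails loudly rather than guessing.

From the mask come the conventional parameters: SUVmax, SUVaverage,
metabolic volume (MV, voxel count times voxel volume, cm³), and a binary MV
category at 45 cm³ — a conservative volume cutoff used later to keep the
texture parameters' prognostic claims honest against tumor bulk.

## Gray-level quantization

Texture matrices need a small discrete alphabet. The segmented SUVs are
recoded to $L = 64$ levels relative to the in-mask range:

$$\ell(v) = \min\!\left(L,\; 1 + \left\lfloor
L\,\frac{\mathrm{SUV}(v) - v_{\min}}{v_{\max} - v_{\min}}
\right\rfloor\right),$$

with a constant region mapping to level 1. Min–max relative binning
normalizes scale across patients and scanners; the price is that any affine
rescaling of the lesion values is invisible downstream (a property the test
suite checks explicitly), and that in a nearly homogeneous lesion the
scheme stretches whatever variation remains — including the noise floor —
across all 64 levels. Both consequences are discussed again under the
synthetic generator. Whether to bin relative to the lesion range or on an
absolute SUV grid is a genuinely open design choice in PET radiomics;
relative binning is implemented here and flagged in the documentation.

## Texture families and the eight parameters

All four families are built on the quantized lesion, aggregating the 13
unique 3D directions (and both orientations where relevant) into a single
matrix before any statistic — not one matrix per direction averaged after.
The offset is one grid step with no mm correction on anisotropic voxels.

* **Co-occurrence (Co, local).** $p(i,j)$ is the normalized count of
  level pairs one step apart. Entropy
  $-\sum p(i,j)\log_2 p(i,j)$ (base 2 by default, configurable) measures
  pair randomness; homogeneity $\sum p(i,j)/(1+|i-j|)$ concentrates on the
  diagonal. A uniform lesion has entropy 0 and homogeneity 1.
* **Neighborhood intensity difference (NID, local).** For each voxel with
  at least one in-mask 26-neighbor, the absolute difference between its
  level and its neighbors' mean level is accumulated per level ($s_i$),
  with $p_i$ the level frequencies. Busyness
  $\sum_i p_i s_i / \sum_{i \ne j} |i p_i - j p_j|$ captures rapid local
  change; contrast couples the dynamic range of present levels with the
  mean neighborhood difference. Both are defined as 0 when their
  denominator vanishes, so degenerate uniform tumors pass through rather
  than crash. Voxels with no in-mask neighbor are skipped, which keeps thin
  lesions usable.
* **Run length / voxel alignment (VA, regional).** Maximal runs of equal
  level along each direction, summed over the 13 directions (an isolated
  voxel therefore contributes 13 unit runs). Intensity variability
  (gray-level nonuniformity) $\sum_g (\sum_r R_{gr})^2 / n_{\text{runs}}$
  and short-run emphasis $\sum_{g,r} R_{gr} r^{-2} / n_{\text{runs}}$.
* **Size zone (ISZ, regional).** 26-connected equal-level zones;
  intensity variability as above over zones, and high-intensity-zone
  emphasis $\sum_{g,s} Z_{gs}\, g^2 / n_{\text{zones}}$.

`extract_features` returns these eight heterogeneity parameters plus the
conventional values and minimal global histogram features (mean, variance,
gray-level entropy); the global family is kept minimal because the
screening stage never selects it. Single-voxel masks have no voxel pairs,
so the Co features are returned as `NA` with a `no_pairs` flag while the
regional features stay defined.

Every matrix builder is validated against naive exhaustive-enumeration
oracles (double loops over voxel pairs, walked runs, flood-filled zones) on
hundreds of random small blobs, and the closed-form toy cases in the help
pages are asserted exactly.

## Screening and the eight-parameter panel

Across a cohort, each parameter is Spearman-rank-correlated against
co-occurrence entropy, the working reference measure of heterogeneity.
Ties get average ranks; P-values use the asymptotic t approximation (ties
preclude the exact permutation distribution, and the intended cohort sizes
are asymptotic territory); significance is Bonferroni-adjusted over the
non-reference parameters at $P \le 0.001$. The panel then takes four
significantly positively and four significantly negatively correlated
parameters, each sign group drawing from distinct feature parents (Co, VA,
NID, ISZ, global, conventional). Within a parent the largest $|\rho|$
wins, with lexicographic tie-breaking — the selection is deterministic
given the correlation table. If either sign cannot field four parents the
selection fails with an explicit shortfall message rather than returning a
smaller panel.

## Survival modelling

PFS runs from treatment start to the earlier of progression or all-cause
death, censored at last follow-up, with months defined as 30.44 days.

**Optimal cutoff.** Each parameter is dichotomized at the cutpoint that
maximizes the Cox hazard ratio of the risk-group indicator subject to Wald
$P \le 0.05$, scanning every midpoint between adjacent sorted unique values
with both groups at least 5% of the cohort (configurable). For a single
binary split on one covariate this exhaustive scan is equivalent to a
recursive-partitioning step while being transparent and deterministic.
When no candidate is significant the result is an explicit
`no_significant_cutoff` object, never a silent best guess. Two numerical
cautions are documented from simulation: the HR-maximizing rule has
heavy-tailed localization error (under a sharp planted hazard step at
$n = 200$ the median error is within one order statistic, but individual
replicates can land several away), and it is biased toward extreme splits,
which the minimum-group-fraction constraint tempers. The scan is invariant
under strictly monotone transformation of the feature. Small validation
cohorts skip the scan entirely and use fixed tertile (or other quantile)
dichotomization via `quantile_cutoff_sweep`.

**Cox models and concordance.** Fits use maximum partial likelihood with
Breslow tie handling (`survival::coxph`); separation and non-convergence
are turned into explicit errors. Harrell's C is authored here as
event-anchored pair counting — a pair is usable when the shorter observed
time belongs to an event (or, at a tied time, exactly one member is
censored), concordant when that subject carries the higher risk score, with
risk ties counted ½ — and is cross-checked in the tests both against an
exhaustive pair-counting oracle and against `survival::concordance` on
tie-free data. Incremental predictive value compares a base model (disease
status + ECOG performance-status group) with the base model plus a texture
parameter (optionally plus MV category): both models are refitted on paired
bootstrap resamples of subjects, giving percentile intervals for each C and
a two-sided bootstrap P-value for $\Delta C = 0$; degenerate resamples are
skipped and counted. The adjusted hazard-ratio models use
ECOG group, initial disease status and the 45 cm³ MV category.

## The synthetic generators

Because clinical PET volumes cannot ship with a package, every stage is
exercised on two generators whose defaults are the package's reference
conditions.

**Phantoms** (`make_phantom`) place an ellipsoidal lesion (default
semi-axes 30 × 24 × 20 mm, base SUV 8) on a low background (SUV 0.8) in a
48 × 48 × 32 grid at 4.07 × 4.07 × 3 mm spacing, with additive white
scanner noise (sd 0.05 SUV). Heterogeneity is a unit-variance random field
scaled by `mixing_amplitude` (SUV). The field blends a spatially coherent
component — white noise smoothed to an 8 mm correlation length — with an
unsmoothed voxel-scale component whose weight grows with the amplitude as
$a/(a+1)$. The coupling is deliberate: min–max quantization discards affine
rescaling, so a purely additive amplitude would be invisible to the texture
stage, and relative binning amplifies the scanner noise floor in a
near-uniform lesion (a real radiomics artifact — a homogeneous lesion can
score near-maximal entropy on relative bins). Tying amplitude to roughness
makes it a genuine, monotone heterogeneity dial: median co-occurrence
entropy across seeds rises strictly with the amplitude in noise-free
lesions, which is asserted by a property test (run with `noise_sd = 0` to
isolate the texture field from the noise-floor effect). Amplitude 0 still
yields an exactly uniform lesion. The phantom does not model scanner
point-spread, respiratory motion, attenuation artifacts, or multi-lesion
anatomy, so passing tests demonstrate correctness of the measurement
chain, not scanner realism.

**Cohorts** (`make_cohort`) emulate the two-cohort study design the
pipeline targets: an exploratory table of $n = 161$ and a validation table
of $n = 21$ subjects. Features follow a single-factor Gaussian copula: a
latent heterogeneity factor with signed loadings (+0.9 for co-occurrence
entropy, −0.85 homogeneity, +0.8 short-run emphasis, −0.8 VA intensity
variability, −0.75 busyness, +0.75 NID contrast, ±0.7 for the ISZ pair,
weaker positive loadings for SUVmax, SUVaverage and MV), Gaussian margins
on plausible scales, and a lognormal margin for MV (median 30 cm³). This
gives the Spearman screen a known sign structure and makes the
planted-panel test exact. Note the sign convention is the package's own,
consistent with the normalized texture definitions: entropy up = more
heterogeneous, homogeneity down. Event times follow a Weibull
proportional-hazards model (shape 1.2, scale 15 months, baseline median
≈ 11 months — a realistic PFS scale for first-line TKI) with default
log-hazards of 0.5 per latent SD of entropy, 0.6 for poor ECOG group
(prevalence 0.13) and 0.3 for metastatic presentation (prevalence 0.85).
Censoring is independent exponential with its rate calibrated by root
finding so the expected censored fraction equals the target (default 0.2);
the empirical fraction lands within ±3 percentage points at $n \ge 500$.

## Pipeline, determinism and problem sizes

`run_pipeline` orchestrates the stages in two modes — image mode (volumes
plus a survival table) and table mode (a ready per-subject table; imaging
stages skipped) — writing `features.csv`, `corr.csv`, a cutoff/Cox table,
a concordance table, Kaplan–Meier plots, a log, and the verbatim
configuration into the output directory. Runs are deterministic given
configuration and seed; the test suite asserts byte-identical tabular
outputs across repeated runs. Published subject-level cohort exports can
be fed through table mode unchanged; the package does not redistribute any
clinical data, so its own checks run entirely on the generators.

Problem sizes in the shipped tests are chosen for sharp verdicts at small
cost: texture oracles on 100+ random blobs up to 6³; concordance oracles to
$n = 50$; hazard-ratio recovery at $n = 2000$; cutoff localization on
eleven 200-subject replicates; a 36-phantom end-to-end cohort through
NIfTI, segmentation, extraction and cutoff search. The full suite runs in
a few minutes on one CPU.

## Known limitations

* Fixed-SUV isocontour segmentation fails on lesions fainter than the
  threshold and ignores necrotic cores below it; no gradient or adaptive
  method is provided.
* Texture values depend on the quantization convention; other toolchains
  using unnormalized counts or absolute binning will produce different
  absolute numbers (including different sign conventions for entropy), so
  cross-software comparisons should be made on dichotomized or rank scales.
* The optimal-cutoff procedure reuses the data that selected the cutoff
  when estimating its hazard ratio; the reported HRs are therefore
  optimistic, which is why the small-cohort path uses prespecified
  tertiles.
* The bootstrap comparison of concordance indices is a pragmatic choice;
  it does not implement any specific closed-form variance estimator for
  correlated C statistics.
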