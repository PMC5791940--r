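# pethet

Intratumoral metabolic heterogeneity on FDG-PET, measured by texture
analysis and tested as a predictor of progression-free survival (PFS) on
EGFR tyrosine kinase inhibitors.

Tumors with the same size and peak uptake can organize their metabolism
very differently in space, and that spatial disorder is a candidate imaging
marker of the clonal diversity that drives early failure of targeted
therapy. `pethet` is an R implementation of the full measurement-to-
inference chain for this question, aimed at imaging and clinical-statistics
researchers:

1. **SUV conversion and NIfTI I/O** —
   SUV = activity (kBq/mL) / (injected dose / body weight, kBq/g).
2. **Segmentation** — the 26-connected component above a fixed SUV 3.5
   isocontour containing a seed voxel; conventional parameters (SUVmax,
   SUVaverage, metabolic volume with a 45 cm³ category).
3. **Quantization** — min–max relative recoding of the lesion to 64 gray
   levels: ℓ(v) = min(L, 1 + ⌊L·(SUV−vmin)/(vmax−vmin)⌋).
4. **Texture features** — one aggregated matrix per family over the 13
   unique 3D directions: co-occurrence (entropy −Σ p log₂ p, homogeneity
   Σ p/(1+|i−j|)), neighborhood intensity difference (busyness, contrast),
   run length (intensity variability, short-run emphasis) and size zone
   (intensity variability, high-intensity-zone emphasis). All validated
   against exhaustive-enumeration oracles.
5. **Screening** — Spearman correlation of every parameter against
   co-occurrence entropy with Bonferroni-corrected significance (P ≤ 0.001),
   then an eight-parameter panel: four positive and four negative
   correlates from distinct feature parents.
6. **Survival analysis** — hazard-ratio-maximizing cutoff dichotomization
   (exhaustive midpoint scan, Wald P ≤ 0.05, minimum group fraction),
   univariate and adjusted Cox models (Breslow ties), Kaplan–Meier curves,
   quantile/tertile sweeps for small validation cohorts, and incremental
   predictive value via Harrell's C-index with a paired bootstrap.
7. **Synthetic generators** — textured ellipsoidal phantoms with a
   monotone heterogeneity dial, and survival cohorts (exploratory n = 161 /
   validation n = 21 scale) with a Gaussian-copula feature structure and a
   Weibull proportional-hazards outcome with calibrated censoring.

The methods vignette (`vignettes/pet-heterogeneity.Rmd`) documents the
model, conventions, and numerical choices in detail.

## Worked example

```r
library(pethet)

# a textured phantom lesion, segmented and measured
ph   <- make_phantom(phantom_spec(mixing_amplitude = 2, seed = 42))
mask <- segment_tumor(ph$volume, seed = c(24, 24, 16))
mask
#> Tumor mask: 1186 voxels at SUV >= 3.5
fv <- extract_features(ph$volume, mask)
round(fv[c("co_entropy", "co_homogeneity", "nid_busyness",
           "suv_max", "metabolic_volume")], 3)
#>       co_entropy   co_homogeneity     nid_busyness          suv_max
#>           10.531            0.168            0.160           15.654
#> metabolic_volume
#>           58.938

# a synthetic exploratory cohort: cutoff dichotomization and C-index gain
coh <- make_cohort(cohort_spec(seed = 42))
optimal_cutoff(coh, "co_entropy")
#> co_entropy: cutoff 5.4177 (151 above / 10 below), HR 3.19 (1.17-8.73),
#>   P = 0.0237 [risk: above]
compare_c(coh, c("disease_status", "ecog_group"),
          c("disease_status", "ecog_group", "co_entropy"),
          n_boot = 500, seed = 42)
#> Harrell's C: base 0.565 (0.525-0.607) vs extended 0.640 (0.598-0.699)
#>   delta C = 0.075 (0.039-0.130), bootstrap P = 0 (500 resamples)
```

Read: the phantom's lesion (59 cm³, SUVmax 15.7) carries substantial pair
randomness (entropy 10.5 bits of a 12-bit maximum). In the simulated
cohort, subjects above the selected entropy cutoff progress 3.2× faster,
and adding entropy to a clinical base model raises the concordance index
from 0.565 to 0.640 with a bootstrap P below 1/500.

The full pipeline (`run_pipeline`) runs either from volumes + survival
table (image mode) or from a per-subject feature table (table mode) and
writes `features.csv`, `corr.csv`, cutoff/Cox and C-index tables, KM plots,
a log, and the verbatim configuration.

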