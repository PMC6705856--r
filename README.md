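# ivdquant

Quantitative T2-mapping analysis of lumbar intervertebral discs (IVDs), as
used in disc-degeneration and low-back-pain research, packaged as a tested,
fully reproducible pipeline:

1. **Voxel-wise T2 relaxometry** — fit the mono-exponential multi-echo
   spin-echo model `S(t) = S0 · exp(−t / T2)` per voxel (weighted log-linear
   fit, optional nonlinear refinement) and truncate bright noise.
2. **Semi-automated disc segmentation** — seeded region growing on a
   structural series, contour contraction by morphological erosion, and
   geometric transfer of the ROI onto the T2-map grid via pixel-spacing /
   patient-position information.
3. **Five sub-regions** — partition each disc ROI into five equally wide
   bands along its anterior–posterior axis (1 = anterior … 5 = posterior).
4. **Histogram metrics** — per disc: mean T2, SD, and the peak separation
   Δμ = μ₂ − μ₁ of a two-component Gaussian mixture fitted to the pooled
   T2 values by EM. Δμ measures the remaining distinction between nucleus
   pulposus (NP, high T2) and annulus fibrosus (AF, low T2).
5. **Statistics** — Mann–Whitney U (exact by enumeration for small pooled
   n, tie-corrected normal approximation otherwise), Cohen's κ with
   Landis–Koch interpretation, ICC(2,1) with Cicchetti interpretation.
6. **Cohort bookkeeping** — grade × HIZ summary tables, subject-level HIZ
   (high-intensity zone) prevalence, and an end-to-end scripted study.

Because no patient data accompany the analysis this package re-implements,
it ships a first-class **synthetic phantom generator**: multi-echo sagittal
disc cross-sections with a high-T2 NP core, low-T2 AF ring, grade-dependent
T2 decline and NP/AF blending, per-disc biological jitter, small bright HIZ
foci confined to the posterior fifth of the disc, Rician magnitude noise,
and ground-truth masks — so every stage is testable end to end.

## Worked example

```r
library(ivdquant)

# one moderately degenerated (grade 3) disc
sp <- phantom_spec(discs = list(disc_descriptor("L4-L5", center_mm = c(20, 24),
                                                grade = 3)),
                   seed = 2)
ph  <- build_phantom(sp)
map <- truncate_bright_noise(
  fit_t2_map(ph$series, mask = ph$truth$disc_labels > 0), ceiling = 300)

idx <- which(ph$truth$disc_labels == 1, arr.ind = TRUE)
roi <- disc_roi(data.frame(slice = idx[,1], row = idx[,2], col = idx[,3]),
                ph$series$geometry, check_connected = FALSE)
disc_metrics(map, roi)[, 1:4]
#>    mean_t2    sd_t2 delta_mu n_valid
#> 1 57.26252 11.85773 22.10656    1089
```

Mean T2 ≈ 57 ms and Δμ ≈ 22 ms are what a moderately degenerated (grade 3)
disc should show: the NP has lost T2 (its true core value here is 71.8 ms
after biological jitter, against an annulus at ~45 ms) and the two tissue
peaks have moved closer together.

The cohort-table arithmetic on a published reference distribution (25
patients / 124 discs, 12 controls / 59 discs):

```r
tab <- expand_counts(reference_cohort_counts(),
                     n_subjects = list(patient = 25, control = 12),
                     n_subjects_with_hiz = list(patient = 16, control = 4))
s <- summarize_cohort(tab)
s[s$status == "hiz" & s$grade == "1-5", ]
#>     cohort status grade  n  pct
#> 12 patient    hiz   1-5 20 16.1
#> 30 control    hiz   1-5  4  6.8
hiz_prevalence(tab)$prevalence_pct
#> [1] 64.0 33.3
```

A full phantom study (25 patient-like + 12 control-like subjects, ~1 min):

```r
res <- run_study(study_config(), seed = 1, out_dir = "results")
subset(res$comparisons, stratum == "1-5",
       select = c(analysis, metric, p, significant))
```

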