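# mnvmorph

Morphometry of macular neovascularization (MNV) from en-face OCT
angiography, and robust modelling of long-term anti-VEGF treatment
demand.

## What problem this solves, and for whom

In neovascular age-related macular degeneration (nAMD), patients receive
intravitreal anti-VEGF injections (IVIs) for years, with widely varying
injection counts. OCT angiography (OCTA) shows the MNV vascular network
non-invasively at diagnosis, so its geometry is a candidate predictor of
treatment demand. `mnvmorph` is for retinal-imaging researchers who want
a tested, reproducible pipeline that:

1. extracts the four standard MNV vascular parameters from an en-face
   angiogram plus a delineated region of interest — **area** (mm²),
   **total vascular length, sumL** (mm), **box-counting fractal
   dimension, FD**, and **flow density** (%);
2. relates them to the 3-year IVI count and to visual-acuity change with
   outlier-robust weighted regression; and
3. simulates ground-truthed vascular images and statistically calibrated
   68-eye cohorts, so every stage is testable without access to patient
   data.

## The core methods

**Morphometry.** Binarization is Otsu-within-ROI (with despeckling and
small-hole filling); skeletonization is topology-preserving Zhang–Suen
thinning with simple-point cleanup; the skeleton becomes a centerline
graph (endpoints, clustered junctions, pixel-path edges) whose edge
lengths use axial steps of `pixel_scale` and diagonal steps of
`sqrt(2) * pixel_scale`, with corner cutting. FD is the slope of
log N(b) vs log(1/b) over a deterministic power-of-two box ladder. Flow
density is `100 * |mask| / |ROI|`.

**Robust statistics.** For each continuous model variable with sample
percentiles p10, p90, the fences are

    t_low  = p10 - 1.5 (p90 - p10)
    t_high = p90 + 1.5 (p90 - p10)

and an observation at x receives weight

    w(x) = exp( -0.5 * ( max(0, t_low - x, x - t_high) / (0.5 (t_high - t_low)) )^2 )

(1 inside the fences, Gaussian decay outside). A model's observation
weights are the geometric mean of the fence weights of its variables;
fits are weighted least squares (t-based p-values on n − p df) or
weighted logistic IRLS, both oracle-tested against `lm()` / `glm()`.
`analyze_cohort()` fits the full grid: 4 parameters × {IVI count,
visual-acuity change (baseline-adjusted)} plus MNV type (two indicators,
joint F-test) × both outcomes.

**Simulation.** Cohorts: log-normal area/sumL with a log-scale copula,
truncated-normal FD and flow density (moment-exact after truncation),
negative-binomial injection counts whose intercept and dispersion are
solved in closed form so the marginal mean/SD are exact, and visual
acuity independent of the vasculature. Images: stochastic branching
trees with exact length bookkeeping, rasterized at 0.012 mm/px and
degraded by gamma speckle plus a smooth background field.

## Worked example

```r
library(mnvmorph)

cohort <- generate_cohort(default_cohort_params(), seed = 1)
round(colMeans(cohort[, c("area_mm2", "suml_mm", "fd",
                          "flow_density_pct", "ivi_count_3y")]), 3)
#>         area_mm2          suml_mm               fd flow_density_pct
#>            1.135           12.247            1.249           41.653
#>     ivi_count_3y
#>           20.603

report <- analyze_cohort(cohort)
print(report)
#> MNV cohort analysis (68 eyes, alpha = 0.05, weights = fence)
#>                    model             term estimate  p_value significant
#>          area_mm2_vs_ivi         area_mm2   4.9420 1.97e-08        TRUE
#>           suml_mm_vs_ivi          suml_mm   0.5458 1.28e-07        TRUE
#>                fd_vs_ivi               fd  25.6600 3.60e-06        TRUE
#>  flow_density_pct_vs_ivi flow_density_pct  -0.1203 4.92e-01       FALSE
#>  ...
#> joint tests:
#>   mnv_type_vs_ivi: p = 0.3002
#>   mnv_type_vs_va: p = 0.0507
```

The one-seed cohort means sit near their calibration targets (area
1.106 mm², sumL 12.95 mm, FD 1.263, flow density 41.19%, IVI 19.8), and
the analysis recovers the designed association pattern: area, sumL and FD
predict the 3-year injection count; flow density, MNV type and all
visual-acuity models are null.

The image side of the pipeline:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "run1",
                               n_eyes = 12, n_images = 3, paired = TRUE))
res$metrics          # per-eye measured area / sumL / FD / flow density
```

A thin command-line front end wraps the same stages:

```sh
Rscript inst/scripts/mnv-pipeline.R run-all --seed 5 --out run5
Rscript inst/scripts/mnv-pipeline.R analyze --cohort cohort.csv --out out
```

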