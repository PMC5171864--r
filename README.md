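# finregen

Standardized quantification of caudal-fin regeneration and de-novo bone
mineralization in adult zebrafish, from paired bright-field and alizarin
red S (AR-S) fluorescence micrographs.

Zebrafish regrow an amputated caudal fin in under two weeks, and the
regenerating bony rays re-mineralize as the tissue extends — which makes
the fin a workhorse assay for screening pro- and anti-regenerative or
mineralogenic compounds. The raw readouts, however, confound treatment
effects with fish size and with each other. `finregen` implements a
size-corrected, two-axis analysis for people running such screens:

* **Histomorphometry** — REG (regenerated area), RMA (real mineralized
  area, by RGB colour threshold within REG), EMA (tip polygon), RAY (mean
  ray width at the first intersegment joint below the amputation plane),
  STU (stump width), from an image pair plus a two-point amputation-plane
  annotation and a mm-per-pixel calibration.
* **Correction factors** — REG/STU for overall regeneration and RMA/RAY
  for mineral deposition, with (RMA/RAY)/(REG/STU) as the mineralized
  fraction of the regenerate. The correctors come from the same image, so
  no extra weighing or length measurement is needed.
* **Phase model** — RMA/RAY versus REG/STU is flat (P1, pre-mineralization)
  then linear (P2, co-growth): a continuous segmental (broken-stick)
  regression estimates the breakpoint x0, and an OLS *standard curve* on
  control data inside the 84–240 hours-post-amputation window supports
  treatment classification: displacement **along** the curve = regenerative
  effect, displacement **off** the curve = mineralogenic effect (unpaired
  t tests at α = 0.05).
* **Staining-intensity analysis** — the luma (YUV Y) histogram of the
  mineralized pixels over the 15–254 spectrum, summarized into low (15–29)
  and high (30–44) intensity classes, as a proxy for mineral density or
  hemiray thickness; it catches transverse-plane effects that area metrics
  miss.
* **Statistics** — Pearson, one-way ANOVA, Tukey HSD, pooled/Welch t
  tests, Grubbs' outlier test, all returning tidy tibbles.
* **Synthetic fins** — a generator that renders image pairs (rays, joints,
  bifurcations, controllable mineral signal and noise) and simulates
  longitudinal cohorts with exact ground truth, so the entire chain is
  testable without animal data.

## Worked example

Everything below runs without any input data, using the synthetic
generator.

```r
library(finregen)
library(dplyr)

# one rendered specimen, measured end to end
rf  <- render_fin(synthetic_fin_spec(seed = 42), specimen_id = "fish01", time_hpa = 120)
res <- analyze_fin(rf$record)
res$measurements |> select(specimen_id, reg_mm2, rma_mm2, ema_mm2, ray_mm, stu_mm)
#>   specimen_id reg_mm2  rma_mm2   ema_mm2    ray_mm stu_mm
#> 1      fish01   1.476 0.444875 0.9980375 0.0634375  1.995
```

1.476 mm² of regenerate above a 1.995 mm stump; 0.445 mm² of it is
AR-S-positive mineral (EMA, which adds the inter-ray spaces, overestimates
it at 0.998 mm²); the rays are 63 µm wide at the first joint below the cut.

```r
# a 60-fish control time course (24-240 hpa), and the phase model
coh <- simulate_cohort(cohort_spec(seed = 1))
fit <- fit_segmental(coh)
fit
#> <segmental_fit> x0 = 0.5735, P1 slope b = -2.107e-10, P2 slope c = 1.148
#>   n = 60 (P1: 22, P2: 38), SSE = 0.08999 (single line: 0.8065)

curve <- build_standard_curve(coh)   # P2 standard curve, 84-240 hpa window
curve
#> <standard_curve> y = -0.6482 + 1.139 x, r = 0.9837, n = 40, window 84-240 hpa
```

Mineralization is absent until REG/STU reaches the breakpoint (x0 ≈ 0.57
here, generator truth 0.586) and then tracks regeneration linearly — the
regime in which screening is meaningful.

```r
# classify a retinoic-acid-like treatment (stunted growth, enriched mineral)
ra  <- simulate_cohort(cohort_spec(n_fish = 10, time_points_hpa = 120, seed = 2,
                                   treatment_effects = ra_like_effects,
                                   group_label = "RA"))
ctl <- simulate_cohort(cohort_spec(n_fish = 10, time_points_hpa = 120, seed = 3))
classify_effect(ra, ctl, curve)
#> <effect_call> regeneration: under (dx = -0.346, p = 3.09e-14)
#>               mineralization: over (dy = 0.308, p = 7.73e-12)
```

The treated group sits 0.35 mm lower in REG/STU (under-regenerated) and
0.31 mm above the control standard curve (over-mineralized) — the
canonical retinoic-acid phenotype. `autoplot()` methods exist for every
fitted object (`segmental_fit`, `standard_curve`, `effect_call`,
`intensity_histogram`, `poly2_fit`), and `tidy()`/`glance()` return
tibbles.

For batch work, `run_pipeline("manifest.csv", out_dir = "out")` measures
every record in a manifest (image paths, plane endpoints, calibration,
group, time), builds the control standard curve, classifies every treated
group and compares intensity classes; `inst/cli/finregen.R` wraps the same
functions as `measure` / `model` / `classify` / `simulate` / `report`
subcommands.

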