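# evprofiler

Single-particle profiling of extracellular vesicles (EVs) and
non-vesicular extracellular particles (NVEPs) from single-molecule
localization microscopy (SMLM/dSTORM).

Affinity-captured particles imaged by dSTORM appear as clusters of
blinking-fluorophore localizations. `evprofiler` turns a per-ROI
localization table (x, y, frame, intensity, channel; nm coordinates)
into per-particle biophysical measurements and condition-level
statistics:

1. **Voronoi-tessellation clustering.** Each localization's local
   density is the reciprocal area of its Voronoi cell (cells clipped to
   the ROI rectangle, so the tessellation is exact). Localizations at
   density ≥ *f*·(n/A) — *f* = 2 by default, n/A the mean ROI density —
   are signal; connected components of the cell-adjacency graph carrying
   enough signal become candidate particles.
2. **Admission filters.** Small clusters (20–100 nm equivalent-circle
   diameter) are admitted with 2α–2,000 localizations; large clusters
   (>100 nm) with 100–15,000; an optional 250 nm size cap applies to
   SNA-capture/SNA-detection data; mouse-sample mode uses 30–100 nm and
   2.5α. α is the calibrated mean number of localizations per
   fluorescent probe (shipped registry: SNA-AF647 α=6, antibody-AF647
   α=10, antibody-CF568 α=11, ApoE-antibody-AF647 α=11).
3. **Cargo and morphology.** Cargo molecules per particle =
   round(n_loc/α); diameter d = 2·√(A_hull/π); circularity
   4π·A/P² (1 = perfect circle); eccentricity √(1 − λ₂/λ₁) from the
   localization covariance (0 = circle).
4. **Reporter colocalization.** A second-channel reconstruction (e.g.
   eSRRF of an mNeonGreen reporter) is max-normalized, thresholded at an
   absolute 0.3 (tissue) or 0.4 (plasma), coarsely aligned by
   integer-pixel translation, and particles are called
   reporter-positive by centroid-pixel membership.
5. **Cohort statistics.** Per-ROI summaries (particles/μl =
   count × dilution / reference volume), mean ± SEM over ROIs per
   condition, and two-group / ANOVA / Tukey / Mann-Whitney comparisons
   with the usual star convention.

A fully seeded synthetic generator (`sample_particles()`,
`emit_localizations()`, `render_reporter_image()`,
`make_buffer_control()`) simulates 41 × 41 μm ROIs of blinking
fluorophores from four particle classes (EV, exomere, supermere,
lipoprotein particle) plus background, so the entire pipeline is
testable against known ground truth without any external data.

## Worked example

```r
library(evprofiler)

cfg   <- load_config()                      # assay defaults, alpha = 10
roi   <- cfg$roi_geometry                   # 41 x 41 um, 256 px, 25k frames
truth <- sample_particles(c(EV = 100), roi, seed = 11)
locs  <- emit_localizations(truth, cfg$fluor, noise_model(), roi, seed = 12)
rec   <- detect_particles(locs, cfg)
nrow(rec)
#> [1] 90
recovery_report(rec, truth)
#> recovery: 90/94 detected matched (precision 1.000, recall 0.957)
#>   class_name n_matched diameter_bias diameter_rmse cargo_bias cargo_rmse
#> 1         EV        90      14.19071      20.92251  0.5111111   4.444722
round(c(diameter = mean(rec$diameter_nm),
        circularity = mean(rec$circularity)), 2)
#>    diameter circularity
#>      102.49        0.87
summarize_roi(rec, dilution_factor = 10000)$particles_per_ul
#> [1] 900000
```

The 94 simulated EVs (Poisson draw at rate 100) yield 90 admitted
particles; every detection matches a true particle within 100 nm
(precision 1.0), 96 % of true particles are found, the estimated cargo
is unbiased to ~0.5 molecules, and the mean hull diameter carries the
expected small positive bias from localization error (~10 nm at
σ_loc = 10 nm). At a 10,000-fold dilution the 90 detections correspond
to 9 × 10⁵ particles per μl of stock.

A command-line interface covers the same stages:

```sh
Rscript -e 'evprofiler::run_cli()' simulate --config cfg.json --seed 9 --out-dir out
Rscript -e 'evprofiler::run_cli()' profile  out/localizations.csv --out-dir out
```

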