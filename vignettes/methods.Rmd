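---
title: "Methods: single-particle EV/NVEP profiling from SMLM localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle EV/NVEP profiling from SMLM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Affinity-captured extracellular vesicles (EVs) and non-vesicular
extracellular particles (NVEPs — exomeres and supermeres) are imaged by
dSTORM: each fluorescent probe blinks stochastically and every blink is
localized to a few-nanometre precision, so one particle appears as a
compact cloud of localizations. Three facts drive the analysis design:

* a probe emits a *random number* of localizations whose calibrated
  mean α converts localization counts into molecule counts;
* localization density inside a particle is orders of magnitude above
  the field average, so density, not distance, separates particles from
  background;
* particle size (25–150 nm) is near the localization precision
  (~10 nm), so morphology estimates are blurred and must be read as
  convolved quantities.

## Voronoi density clustering

For localizations $p_1,\dots,p_n$ in a rectangular ROI, every Voronoi
cell is clipped to the ROI rectangle, making all cells bounded and the
cell areas an exact partition of the ROI area (the package's compiled
implementation keeps the relative conservation error below $10^{-6}$;
the acceptance suite checks $20$ seeded point sets). The first-rank
density of a localization is $1/\text{area}$ of its cell. Coincident
localizations share their common cell's area equally. Fewer than 4
points, or an exactly collinear point set, cannot support a meaningful
tessellation: the field is flagged degenerate and treated as noise.

Signal is called by a single threshold
$\rho \ge f \cdot n/A$, with $f$ the `threshold_factor` (default 2, the
usual convention for tessellation-based SMLM clustering; the source
protocol does not restate its factor, so it is configuration, logged in
the run provenance). With `smooth = TRUE` (the pipeline default) the
thresholded quantity is the mean first-rank density over the cell and
its Voronoi neighbours, which stabilises the call at cluster rims.

**Cluster membership (design decision).** Clusters are connected
components of the Voronoi adjacency graph (cells sharing an edge),
restricted to edges whose generators are closer than `max_edge_nm`, and
a component is a cluster when it contains at least `min_members = 2`
supra-threshold localizations — *all* component members then belong to
the cluster. Two departures from the textbook "supra-threshold cells
sharing edges" rule are deliberate:

* *Distance-restricted adjacency.* In a sparse field, rim cells of two
  distinct particles can share a Voronoi edge across micrometres of
  empty space; pure shared-edge connectivity would merge them. The
  default cut-off is derived from the threshold itself,
  $\sqrt{1/\rho_{thr}}$ — the inter-point spacing of a region at
  exactly threshold density — so it introduces no new free parameter.
  `max_edge_nm = Inf` restores pure shared-edge adjacency.
* *Border membership.* The outermost cells of a dense particle bulge
  into the surrounding empty space and can fall below any density
  threshold (their Voronoi neighbours are often all rim cells, so no
  one-hop smoothing rescues them). Excluding them would shave particle
  rims and bias diameter and cargo low. Components are therefore formed
  over all localizations and qualified by their signal content — the
  DBSCAN border-point semantics. On ROIs whose particles are well
  separated with zero background, the resulting memberships are
  *exactly* those of a brute-force distance-threshold
  connected-components oracle, which the acceptance suite asserts on 20
  seeded ROIs.

An optional pre-step merges re-blinks of one fluorophore
(localizations within `merge_radius_nm` and a frame gap up to the
probe's maximum dark time, merged transitively to their centroid). It
is off by default: the admission rules below are expressed in units of
α, which already absorbs re-blinking on average, and the synthetic
emitter assigns frames uniformly, which carries no dark-time structure.

## Admission filters

Candidate clusters are classified by equivalent-circle diameter
$d = 2\sqrt{A_{hull}/\pi}$ and admitted by the assay's calibrated
rules, all bounds inclusive:

| class | diameter | localizations |
|---|---|---|
| small | 20–100 nm | 2α … 2,000 |
| large | > 100 nm | 100 … 15,000 |

A diameter of exactly 100 nm is small. Clusters below 20 nm are
rejected as fragments. For SNA-capture/SNA-detection data an additional
250 nm size cap rejects large aggregation artifacts. Mouse-sample mode
narrows the small class to 30–100 nm with a 2.5α minimum. Every
rejection is logged with a reason code, and filtering is idempotent.

## Cargo and morphology

* **Cargo**: $\mathrm{round}(n_{loc}/\alpha)$, round-half-up, floored
  at 1 — a detected particle implies at least one probe.
* **Diameter**: equivalent-circle from the convex-hull area; the
  maximum Feret diameter is also emitted but the gate uses the
  area-based value, which is robust to single stray localizations.
* **Circularity**: $4\pi A/P^2$ of the hull polygon (perimeter from the
  hull, not an alpha shape: deterministic and parameter-free).
* **Eccentricity**: $\sqrt{1-\lambda_2/\lambda_1}$ from the unweighted
  localization covariance.

Degenerate clusters (<3 points or a zero-area hull) get the maximum
pairwise distance as diameter and undefined shape metrics; they are
flagged, never silently dropped.

Two estimator properties matter when reading results. The hull of a
blurred point cloud overestimates the geometric diameter by roughly
$2$–$3\sigma_{loc}$ (about +10 % for a 100 nm particle at
$\sigma_{loc}=10$ nm). And sample eccentricity is biased upward when
the number of *molecules* (not localizations) is small, because blinks
of one molecule are spatially redundant; EV/NVEP eccentricity contrasts
at realistic cargo counts are therefore compressed, which is visible in
the ordering acceptance test (the eccentricity ordering is the weakest
of the three).

## Reporter colocalization

The second channel arrives as an already-reconstructed intensity image.
It is max-normalized and binarized at a single absolute threshold —
0.3 for tissue-derived samples, 0.4 for plasma (the assay's optimized
values; a no-normalization mode exists for pre-scaled images). Coarse
two-channel registration is an exhaustive integer-pixel translation
search maximizing the number of particle centroids on true mask pixels,
ties broken toward the smallest shift; affine or subpixel registration
is out of scope. A particle is reporter-positive when its shifted
centroid pixel is true (an overlap-fraction mode — ≥ 25 % of hull
pixels — is available but never mixed silently). Centroid-hit scoring
plateaus when mask blobs are much wider than a pixel, so exact-shift
tests use a reference rendered with a PSF below one pixel.

## Concentration and condition statistics

`particles_per_ul = count × dilution_factor / reference_volume_ul`.
The upstream protocol states the output unit ("per 1 μl") but not the
formula; whether the reference volume refers to diluted sample applied
or undiluted stock differs by a constant factor, so both are explicit
configuration and the choice is logged. Buffer-control counts are
reported alongside, not subtracted, by default.

The statistical unit is the ROI (the standard design images 5 ROIs per
fraction, n fractions per condition); condition summaries are
mean ± SEM over ROI values. Fraction nesting is recorded and a caveat
emitted when several fractions are pooled, but mixed models are out of
scope, matching the source design. Two-group comparisons use the
two-tailed Student's t-test (equal variances); one-way ANOVA with
optional Tukey HSD and Mann-Whitney are available; no multiple-testing
correction is applied across metrics. Degenerate zero-variance,
equal-mean comparisons return p = 1 by convention. Stars follow
\*p<0.05, \*\*p<0.01, \*\*\*p<0.001, \*\*\*\*p<0.0001.

## The synthetic generator: what it emulates, what it does not

`sample_particles()` draws Poisson particle counts per class, uniform
centroids (with an edge margin so particles are not clipped), sizes and
axial ratios from per-class distributions, and scatters cargo molecules
uniformly inside each particle's ellipse, thinned by a labelling
efficiency. `emit_localizations()` gives every labelled molecule a
geometric number of localizations with mean α (the calibration states
only the mean; a zero-truncated Poisson alternative is provided — both
have support ≥ 1), adds isotropic Gaussian localization error, assigns
frames uniformly, adds a uniform Poisson background, and discards (not
clamps) localizations falling outside the ROI, logging the count.
`render_reporter_image()` renders reporter-positive particles as unit
Gaussian spots on the pixel grid, max-normalized, with optional sparse
false spots for control simulations. Everything is bitwise reproducible
given (configuration, seed).

Default class parameters are synthetic stand-ins chosen once to
reproduce the qualitative EV/NVEP contrast, not measured truth:
EV diameters lognormal (median 90 nm, sdlog 0.25), exomere 35 nm,
supermere 25 nm, LPP 49 nm (sdlog 0.12–0.15); axial ratio ~1.1 for
EV/LPP and ~1.8 for NVEPs; cargo 10–40 molecules for EVs and 4–12 for
NVEPs and LPPs (LPPs are not given their own cargo scale by the
protocol, so they share the NVEP range); labelling efficiency 0.9
(typical immunolabelling); background 0.5 localizations/μm² per
acquisition (sparse enough that buffer controls carry minimal signal,
as observed in the assay); localization precision σ = 10 nm (typical
dSTORM; the setup's value is not stated, so it is configuration).

The generator does **not** simulate raw fluctuation movies, eSRRF
reconstruction, camera noise, drift, temporally correlated blinking, or
chromatic aberration. A green test therefore establishes that the
*analysis* recovers what the *stated generative model* produced — it
does not validate the microscope model itself.

## Numerical choices

* Voronoi cells are computed by incremental half-plane clipping with a
  grid-accelerated candidate search and an exact early-stop criterion
  (a generator at distance $d$ cannot cut a cell whose farthest vertex
  is nearer than $d/2$); the implementation is validated in-suite
  against a brute-force R oracle.
* Ties at the density threshold are signal (≥, not >).
* Cluster labels are contiguous from 0, ordered by smallest member
  index; noise is −1. Row order of the input never changes memberships.
* Coordinates are nm, origin top-left, y downward; pixels 0-based,
  pixel (i, j) covering the half-open nm square
  $[j p, (j{+}1)p) \times [i p, (i{+}1)p)$.
* TIFF support (needed because the R stack here has no TIFF package) is
  a minimal baseline implementation: uncompressed single-strip
  grayscale, float32 write, float32/uint8/uint16 read.

## Known limitations

* Diameters are hull-based and blurred upward by localization error; no
  deconvolution is attempted.
* Eccentricity is small-sample biased at low molecule counts (see
  above).
* Alignment is integer-pixel translation only.
* Particles closer than the adjacency cut-off can merge into one
  cluster; at the default densities this affects of order 1 % of
  particles.
* The per-μl normalization inherits the stated reference-volume
  ambiguity; cross-study comparisons must fix the same convention.
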