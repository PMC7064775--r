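---
title: "Models and methods behind smtquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smtquant quantifies the behaviour of fluorescently tagged proteins in
rod-shaped bacteria from single-molecule tracking movies: how much of the
population is receptor-bound versus freely diffusing, how long binding
events last, where molecules sit within the cell, and how many molecules a
cell contains. This vignette explains the underlying models, the tunable
parameters, the synthetic-data generator used for validation, and the
choices made where the methodology was genuinely open.

## Two-state mobility decomposition

A membrane-bound or cytosolic enzyme that intermittently binds a fixed
receptor complex shows two mobility regimes. For Brownian motion with
diffusion coefficient $D$, the displacement per frame interval $\tau$ is
Gaussian per axis with variance $2D\tau$, and the jump distance
$r=\sqrt{dx^2+dy^2}$ follows the radial law

$$p(r \mid D) = \frac{r}{2D\tau}\, e^{-r^2/(4D\tau)}.$$

A population with $K$ mobility states therefore produces the mixture
$p(r)=\sum_k w_k\, p(r \mid D_k)$. `fit_mixture()` maximises the exact
likelihood of this mixture on the raw, unbinned jump distances with an
EM algorithm:

* **E step:** responsibilities $\gamma_{ik}\propto w_k\,p(r_i\mid D_k)$.
* **M step:** $w_k=\overline{\gamma_{\cdot k}}$ and
  $\hat D_k=\sum_i\gamma_{ik} r_i^2 \big/ (4\tau\sum_i\gamma_{ik})$, the
  responsibility-weighted moment estimator.

Initialisation uses a deterministic set of starts (a quantile split of
$r^2$ plus fixed spread patterns), so the fit is reproducible without a
random-number state. Components are always reported sorted by increasing
$D$; component 1 is the static (bound) subpopulation. Model order
($K\in\{1,2,3\}$) is selected by BIC via `select_mixture()`; for genuinely
two-state data the two-component fit wins by a large margin, matching the
visual inadequacy of a single fit to step-size histograms.

When two strains or treatments are compared, `fit_joint()` runs a single
EM over both datasets with the $D_k$ shared and the weights free per
condition. This is why comparison tables list identical diffusion
coefficients for paired strains and differ only in the fraction sizes,
and it makes the static-percentage difference between conditions (e.g.
"52% of molecules lose their binding partner in the mutant") directly
interpretable. `compare_conditions()` computes that difference and
formats it at table precision (one decimal) and prose precision (nearest
integer percent).

Two refinements are available but off by default, since the classic
analysis omits them: a per-axis localization-error floor (`eps`), which
changes the component scale to $2D_k\tau+2\varepsilon^2$, and an
axis-wise Gaussian mixture fit on pooled $dx,dy$
(`fit_mixture_axis()`) as an independent cross-check of the same model.
Measured coefficients of membrane proteins can be multiplied by 1.23
(`curvature_correct()`) to undo the flattening caused by projecting
diffusion on the curved membrane; reported tables conventionally print
the raw values.

Uncertainties: fraction SDs are computed across replicate datasets
(three by default in `run_pipeline()`), mirroring a three-biological-
replicate design; `n_boot` adds bootstrap standard errors within one
dataset.

## Apparent diffusion and the slow-track filter

`per_track_msd()` fits the time-averaged MSD of one track over its first
lags (default 4) with $\mathrm{MSD}(t)=4D_\mathrm{app}t+b$; the offset
absorbs static localization error. Spatial maps of the bound
subpopulation use the filter $D_\mathrm{app}<0.5\,\mu m^2/s$ and
$R^2>0.7$; the $R^2$ condition removes tracks whose MSD is too noisy or
non-linear to classify. A perfectly immobile, noise-free track has a
degenerate (zero-variance) MSD; it is reported as $D_\mathrm{app}=0$
with `r2 = NA` and treated as non-classifiable by filters.

## Dwell times

A dwell event is a maximal run of consecutive localizations within
230 nm (2.3 pixels) of the run's anchor, with at least two
localizations; its duration is $(n-1)\tau$. The exact windowing of the
original external tool is unpublished, so the anchor is defined
deterministically as the first point of the run; a rolling-centroid
variant (`rule = "centroid"`) is provided for sensitivity analysis. The
two rules agree closely on tethered molecules and neither should be
assumed equivalent to the original tool's exact values.

Two systematic effects matter when interpreting the statistic:

* **Bleaching truncation.** Tracks end when the fluorophore bleaches, so
  long binding events are cut short and the detected mean dwell
  *underestimates* the true binding lifetime; simulations show the
  detected mean falling monotonically as the bleaching rate rises.
* **Chance confinement and rebinding.** Mobile molecules bouncing inside
  a 1-µm-wide cell occasionally stay within 230 nm of a point for a few
  frames, and molecules that unbind and rebind within a frame or two
  never leave the radius; both effects add events that are not single
  binding episodes. The statistic is therefore most meaningful as a
  *relative* measure across conditions — which is how it is used — and
  `dwell_events(filter = ...)` can restrict the analysis to slow
  (static-like) tracks, mirroring the convention of quoting dwell times
  of static molecules.

## Standardized-cell heat maps

Each localization is projected through its cell mesh into a reference
cell of 3 × 1 µm: the position along the pole-to-pole axis (pole 1 at
zero — pole order is taken from the mesh as given, without mirroring)
scaled by the standard length, and the position across the local
transverse chord of the polygon scaled by the standard width. The chord
construction makes uniform occupancy in any convex-ish cell map to
uniform density in the standard cell. Maps are binned at 50 nm
(60 × 20 bins, matching the pixel scale) and normalized to sum to one;
`equalize_heatmaps()` rescales count maps to a common total when several
conditions are displayed side by side.

## Copy-number quantification

The counting protocol divides each cell's corrected initial intensity by
the intensity drop of a single bleaching fluorophore.

**Corrections.** Every frame is corrected as
`intensity = (observed - offset) / ratio`. The offset is the per-pixel
median of the first 20 dark frames recorded before the laser switches
on. The illumination ratio comes from cell-free movies: the mean
offset-corrected post-laser intensity per pixel, normalized by its
maximum (values in (0, 1], maximum exactly 1). Because illumination
varies on scales of tens of microns while pixel noise does not, the mean
blank image is lightly smoothed (Gaussian, 2 px) before normalization;
this suppresses both pixel noise and the upward bias of a maximum taken
over noisy pixels, without distorting the profile. Pixels whose ratio
falls below 0.05 are floored and flagged so that field-edge divisions
cannot blow up.

**Autofluorescence.** Unlabelled cells fluoresce. On label-free
(wild-type) movies — typically around ten — the integrated cell signal
right after laser-on is regressed on the local background level as
$AF = a\,BG^2+b\,BG+c$. The background covariate is defined here as the
median corrected intensity in a cell-free shell 3–7 px outside the mesh;
the original tool does not define its regressor, so this definition is a
documented package choice, not an external convention. For sample movies
the model predicts, per cell, the autofluorescence contribution at the
moment the laser switches on, which is subtracted from the cell signal.

**Cell and spot integration.** Cell signal is integrated over the mesh
dilated by 2 px (so PSF tails of molecules at the cell edge are not
lost), minus the shell background times the number of added ring pixels.
Spot intensities use a circle of radius 6 px around the localization;
the background under the circle is the median of in-cell pixels outside
the circle for the in-cell part, and the shell median for the part of
the circle that pokes outside the cell — the circle is wider than half
the cell, so a one-region background would mix medium and cell levels.
Intensity-versus-time traces are median-filtered with window 3, the
smallest odd window that removes single-frame outliers while preserving
a clean bleaching step.

**Unitary step and stoichiometry.** For every track that disappears
before the movie ends, the terminal step is the mean of the last two
filtered trace values; tracks running to the movie end never bleached on
camera and are excluded. Steps are flagged *isolated* when no other
track is within 0.7 µm during those final frames — overlapping emitters
inflate the apparent step, so only isolated steps enter the histogram.
A 1–3 component equal-variance Gaussian peak fit (BIC-selected) to the
step histogram gives the unitary step as the mean of the lowest peak;
equal variances stabilise the two-peak fit at realistic sample sizes.
`classify_bleach_steps()` splits the same histogram into two classes and
reports monomer/dimer fractions, flagging the fit if the second mean is
not roughly twice the first. Finally
$N = I_0/I_\mathrm{unit}$ per cell, with negative $I_0$ clipped to zero
and flagged; cells without detected signal are excluded from population
means but counted in the empty-cell fraction.

## The synthetic-data generator

No raw movies were published for this kind of analysis, so validation
rests on `simulate_experiment()`, which generates movies, meshes and
tracks with known ground truth. Its defaults are the study conditions
the analyses assume:

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 0.015 s | frame interval (~65 Hz) |
| `pixel_size` | 0.100 µm | camera pixel |
| `cell_length`, `cell_width` | 3, 1 µm | spherocylinder projection |
| `D_static`, `D_mobile` | 0.079, 0.657 µm²/s | two-state coefficients |
| `f_static` | 0.697 | stationary bound fraction |
| `mean_bound_dwell` | 0.049 s | mean bound-episode duration |
| `molecules_per_cell_mean` | 5.58 | fluorophores per occupied cell |
| `p_empty` | 0.29 | cells with no labelled molecule |
| `dimer_fraction` | 0.25 | dimer share among bleaching units |
| `unitary_photons` | 5047 | single-fluorophore step |
| `dimer_intensity_ratio` | 8975/5047 | dimer step relative to monomer |
| `laser_on_frame` | 21 | 20 dark frames for the offset |

State kinetics are a stationary two-state Markov chain: the per-frame
unbinding probability is $1-e^{-\tau/\text{dwell}}$ and the binding
probability is chosen for stationarity at `f_static`. Bound episodes
diffuse with `D_static` tethered within `anchor_radius` (default 100 nm
— a receptor-complex-scale confinement, deliberately inside the 230-nm
dwell criterion) around an anchor placed in a polar cap with probability
`polar_bias`; mobile episodes diffuse with `D_mobile`, reflected at the
projected spherocylinder boundary. A `membrane` mode diffuses on the
unrolled cylinder surface and projects the circumferential coordinate,
emulating focal-plane imaging of membrane proteins; the default
`interior` mode is used for parameter-recovery tests because its
measured step statistics equal the nominal coefficients exactly.

Counts per cell are Poisson with zero inflation (`p_empty`); counts are
*fluorophores*, and a fraction of emitting units are dimers — two
fluorophores moving and bleaching as one unit with
`dimer_intensity_ratio` times the monomer intensity (slightly below 2,
as observed for fluorescent-protein pairs bleaching together). Rendering
sums pixel-integrated Gaussian PSFs scaled by a Gaussian illumination
(vignette) profile, adds diffuse medium background outside cells (cells
displace the medium), per-cell autofluorescence following the quadratic
model in the movie's background level, camera offset, optional Poisson
shot noise and Gaussian read noise. Bleaching is a single step to zero;
blinking is not modelled because the counting protocol assumes clean
steps. EM-CCD excess noise is likewise simplified to shot + read noise —
enough to validate the algorithms, not a camera model.

What passing tests on this generator do *not* show: robustness to
blinking and excess camera noise, to segmentation errors in real meshes,
to aberrated PSFs, or to autofluorescence that deviates from the
quadratic model. Those remain caveats for real data.

Determinism: all generator randomness derives from `config$seed` through
one R RNG stream seeded once per experiment, so a given configuration
reproduces its movie, meshes and tracks bit-identically.

One geometric subtlety: meshes are polygons with chord-inscribed caps,
so positions are simulated a hair (12 nm) inside the true spherocylinder
to guarantee every ground-truth localization also lies inside its
polygon — keeping "100% of noiseless localizations assigned to their
cell" an exact invariant.

## Detection and linking

Spot detection is difference-of-Gaussians band-pass filtering, 8-neighbour
local maxima above 5 noise SDs, and least-squares refinement of a
fixed-width pixel-integrated 2-D Gaussian (sub-pixel centre, integrated
photons, local background). Emitters closer than the PSF width are
shape-degenerate with one brighter emitter; candidate merges are flagged
by an intensity-weighted width criterion and, when a calibrated
single-emitter intensity is supplied, by brightness. Linking minimises
total squared frame-to-frame displacement under a hard gate
(`max_disp`, default 0.5 µm ≈ 3σ of the fastest expected step at 15 ms)
using an in-package Hungarian solver — deterministic resolution of
conflicting nearest-neighbour claims. No gap closing: a missed frame
splits the track, and fragments shorter than 4 localizations are
discarded, matching the tracking settings used throughout.

## Problem sizes used in validation

The test-suite and the acceptance script size their simulations to be
statistically decisive while staying quick on one CPU: mixture recovery
uses 2×10⁴ jumps (weight SE ≈ 0.4 points), copy-number validation uses
30-cell fields — several 320-frame movies for bleaching steps (~300
isolated steps), one movie with per-cell counts 1–30 for recovery, two
270-frame blank movies and ten short label-free movies for the
corrections; dwell and heat-map properties use 40-cell track-level
simulations. These sizes are the package's validation choices; larger
runs only tighten the same estimates.

## Known limitations

* The dwell statistic conflates binding episodes separated by sub-frame
  unbinding; absolute dwell values depend on the (unpublished) windowing
  of the original tool.
* Counting assumes dimers bleach in one simultaneous step; stepwise
  dimer bleaching would be classified as two monomer events.
* The autofluorescence regressor is a package definition (cell-free
  shell median); other definitions shift coefficients but, in
  simulations, not the predicted contribution.
* Counts are in corrected camera units ("photons" by convention), not
  absolute photons; no EM-gain calibration is attempted.
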