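# smtquant

Single-molecule tracking quantification for rod-shaped bacteria.

Low-copy signalling enzymes such as diguanylate cyclases spend part of
their time bound to receptor complexes and part diffusing freely. Given
single-particle tracks from live-cell movies, `smtquant` answers four
questions about such a protein:

1. **How much of the population is bound?** Frame-to-frame jump
   distances are decomposed into static and mobile subpopulations by
   maximum-likelihood fitting of the jump-distance mixture
   `p(r) = Σ_k w_k · r/(2 D_k τ) · exp(−r² / (4 D_k τ))`
   (EM on raw jumps, BIC model selection, components sorted so that
   component 1 is the static state). Compared conditions are fitted
   jointly with shared diffusion coefficients and condition-specific
   weights, so fraction differences between strains are directly
   interpretable (`fit_mixture()`, `fit_joint()`,
   `compare_conditions()`).
2. **How long do binding events last?** Dwell events are maximal runs of
   localizations within a 230-nm radius of their anchor; durations are
   `(n − 1)·τ`, summarised with SDs across replicates
   (`dwell_events()`, `mean_dwell_time()`).
3. **Where do molecules sit?** Localizations are projected through their
   cell mesh into a standardized 3 × 1 µm cell and binned into heat
   maps, optionally restricted to slow tracks
   (`D_app < 0.5 µm²/s`, `R² > 0.7`) (`build_heatmap()`).
4. **How many molecules per cell?** The corrected initial cell intensity
   (offset, flat-field and autofluorescence corrected via
   `intensity = (observed − offset)/ratio`) is divided by the unitary
   bleaching step of a single fluorophore, estimated from a
   multi-Gaussian peak fit to terminal bleaching-step intensities
   (`estimate_unitary_step()`, `count_fluorophores()`,
   `classify_bleach_steps()`).

Because raw movies for this kind of study are rarely deposited, the
package ships a first-class synthetic-data generator
(`sim_config()`, `simulate_experiment()`) producing movies (16-bit
multi-page TIFF + JSON metadata), cell meshes and track tables with known
ground truth — two-state Markov switching, tethered/free diffusion in a
spherocylinder, vignetted Gaussian PSFs, camera offset and noise, diffuse
background, quadratic cell autofluorescence and single-step bleaching —
so every stage is validated by parameter recovery.

## Worked example

```r
library(smtquant)

# simulate two conditions differing only in their bound fraction
cfgs <- list(
  WT  = sim_config(n_cells = 10, n_frames = 170, f_static = 0.70,
                   molecules_per_cell_mean = 8, p_empty = 0),
  mut = sim_config(n_cells = 10, n_frames = 170, f_static = 0.25,
                   molecules_per_cell_mean = 8, p_empty = 0))
rep <- run_pipeline(cfgs, seed = 3, n_replicates = 2,
                    stages = c("gmm", "dwell", "heatmap"))
rep$fit
#> Jump-distance mixture fit: K = 2, n = 5877 jumps, tau = 0.015 s
#>   logLik = 7639.52, BIC = -15244.32, converged: TRUE (53 iter)
#>  condition D_static D_mobile static_pct mobile_pct
#>         WT   0.0826    0.625       71.3       28.7
#>        mut   0.0826    0.625       28.1       71.9
rep$comparison
#> static fraction WT: 71.3%  vs  mut: 28.1%
#>   delta = 43.2 points (43% of molecules lose their partner)
```

The fitted table reads like a per-strain mobility table: one shared pair
of diffusion coefficients (µm²/s) and per-condition static/mobile
percentages; the comparison line is the fraction of molecules that lose
their binding partner in the mutant. `rep$dwell` holds mean dwell times
(s) with replicate SDs and `rep$heatmaps` normalized standardized-cell
densities.

Copy-number quantification on rendered movies follows the counting
protocol end to end:

```r
base  <- sim_config(n_cells = 30, n_frames = 320, seed = 101)
blank <- render_blank_movie(base, n_frames = 270, seed = 1)
ratio <- estimate_illumination_ratio(blank)             # max = 1
steps <- NULL
for (k in 1:2) {                                        # two sample movies
  cfg <- base; cfg$seed <- 100L + k
  ex     <- simulate_experiment(cfg)
  offset <- estimate_offset(ex$movie)                   # 20 dark frames
  mc     <- correct_intensity(ex$movie, offset, ratio)
  steps  <- rbind(steps, extract_bleach_steps(mc, ex$tracks, ex$meshes))
}
estimate_unitary_step(steps$step[steps$isolated])
#> unitary bleaching step: 5017 photons (2 peaks, n = 76)
```

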