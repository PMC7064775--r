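#' Simulation configuration
#'
#' Builds the parameter set for the synthetic single-molecule movie/track
#' generator. Defaults emulate the acquisition and photophysics of
#' single-molecule tracking of a low-copy membrane diguanylate cyclase in
#' exponentially growing rod-shaped bacteria: 15 ms frames, 100 nm pixels,
#' ~3 x 1 um spherocylindrical cells, a two-state (static/mobile) diffusion
#' model, single-step photobleaching and a monomer/dimer bleaching-step
#' mixture.
#'
#' @param n_cells number of cells placed in the field of view.
#' @param cell_length,cell_width cell dimensions in um (pole-to-pole length
#'   and diameter of the spherocylinder).
#' @param cell_length_sd between-cell SD of the length draw, um.
#' @param tau frame interval in seconds.
#' @param pixel_size pixel size in um.
#' @param n_frames total number of frames, including pre-laser dark frames.
#' @param laser_on_frame 1-based index of the first illuminated frame;
#'   frames `1:(laser_on_frame - 1)` contain camera offset and read noise
#'   only. The default leaves 20 dark frames for offset estimation.
#' @param D_static,D_mobile diffusion coefficients of the two mobility
#'   states, um^2/s.
#' @param f_static stationary fraction of time spent in the static (bound)
#'   state, in \[0, 1\].
#' @param mean_bound_dwell mean duration of a bound (static) episode, s.
#' @param molecules_per_cell_mean mean number of fluorophores per occupied
#'   cell (Poisson). Each tracked protein carries one fluorophore; dimers
#'   pair two of them into one emitting unit.
#' @param molecules_per_cell optional integer vector of exact per-cell
#'   fluorophore counts, overriding the Poisson draw (recycled to
#'   `n_cells`).
#' @param p_empty probability that a cell contains no labelled molecule at
#'   all (zero inflation on top of the Poisson draw).
#' @param dimer_fraction fraction of emitting units that are dimers (two
#'   fluorophores bleaching together in one step).
#' @param unitary_photons integrated photon count of a single-fluorophore
#'   PSF per frame (camera units called photons throughout).
#' @param dimer_intensity_ratio intensity of a dimer relative to a monomer.
#'   Dimers of fluorescent-protein fusions typically bleach with slightly
#'   less than twice the monomer step; the default reproduces an observed
#'   ratio of 8975/5047.
#' @param bleach_rate photobleaching rate, 1/s (single-step, no blinking).
#' @param psf_sigma standard deviation of the 2-D Gaussian PSF, um.
#' @param localization_error per-axis localization error added to emitted
#'   track coordinates, um.
#' @param offset_level camera offset, counts.
#' @param read_noise Gaussian read noise SD, counts.
#' @param vignette_sigma width (SD, um) of the Gaussian illumination
#'   profile; `vignette_center` its center in um (default: field center).
#' @param vignette_center numeric length-2 (x, y) in um, or `NULL`.
#' @param bg_level mean diffuse background photon rate per pixel at full
#'   illumination (medium/pad fluorescence outside cells).
#' @param bg_level_sd between-movie SD of `bg_level` (drives the quadratic
#'   autofluorescence regression).
#' @param autofluorescence_coeffs numeric (a, b, c): total per-cell
#'   autofluorescence photons per frame as a quadratic a*BG^2 + b*BG + c in
#'   the local background level BG.
#' @param polar_bias probability that a static anchor sits in a polar cap
#'   rather than uniformly in the cell.
#' @param anchor_radius confinement radius (um) of the tether around a
#'   static anchor; steps inside a bound episode are Brownian with
#'   `D_static` and reflected at this radius. The default (100 nm) keeps
#'   a bound molecule's whole excursion well inside the 230-nm dwell
#'   criterion, as expected for binding to a fixed receptor complex.
#' @param compartment `"interior"` simulates plain 2-D diffusion in the
#'   projected cell area; `"membrane"` diffuses on the unrolled cylinder
#'   surface and projects the circumferential coordinate.
#' @param fov_px integer length-2, field size in pixels (nx, ny). `NULL`
#'   sizes the field to fit the cell grid.
#' @param shot_noise logical, apply Poisson noise to photon counts.
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 4, n_frames = 60, seed = 1)
#' cfg$tau
#' @export
sim_config <- function(n_cells = 9,
                       cell_length = 3.0, cell_width = 1.0,
                       cell_length_sd = 0.3,
                       tau = 0.015, pixel_size = 0.100,
                       n_frames = 520, laser_on_frame = 21,
                       D_static = 0.079, D_mobile = 0.657,
                       f_static = 0.697,
                       mean_bound_dwell = 0.049,
                       molecules_per_cell_mean = 5.58,
                       molecules_per_cell = NULL,
                       p_empty = 0.29,
                       dimer_fraction = 0.25,
                       unitary_photons = 5047,
                       dimer_intensity_ratio = 8975 / 5047,
                       bleach_rate = 3.0,
                       psf_sigma = 0.130,
                       localization_error = 0.020,
                       offset_level = 100,
                       read_noise = 2,
                       vignette_sigma = 12,
                       vignette_center = NULL,
                       bg_level = 30,
                       bg_level_sd = 6,
                       autofluorescence_coeffs = c(2, 60, 500),
                       polar_bias = 0.7,
                       anchor_radius = 0.10,
                       compartment = c("interior", "membrane"),
                       fov_px = NULL,
                       shot_noise = TRUE,
                       seed = 1L) {
  compartment <- match.arg(compartment)
  cfg <- list(
    n_cells = as.integer(n_cells), cell_length = cell_length,
    cell_width = cell_width, cell_length_sd = cell_length_sd,
    tau = tau, pixel_size = pixel_size,
    n_frames = as.integer(n_frames),
    laser_on_frame = as.integer(laser_on_frame),
    D_static = D_static, D_mobile = D_mobile, f_static = f_static,
    mean_bound_dwell = mean_bound_dwell,
    molecules_per_cell_mean = molecules_per_cell_mean,
    molecules_per_cell = if (is.null(molecules_per_cell)) NULL else
      as.integer(rep_len(molecules_per_cell, n_cells)),
    p_empty = p_empty, dimer_fraction = dimer_fraction,
    unitary_photons = unitary_photons,
    dimer_intensity_ratio = dimer_intensity_ratio,
    bleach_rate = bleach_rate, psf_sigma = psf_sigma,
    localization_error = localization_error,
    offset_level = offset_level, read_noise = read_noise,
    vignette_sigma = vignette_sigma, vignette_center = vignette_center,
    bg_level = bg_level, bg_level_sd = bg_level_sd,
    autofluorescence_coeffs = autofluorescence_coeffs,
    polar_bias = polar_bias, anchor_radius = anchor_radius,
    compartment = compartment,
    fov_px = if (is.null(fov_px)) NULL else as.integer(fov_px),
    shot_noise = isTRUE(shot_noise), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 0, cfg$cell_length > 0, cfg$cell_width > 0,
            cfg$cell_length >= cfg$cell_width,
            cfg$tau > 0, cfg$pixel_size > 0, cfg$n_frames >= 1)
  if (cfg$f_static < 0 || cfg$f_static > 1)
    stop("f_static must lie in [0, 1]")
  if (cfg$dimer_fraction < 0 || cfg$dimer_fraction > 1)
    stop("dimer_fraction must lie in [0, 1]")
  if (cfg$p_empty < 0 || cfg$p_empty > 1)
    stop("p_empty must lie in [0, 1]")
  for (f in c("D_static", "D_mobile", "mean_bound_dwell", "bleach_rate",
              "unitary_photons", "psf_sigma", "localization_error",
              "offset_level", "read_noise", "bg_level", "bg_level_sd",
              "molecules_per_cell_mean", "polar_bias", "anchor_radius",
              "cell_length_sd"))
    if (cfg[[f]] < 0) stop(sprintf("%s must be non-negative", f))
  if (length(cfg$autofluorescence_coeffs) != 3L)
    stop("autofluorescence_coeffs must be length 3 (a, b, c)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (sim_config)\n")
  cat(sprintf("  %d cells (%.1f x %.1f um), %d frames @ tau = %g s, %g um/px\n",
              x$n_cells, x$cell_length, x$cell_width, x$n_frames, x$tau,
              x$pixel_size))
  cat(sprintf("  D_static = %g, D_mobile = %g um^2/s, f_static = %g, dwell = %g s\n",
              x$D_static, x$D_mobile, x$f_static, x$mean_bound_dwell))
  cat(sprintf("  %g molecules/cell, %g%% empty cells, dimer fraction %g\n",
              x$molecules_per_cell_mean, 100 * x$p_empty, x$dimer_fraction))
  cat(sprintf("  unitary step %g photons, bleach rate %g /s, seed %d\n",
              x$unitary_photons, x$bleach_rate, x$seed))
  invisible(x)
}
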