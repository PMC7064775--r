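#' Movie container
#'
#' An `smt_movie` is a list with `pixels` (numeric array
#' `ny x nx x n_frames`, camera counts; row = y, column = x, origin at the
#' image top-left), acquisition metadata `tau` (s), `pixel_size` (um) and
#' `laser_on_frame` (1-based index of the first illuminated frame), plus a
#' free-form `meta` list.
#'
#' @param pixels numeric array `ny x nx x n_frames`.
#' @param tau frame interval, s.
#' @param pixel_size pixel size, um.
#' @param laser_on_frame 1-based index of the first illuminated frame.
#' @param meta list of additional metadata (seed, background level, ...).
#' @return an `smt_movie` object.
#' @export
smt_movie <- function(pixels, tau, pixel_size, laser_on_frame, meta = list()) {
  stopifnot(length(dim(pixels)) == 3, tau > 0, pixel_size > 0,
            dim(pixels)[3] >= 1)
  structure(list(pixels = pixels, tau = tau, pixel_size = pixel_size,
                 laser_on_frame = as.integer(laser_on_frame), meta = meta),
            class = "smt_movie")
}

#' @export
print.smt_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "smt_movie: %d x %d px, %d frames (laser on at %d), tau = %g s, %g um/px\n",
    d[2], d[1], d[3], x$laser_on_frame, x$tau, x$pixel_size))
  invisible(x)
}

n_frames <- function(movie) dim(movie$pixels)[3]

# vignette (illumination) profile over the pixel grid, max ~ 1 at center
vignette_matrix <- function(nx, ny, pixel_size, sigma, center = NULL) {
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  if (is.null(center)) center <- c(nx, ny) / 2 * pixel_size
  gx <- exp(-(xc - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(yc - center[2])^2 / (2 * sigma^2))
  outer(gy, gx)
}

# add one pixel-integrated Gaussian PSF (integral A before vignetting)
add_psf <- function(P, x, y, A, sigma, pixel_size) {
  ny <- nrow(P); nx <- ncol(P)
  r <- ceiling(5 * sigma / pixel_size) + 1L
  j0 <- floor(x / pixel_size) + 1L
  i0 <- floor(y / pixel_size) + 1L
  js <- max(1L, j0 - r):min(nx, j0 + r)
  is <- max(1L, i0 - r):min(ny, i0 + r)
  if (length(js) == 0L || length(is) == 0L) return(P)
  fx <- diff(stats::pnorm(c(js[1] - 1L, js) * pixel_size, x, sigma))
  fy <- diff(stats::pnorm(c(is[1] - 1L, is) * pixel_size, y, sigma))
  P[is, js] <- P[is, js] + A * outer(fy, fx)
  P
}

# pixel indices (matrix row/col) whose centers fall inside a polygon
polygon_pixel_mask <- function(poly, nx, ny, pixel_size) {
  jr <- max(1L, floor(min(poly[, 1]) / pixel_size)):
        min(nx, ceiling(max(poly[, 1]) / pixel_size))
  ir <- max(1L, floor(min(poly[, 2]) / pixel_size)):
        min(ny, ceiling(max(poly[, 2]) / pixel_size))
  grid <- expand.grid(i = ir, j = jr)
  ctr <- cbind((grid$j - 0.5) * pixel_size, (grid$i - 0.5) * pixel_size)
  keep <- points_in_polygon(ctr, poly)
  cbind(i = grid$i[keep], j = grid$j[keep])
}

#' Render the camera movie from ground truth
#'
#' Frames before `laser_on_frame` contain camera offset and read noise
#' only. From `laser_on_frame` on, each live fluorophore contributes a
#' pixel-integrated 2-D Gaussian PSF whose total photon count is
#' `unitary_photons` (dimers `dimer_intensity_ratio` times that),
#' multiplied by the illumination (vignette) factor at the molecule
#' position. Diffuse background (outside cells; cells displace the
#' medium) and per-cell autofluorescence — a quadratic
#' `a*BG^2 + b*BG + c` in the movie's background level, spread uniformly
#' over the cell's pixels — are added under the same illumination profile.
#' Bleaching is a single step to zero per fluorophore. Optional Poisson
#' shot noise applies to all photon signal; Gaussian read noise to every
#' frame.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list (see [simulate_experiment()]).
#' @param layout cell layout from the simulation (meshes, field size).
#' @param bg_level background photon level for this movie; `NULL` draws
#'   one from `N(bg_level, bg_level_sd)` truncated at zero.
#' @return an [smt_movie()] with the generating metadata in `$meta`.
#' @export
render_movie <- function(config, truth, layout, bg_level = NULL) {
  if (config$n_frames <= config$laser_on_frame - 1L)
    stop("n_frames must exceed the number of pre-laser frames")
  px <- config$pixel_size
  dims <- if (is.null(config$fov_px))
    as.integer(ceiling(layout$field_um / px)) else config$fov_px
  nx <- dims[1]; ny <- dims[2]
  V <- vignette_matrix(nx, ny, px, config$vignette_sigma,
                       config$vignette_center)
  if (is.null(bg_level))
    bg_level <- max(0, stats::rnorm(1, config$bg_level, config$bg_level_sd))
  co <- config$autofluorescence_coeffs
  af_total <- co[1] * bg_level^2 + co[2] * bg_level + co[3]
  # base photon map: background outside cells, autofluorescence inside
  bg_map <- matrix(bg_level, ny, nx)
  ids <- if (config$n_cells > 0) mesh_cell_ids(layout$meshes) else integer(0)
  for (cid in ids) {
    mask <- polygon_pixel_mask(mesh_polygon(layout$meshes, cid), nx, ny, px)
    if (nrow(mask) > 0) bg_map[mask] <- af_total / nrow(mask)
  }
  P0 <- V * bg_map
  mols <- truth$molecules
  # per-frame list of live molecules
  frames <- array(0, dim = c(ny, nx, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    if (f < config$laser_on_frame) {
      P <- matrix(0, ny, nx)
    } else {
      P <- P0
      rel <- f - config$laser_on_frame + 1L
      live <- if (nrow(mols) > 0) which(mols$frames_alive >= rel) else integer(0)
      for (m in live) {
        p <- truth$positions[[m]][rel, ]
        j <- min(nx, max(1, floor(p[1] / px) + 1))
        i <- min(ny, max(1, floor(p[2] / px) + 1))
        A <- config$unitary_photons *
          if (mols$dimer[m]) config$dimer_intensity_ratio else 1
        P <- add_psf(P, p[1], p[2], A * V[i, j], config$psf_sigma, px)
      }
    }
    if (config$shot_noise && any(P > 0))
      P[] <- stats::rpois(length(P), P)
    fr <- config$offset_level + P
    if (config$read_noise > 0)
      fr <- fr + stats::rnorm(length(fr), 0, config$read_noise)
    frames[, , f] <- fr
  }
  smt_movie(frames, config$tau, px, config$laser_on_frame,
            meta = list(seed = config$seed, bg_level = bg_level,
                        field_um = c(nx, ny) * px))
}

#' Render a cell-free (blank) movie for illumination calibration
#'
#' @param config a [sim_config()]; cells and molecules are ignored.
#' @param n_frames optional frame count override.
#' @param seed seed for the noise draw.
#' @return an [smt_movie()].
#' @export
render_blank_movie <- function(config, n_frames = NULL, seed = config$seed) {
  cfg <- config
  if (is.null(cfg$fov_px)) {
    g <- grid_geometry(config)   # keep the sample-movie field size
    cfg$fov_px <- as.integer(ceiling(g$field_um / cfg$pixel_size))
  }
  cfg$n_cells <- 0L
  if (!is.null(n_frames)) cfg$n_frames <- as.integer(n_frames)
  cfg$molecules_per_cell <- integer(0)
  set.seed(seed)
  lay <- layout_cells(cfg)
  lay$field_um <- cfg$fov_px * cfg$pixel_size
  truth <- list(molecules = data.frame(molecule_id = integer(),
                                       cell_id = integer(),
                                       dimer = logical(),
                                       frames_alive = integer()),
                positions = list(), config = cfg)
  render_movie(cfg, truth, lay, bg_level = cfg$bg_level)
}

# ---- TIFF + sidecar JSON I/O -----------------------------------------------

#' Write / read a movie as multi-page 16-bit TIFF with JSON metadata
#'
#' The sidecar `<path>.json` stores `tau_s`, `pixel_size_um`,
#' `laser_on_frame` (0-based, matching the on-disk convention) and `seed`.
#' Pixel values are rounded and clipped to the 16-bit range on write.
#'
#' @param movie an [smt_movie()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  n <- n_frames(movie)
  pages <- lapply(seq_len(n), function(f) {
    m <- round(movie$pixels[, , f])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(tau_s = movie$tau, pixel_size_um = movie$pixel_size,
               laser_on_frame = movie$laser_on_frame - 1L,
               seed = movie$meta$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]]
  smt_movie(arr, meta$tau_s, meta$pixel_size_um, meta$laser_on_frame + 1L,
            meta = list(seed = meta$seed))
}

#' Write / read a track table as CSV
#'
#' On-disk frames are 0-based (`track_id,frame,x_um,y_um,cell_id`);
#' in-memory frames are 1-based.
#'
#' @param tracks a track table.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- tracks[, c("track_id", "frame", "x_um", "y_um", "cell_id")]
  out$frame <- out$frame - 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  d$frame <- as.integer(d$frame) + 1L
  d
}
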