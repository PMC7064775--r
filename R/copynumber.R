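#' @title Fluorophore copy-number quantification by bleaching-step analysis
#' @description
#' The counting protocol has two halves: (A) estimate the intensity drop
#' caused by bleaching of one fluorophore (the unitary step) from the
#' terminal intensities of tracked spots, and (B) measure each cell's
#' integrated intensity right after the laser switches on, fully
#' corrected for camera offset, uneven illumination and cell
#' autofluorescence. Dividing (B) by (A) estimates the number of
#' fluorophores per cell. All frame corrections follow
#' `intensity = (observed - offset) / ratio`.
#' @name copy-number
NULL

# ---- corrections ------------------------------------------------------------

#' Estimate the camera offset from pre-laser dark frames
#'
#' Per-pixel (default) or global median over the first 20 frames before
#' the laser is switched on.
#'
#' @param movie an [smt_movie()].
#' @param mode `"pixel"` or `"scalar"`.
#' @param n_dark number of dark frames used (at least this many pre-laser
#'   frames must exist).
#' @return matrix (pixel mode) or scalar offset, counts.
#' @export
estimate_offset <- function(movie, mode = c("pixel", "scalar"),
                            n_dark = 20L) {
  mode <- match.arg(mode)
  pre <- movie$laser_on_frame - 1L
  if (pre < n_dark)
    stop("insufficient dark frames: ", pre, " pre-laser frames, need ",
         n_dark)
  dark <- movie$pixels[, , seq_len(n_dark), drop = FALSE]
  if (mode == "scalar") return(stats::median(dark))
  apply(dark, c(1, 2), stats::median)
}

#' Estimate the illumination (vignette) ratio from cell-free movies
#'
#' For each pixel, the mean offset-corrected intensity over all
#' post-laser frames of the blank movies, divided by the maximum, giving
#' values in (0, 1] with max exactly 1. Pixels whose ratio falls below
#' `floor` (field edges) are floored and flagged; they should be excluded
#' from cell integration.
#'
#' @param blank_movies an [smt_movie()] or list of them (no cells).
#' @param offset offset for correction; `NULL` estimates it from each
#'   blank movie's own dark frames.
#' @param floor minimum admissible ratio.
#' @param smooth_sigma Gaussian smoothing (px) of the mean blank image
#'   before normalization; the illumination profile varies on scales far
#'   larger than a pixel, so smoothing suppresses pixel noise (and the
#'   upward bias of the maximum over noisy pixels) without distorting the
#'   profile. 0 disables.
#' @return matrix with attribute `flagged` (logical matrix of floored
#'   pixels).
#' @export
estimate_illumination_ratio <- function(blank_movies, offset = NULL,
                                        floor = 0.05, smooth_sigma = 2) {
  if (inherits(blank_movies, "smt_movie")) blank_movies <- list(blank_movies)
  acc <- NULL
  for (mv in blank_movies) {
    off <- if (is.null(offset)) estimate_offset(mv) else offset
    post <- mv$laser_on_frame:n_frames(mv)
    m <- apply(mv$pixels[, , post, drop = FALSE], c(1, 2), mean) - off
    acc <- if (is.null(acc)) m else acc + m
  }
  acc <- acc / length(blank_movies)
  if (smooth_sigma > 0)
    acc <- EBImage::gblur(acc, sigma = smooth_sigma)
  ratio <- acc / max(acc)
  flagged <- ratio < floor
  ratio[flagged] <- floor
  structure(ratio, flagged = flagged)
}

#' Apply the correction equation to a frame or movie
#'
#' `intensity = (observed - offset) / ratio`, applied per pixel.
#'
#' @param x numeric matrix (one frame) or an [smt_movie()].
#' @param offset scalar or matrix offset.
#' @param ratio illumination ratio matrix (or 1).
#' @return corrected frame or movie of the same shape.
#' @export
correct_intensity <- function(x, offset, ratio = 1) {
  if (inherits(x, "smt_movie")) {
    px <- x$pixels
    for (f in seq_len(dim(px)[3])) px[, , f] <- (px[, , f] - offset) / ratio
    x$pixels <- px
    return(x)
  }
  (x - offset) / ratio
}

# distance of pixel centers to a polygon (negative inside), on a bounding
# box; returns list of index matrices for inside/dilated/shell masks
cell_pixel_cache <- function(poly, nx, ny, pixel_size, dilate_px = 2,
                             shell_px = c(3, 7)) {
  pad <- (max(shell_px) + 2) * pixel_size
  jr <- max(1L, floor((min(poly[, 1]) - pad) / pixel_size)):
        min(nx, ceiling((max(poly[, 1]) + pad) / pixel_size))
  ir <- max(1L, floor((min(poly[, 2]) - pad) / pixel_size)):
        min(ny, ceiling((max(poly[, 2]) + pad) / pixel_size))
  grid <- expand.grid(i = ir, j = jr)
  ctr <- cbind((grid$j - 0.5) * pixel_size, (grid$i - 0.5) * pixel_size)
  inside <- points_in_polygon(ctr, poly)
  # distance to polygon boundary (px units)
  closed <- rbind(poly, poly[1, ])
  dmin <- rep(Inf, nrow(ctr))
  for (e in seq_len(nrow(closed) - 1)) {
    a <- closed[e, ]; b <- closed[e + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((ctr[, 1] - a[1]) * ab[1] + (ctr[, 2] - a[2]) * ab[2]) /
      max(len2, 1e-12)
    t <- pmin(1, pmax(0, t))
    dx <- ctr[, 1] - (a[1] + t * ab[1])
    dy <- ctr[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  d_px <- dmin / pixel_size
  sel <- function(mask) cbind(i = grid$i[mask], j = grid$j[mask])
  list(inside = sel(inside),
       dilated = sel(inside | d_px <= dilate_px),
       ring = sel(!inside & d_px <= dilate_px),
       shell = sel(!inside & d_px > shell_px[1] & d_px <= shell_px[2]))
}

# integrated cell signal on a corrected image: sum over the 2-px-dilated
# mesh minus the local (shell) background times the ring pixel count
measure_cell <- function(img, cache) {
  bg <- stats::median(img[cache$shell])
  signal <- sum(img[cache$dilated]) - bg * nrow(cache$ring)
  list(signal = signal, bg = bg, n_px = nrow(cache$dilated))
}

#' Fit the quadratic autofluorescence model on label-free movies
#'
#' Regresses the integrated cell signal of unlabelled (wild-type) cells,
#' measured on the mean of the first two illuminated frames after offset
#' and illumination correction, on the local background level of each
#' cell (median corrected intensity in a shell outside the mesh):
#' `AF = a*BG^2 + b*BG + c`. Applied to sample movies the model predicts
#' the autofluorescence contribution at the moment the laser switches on.
#' The definition of the background covariate (cell-free shell signal) is
#' a documented package choice.
#'
#' @param wt_movies list of label-free [smt_movie()]s (typically ~10).
#' @param wt_meshes list of mesh sets, parallel to `wt_movies`.
#' @param ratio illumination ratio matrix.
#' @param offset offset; `NULL` estimates it per movie.
#' @param n_init number of initial illuminated frames averaged.
#' @return object of class `smt_af_model`: coefficients `a`, `b`, `c`,
#'   the underlying `lm` fit and the per-cell training data.
#' @export
fit_autofluorescence <- function(wt_movies, wt_meshes, ratio, offset = NULL,
                                 n_init = 2L) {
  if (inherits(wt_movies, "smt_movie")) wt_movies <- list(wt_movies)
  if (inherits(wt_meshes, "smt_mesh")) wt_meshes <- list(wt_meshes)
  rows <- list()
  for (k in seq_along(wt_movies)) {
    mv <- wt_movies[[k]]
    off <- if (is.null(offset)) estimate_offset(mv) else offset
    img <- init_intensity_image(mv, off, ratio, n_init)
    dims <- dim(mv$pixels)
    for (cid in mesh_cell_ids(wt_meshes[[k]])) {
      cache <- cell_pixel_cache(mesh_polygon(wt_meshes[[k]], cid),
                                dims[2], dims[1], mv$pixel_size)
      m <- measure_cell(img, cache)
      rows[[length(rows) + 1L]] <-
        data.frame(movie = k, cell_id = cid, af = m$signal, bg = m$bg)
    }
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 3)
    stop("underdetermined autofluorescence fit: need at least 3 cells")
  fit <- stats::lm(af ~ I(bg^2) + bg, data = d)
  co <- stats::coef(fit)
  structure(list(a = unname(co["I(bg^2)"]), b = unname(co["bg"]),
                 c = unname(co["(Intercept)"]), fit = fit, data = d),
            class = "smt_af_model")
}

#' Predict the autofluorescence contribution for a background level
#' @param model `smt_af_model`.
#' @param bg background level(s), corrected counts per pixel.
#' @return predicted autofluorescence signal per cell.
#' @export
predict_autofluorescence <- function(model, bg) {
  model$a * bg^2 + model$b * bg + model$c
}

#' @export
print.smt_af_model <- function(x, ...) {
  cat(sprintf(
    "autofluorescence model: AF = %.4g*BG^2 + %.4g*BG + %.4g (%d cells)\n",
    x$a, x$b, x$c, nrow(x$data)))
  invisible(x)
}

# mean corrected image over the first n_init illuminated frames
init_intensity_image <- function(movie, offset, ratio, n_init = 2L) {
  fr <- movie$laser_on_frame + seq_len(n_init) - 1L
  img <- matrix(0, dim(movie$pixels)[1], dim(movie$pixels)[2])
  for (f in fr) img <- img + (movie$pixels[, , f] - offset) / ratio
  img / length(fr)
}

# ---- spot traces and bleaching steps ---------------------------------------

#' Integrated spot intensity with local background subtraction
#'
#' Sums corrected pixel intensities inside a circle of radius `r_px`
#' pixels centered on the spot and subtracts the local background. The
#' in-cell background per pixel is the median of the pixels outside the
#' circle but inside the cell contour extended by `dilate_px` pixels.
#' Because the circle (radius 6 px = 0.6 um) is wider than half the cell,
#' part of it usually lies outside the cell where the background level
#' (medium) differs from in-cell autofluorescence; those circle pixels
#' are corrected with the cell-free shell median instead, so the
#' subtraction is exact on both sides of the cell boundary.
#'
#' @param img corrected frame (matrix).
#' @param x_um,y_um spot position, um.
#' @param mesh mesh set; `cell` the containing cell id.
#' @param cell cell id.
#' @param pixel_size pixel size, um.
#' @param r_px circle mask radius, px.
#' @param dilate_px cell contour extension, px.
#' @return spot intensity (photons); attribute `truncated` is TRUE when
#'   the circle extends past the image edge.
#' @export
spot_integrated_intensity <- function(img, x_um, y_um, mesh, cell,
                                      pixel_size, r_px = 6L,
                                      dilate_px = 2L) {
  ny <- nrow(img); nx <- ncol(img)
  jc <- x_um / pixel_size + 0.5  # pixel-center units
  ic <- y_um / pixel_size + 0.5
  jr <- max(1L, floor(jc - r_px)):min(nx, ceiling(jc + r_px))
  ir <- max(1L, floor(ic - r_px)):min(ny, ceiling(ic + r_px))
  grid <- expand.grid(i = ir, j = jr)
  incirc <- (grid$i - ic)^2 + (grid$j - jc)^2 <= r_px^2
  circ <- cbind(grid$i[incirc], grid$j[incirc])
  truncated <- (jc - r_px < 0.5) || (jc + r_px > nx + 0.5) ||
               (ic - r_px < 0.5) || (ic + r_px > ny + 0.5)
  if (truncated) warning("spot mask truncated at the image edge")
  cache <- cell_pixel_cache(mesh_polygon(mesh, cell), nx, ny, pixel_size,
                            dilate_px = dilate_px)
  incell <- cache$inside
  key <- function(m) (m[, 2] - 1) * ny + m[, 1]
  circ_in <- key(circ) %in% key(incell)
  bg_idx <- incell[!(key(incell) %in% key(circ)), , drop = FALSE]
  bg_cell <- if (nrow(bg_idx) > 0) stats::median(img[bg_idx]) else 0
  shell_idx <- cache$shell[!(key(cache$shell) %in% key(circ)), ,
                           drop = FALSE]
  bg_out <- if (nrow(shell_idx) > 0) stats::median(img[shell_idx]) else
    bg_cell
  structure(sum(img[circ]) - bg_cell * sum(circ_in) -
              bg_out * sum(!circ_in),
            truncated = truncated, bg_cell = bg_cell, bg_out = bg_out)
}

#' Build the intensity-versus-time trace of one track
#'
#' Integrated spot intensity at each frame of the track on the corrected
#' movie, then median-filtered (window `median_window`) to clean noisy
#' data. Tracks shorter than the filter window are returned unfiltered
#' and flagged.
#'
#' @param movie_corr corrected [smt_movie()] (see [correct_intensity()]).
#' @param track one track (`frame`, `x_um`, `y_um`, `cell_id`).
#' @param meshes mesh set.
#' @param median_window odd filter window, frames.
#' @param ... passed to [spot_integrated_intensity()].
#' @return data frame `frame`, `intensity`, `filtered`; attribute
#'   `unfiltered` if the filter could not run.
#' @export
build_intensity_trace <- function(movie_corr, track, meshes,
                                  median_window = 3L, ...) {
  track <- track[order(track$frame), , drop = FALSE]
  cell <- track$cell_id[1]
  raw <- vapply(seq_len(nrow(track)), function(k)
    as.numeric(spot_integrated_intensity(
      movie_corr$pixels[, , track$frame[k]],
      track$x_um[k], track$y_um[k], meshes, cell,
      movie_corr$pixel_size, ...)), 1)
  unfiltered <- length(raw) < median_window
  filt <- if (unfiltered) raw else
    stats::runmed(raw, median_window, endrule = "median")
  structure(data.frame(frame = track$frame, intensity = raw,
                       filtered = as.numeric(filt)),
            unfiltered = unfiltered)
}

#' Extract terminal bleaching-step intensities from tracked spots
#'
#' For every track that disappears before the movie ends (i.e. that
#' bleaches), the terminal step intensity is the mean of the last two
#' median-filtered trace values. Steps are flagged `isolated` when no
#' other track has a localization within `min_sep_um` during those final
#' frames; only isolated steps should enter the unitary-step histogram,
#' since overlapping emitters inflate the apparent step.
#'
#' @param movie_corr corrected movie.
#' @param tracks cell-assigned track table.
#' @param meshes mesh set.
#' @param min_sep_um isolation radius, um.
#' @param min_length minimum track length (frames) considered.
#' @return data frame: `track_id`, `cell_id`, `step`, `isolated`.
#' @export
extract_bleach_steps <- function(movie_corr, tracks, meshes,
                                 min_sep_um = 0.7, min_length = 3L) {
  last_frame <- n_frames(movie_corr)
  ids <- unique(tracks$track_id)
  out <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < min_length) next
    if (max(tr$frame) >= last_frame) next  # did not bleach on camera
    if (is.na(tr$cell_id[1])) next
    trace <- build_intensity_trace(movie_corr, tr, meshes)
    tail2 <- utils::tail(trace$filtered, 2)
    fin <- utils::tail(tr, 2)
    near <- tracks$track_id != id &
      tracks$frame %in% fin$frame &
      sqrt((tracks$x_um - fin$x_um[nrow(fin)])^2 +
           (tracks$y_um - fin$y_um[nrow(fin)])^2) < min_sep_um
    out[[length(out) + 1L]] <- data.frame(
      track_id = id, cell_id = tr$cell_id[1], step = mean(tail2),
      isolated = !any(near))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = integer(), cell_id = integer(),
                      step = numeric(), isolated = logical())
  out
}

#' Estimate the unitary bleaching step
#'
#' Multi-Gaussian peak fit (1-3 equal-variance components, BIC-selected)
#' to the distribution of terminal step intensities; the mean of the
#' lowest-order (lowest-mean) peak is the single-fluorophore step.
#'
#' @param steps numeric vector of step intensities (photons); typically
#'   the `isolated` steps from [extract_bleach_steps()].
#' @param G candidate numbers of peaks.
#' @param min_steps minimum sample size.
#' @return object of class `smt_unitary_step`: `I_unit`, peak `means`
#'   and `weights`, `n`.
#' @export
estimate_unitary_step <- function(steps, G = 1:3, min_steps = 50L) {
  steps <- steps[is.finite(steps) & steps > 0]
  if (length(steps) < min_steps)
    stop("need at least ", min_steps, " bleaching steps, got ",
         length(steps))
  if (stats::sd(steps) < 1e-9 * mean(steps))   # degenerate histogram
    return(structure(list(I_unit = steps[1], means = steps[1],
                          weights = 1, n = length(steps)),
                     class = "smt_unitary_step"))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this symbol by name
  fit <- tryCatch(
    mclust::Mclust(steps, G = G, modelNames = "E", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("peak fit failed; falling back to a single peak")
    means <- mean(steps); weights <- 1
  } else {
    means <- as.numeric(fit$parameters$mean)
    weights <- as.numeric(fit$parameters$pro)
    ord <- order(means)
    means <- means[ord]; weights <- weights[ord]
  }
  structure(list(I_unit = means[1], means = means, weights = weights,
                 n = length(steps)),
            class = "smt_unitary_step")
}

#' @export
print.smt_unitary_step <- function(x, ...) {
  cat(sprintf("unitary bleaching step: %.0f photons (%d peaks, n = %d)\n",
              x$I_unit, length(x$means), x$n))
  invisible(x)
}

#' Classify bleaching steps into monomer and dimer fractions
#'
#' Two-component equal-variance Gaussian classification of terminal step
#' intensities; reports the fraction and mean step of each class and
#' flags the fit when the second mean is not approximately twice the
#' first (expected for two fluorophores bleaching together).
#'
#' @param steps numeric step intensities.
#' @param min_steps undersampling threshold (warning below it).
#' @return list: `fractions` (monomer, dimer), `means`, `ratio`,
#'   `ratio_ok` (TRUE when mean2/mean1 is within \[1.5, 2.5\]), `n`.
#' @export
classify_bleach_steps <- function(steps, min_steps = 20L) {
  steps <- steps[is.finite(steps) & steps > 0]
  if (length(steps) < min_steps)
    warning("undersampled: only ", length(steps), " bleaching steps")
  if (stats::sd(steps) < 1e-9 * mean(steps))
    return(list(fractions = c(monomer = 1, dimer = 0),
                means = c(monomer = mean(steps), dimer = NA),
                ratio = NA, ratio_ok = NA, n = length(steps)))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this symbol by name
  fit <- tryCatch(
    mclust::Mclust(steps, G = 2, modelNames = "E", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("two-component classification failed; reporting one class")
    return(list(fractions = c(monomer = 1, dimer = 0),
                means = c(monomer = mean(steps), dimer = NA),
                ratio = NA, ratio_ok = NA, n = length(steps)))
  }
  means <- as.numeric(fit$parameters$mean)
  pro <- as.numeric(fit$parameters$pro)
  ord <- order(means)
  means <- means[ord]; pro <- pro[ord]
  ratio <- means[2] / means[1]
  list(fractions = c(monomer = pro[1], dimer = pro[2]),
       means = c(monomer = means[1], dimer = means[2]),
       ratio = ratio, ratio_ok = ratio >= 1.5 && ratio <= 2.5,
       n = length(steps))
}

# ---- per-cell counting ------------------------------------------------------

#' Count fluorophores per cell
#'
#' The corrected initial intensity of each cell is the mean integrated
#' cell signal over the first two illuminated frames (offset subtracted,
#' divided by the illumination ratio, local background and predicted
#' autofluorescence removed); dividing by the unitary bleaching step
#' gives the estimated fluorophore number N. Negative intensities are
#' clipped to zero and flagged.
#'
#' @param movie sample [smt_movie()].
#' @param meshes mesh set for this movie.
#' @param offset camera offset (matrix or scalar).
#' @param ratio illumination ratio matrix.
#' @param af_model `smt_af_model` from [fit_autofluorescence()].
#' @param I_unit unitary step (photons) or an `smt_unitary_step`.
#' @param n_init initial illuminated frames averaged (2 per protocol).
#' @return data frame of class `smt_cell_counts`: `cell_id`,
#'   `length_um`, `bg`, `I0`, `N`, `clipped`.
#' @export
count_fluorophores <- function(movie, meshes, offset, ratio, af_model,
                               I_unit, n_init = 2L) {
  if (inherits(I_unit, "smt_unitary_step")) I_unit <- I_unit$I_unit
  if (I_unit <= 0) stop("I_unit must be positive")
  img <- init_intensity_image(movie, offset, ratio, n_init)
  dims <- dim(movie$pixels)
  lens <- mesh_cell_lengths(meshes)
  out <- lapply(mesh_cell_ids(meshes), function(cid) {
    cache <- cell_pixel_cache(mesh_polygon(meshes, cid), dims[2], dims[1],
                              movie$pixel_size)
    m <- measure_cell(img, cache)
    I0 <- m$signal - predict_autofluorescence(af_model, m$bg)
    clipped <- I0 < 0
    if (clipped) I0 <- 0
    data.frame(cell_id = cid,
               length_um = lens$length_um[lens$cell_id == cid],
               bg = m$bg, I0 = I0, N = I0 / I_unit, clipped = clipped)
  })
  out <- do.call(rbind, out)
  class(out) <- c("smt_cell_counts", "data.frame")
  out
}

#' Correlation between fluorophore number and cell length
#'
#' Pearson correlation of per-cell N against cell length, the check for
#' whether expression scales with cell size.
#'
#' @param counts `smt_cell_counts` (or any data frame with `N` and
#'   `length_um`).
#' @return list: `r`, `p_value`, `n`.
#' @export
count_vs_length <- function(counts) {
  if (nrow(counts) < 3) stop("need at least 3 cells")
  if (stats::sd(counts$N) == 0 || stats::sd(counts$length_um) == 0)
    stop("zero variance in N or cell length")
  ct <- stats::cor.test(counts$N, counts$length_um)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(counts))
}
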