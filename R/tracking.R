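#' @title Spot detection, track linking and cell assignment
#' @description
#' Detects diffraction-limited spots frame by frame (band-pass filtering,
#' local maxima, least-squares 2-D Gaussian refinement), links them into
#' gap-free trajectories by globally optimal frame-to-frame assignment,
#' and labels localizations with the cell mesh that contains them.
#' Defaults follow the tracking settings used throughout: minimum track
#' length 4, no gap closing.
#' @name detection-tracking
NULL

#' Trim a movie to a fixed number of analysis frames
#'
#' Retains all pre-laser frames (needed for offset estimation) plus the
#' first `target_frames` illuminated frames, so that movies of different
#' lengths can be cut to equal analysis lengths.
#'
#' @param movie an [smt_movie()].
#' @param target_frames number of post-laser frames to keep.
#' @return trimmed [smt_movie()].
#' @export
trim_movie <- function(movie, target_frames) {
  if (target_frames <= 0) stop("target_frames must be positive")
  pre <- movie$laser_on_frame - 1L
  avail <- n_frames(movie) - pre
  if (target_frames > avail)
    stop("target_frames (", target_frames, ") exceeds available post-laser ",
         "frames (", avail, ")")
  keep <- c(seq_len(pre), pre + seq_len(target_frames))
  smt_movie(movie$pixels[, , keep, drop = FALSE], movie$tau,
            movie$pixel_size, movie$laser_on_frame, movie$meta)
}

#' Detect single-molecule spots in one frame
#'
#' Band-pass (difference-of-Gaussians) filtering, 8-neighbour local
#' maxima above `snr` times the robust noise scale of the filtered image,
#' then least-squares refinement of a fixed-width 2-D Gaussian (sub-pixel
#' centroid, integrated intensity, constant local background). Spots
#' whose intensity-weighted RMS width clearly exceeds the PSF width are
#' flagged as possible merges of unresolved emitters.
#'
#' @param frame numeric matrix (one movie frame, ideally offset/flat-field
#'   corrected; row = y, col = x).
#' @param pixel_size pixel size, um.
#' @param psf_sigma PSF standard deviation, um.
#' @param snr detection threshold in units of the noise scale of the
#'   band-passed frame.
#' @param min_sep minimum separation between accepted maxima, px.
#' @param expected_photons optional calibrated single-emitter intensity;
#'   spots brighter than 1.5x this are additionally flagged `merged`
#'   (unresolved pairs closer than the PSF width are shape-degenerate
#'   with a brighter single emitter).
#' @return data frame: `x_um`, `y_um`, `photons`, `background`, `rss`,
#'   `merged`. Zero rows for blank/constant frames.
#' @export
detect_spots <- function(frame, pixel_size, psf_sigma = 0.130, snr = 5,
                         min_sep = 2, expected_photons = Inf) {
  s_px <- psf_sigma / pixel_size
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      photons = numeric(), background = numeric(),
                      rss = numeric(), merged = logical())
  if (stats::sd(frame) == 0) return(empty)
  bp <- EBImage::gblur(frame, sigma = s_px) -
        EBImage::gblur(frame, sigma = 2.5 * s_px)
  noise <- stats::mad(bp)
  if (noise == 0) noise <- stats::sd(bp)
  if (noise == 0) return(empty)
  thr <- snr * noise
  ny <- nrow(bp); nx <- ncol(bp)
  # 8-neighbour local maxima (interior pixels only)
  core <- bp[2:(ny - 1), 2:(nx - 1)]
  ismax <- core >= thr &
    core >= bp[1:(ny - 2), 2:(nx - 1)] & core >= bp[3:ny, 2:(nx - 1)] &
    core >= bp[2:(ny - 1), 1:(nx - 2)] & core >= bp[2:(ny - 1), 3:nx] &
    core >= bp[1:(ny - 2), 1:(nx - 2)] & core >= bp[1:(ny - 2), 3:nx] &
    core >= bp[3:ny, 1:(nx - 2)] & core >= bp[3:ny, 3:nx]
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(i = idx[, 1] + 1L, j = idx[, 2] + 1L,
                     v = core[ismax])
  cand <- cand[order(-cand$v), ]
  # greedy suppression of maxima closer than min_sep px
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d2 <- (cand$i[keep] - cand$i[k])^2 + (cand$j[keep] - cand$j[k])^2
    if (min(d2) >= min_sep^2) keep[k] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  r <- max(3L, ceiling(2.5 * s_px))
  out <- lapply(seq_len(nrow(cand)), function(k) {
    i0 <- cand$i[k]; j0 <- cand$j[k]
    is <- max(1L, i0 - r):min(ny, i0 + r)
    js <- max(1L, j0 - r):min(nx, j0 + r)
    patch <- frame[is, js]
    xs <- (js - 0.5) * pixel_size
    ys <- (is - 0.5) * pixel_size
    b0 <- stats::median(patch)
    w <- pmax(patch - b0, 0)
    if (sum(w) == 0) return(NULL)
    x0 <- sum(outer(rep(1, length(is)), xs) * w) / sum(w)
    y0 <- sum(outer(ys, rep(1, length(js))) * w) / sum(w)
    A0 <- max(sum(w), max(patch) - b0)
    fit <- stats::optim(
      c(x0, y0, log(A0), b0),
      function(p) {
        fxx <- diff(stats::pnorm(c(js[1] - 1L, js) * pixel_size, p[1],
                                 psf_sigma))
        fyy <- diff(stats::pnorm(c(is[1] - 1L, is) * pixel_size, p[2],
                                 psf_sigma))
        mod <- p[4] + exp(p[3]) * outer(fyy, fxx)
        sum((patch - mod)^2)
      }, method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-10))
    # intensity-weighted RMS width as a merge diagnostic
    rms <- sqrt(sum(w * (outer(rep(1, length(is)), xs) - x0)^2 +
                    w * (outer(ys, rep(1, length(js))) - y0)^2) /
                  (2 * sum(w)))
    phot <- exp(fit$par[3])
    data.frame(x_um = fit$par[1], y_um = fit$par[2],
               photons = phot, background = fit$par[4],
               rss = fit$value,
               merged = rms > 1.35 * psf_sigma ||
                 phot > 1.5 * expected_photons)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect spots in every illuminated frame of a movie
#'
#' @param movie an [smt_movie()].
#' @param correct optional function applied to each frame before
#'   detection (e.g. offset/flat-field correction).
#' @param ... passed to [detect_spots()].
#' @return data frame of spots with a `frame` column (1-based).
#' @export
detect_spots_movie <- function(movie, correct = NULL, ...) {
  frames <- movie$laser_on_frame:n_frames(movie)
  out <- lapply(frames, function(f) {
    fr <- movie$pixels[, , f]
    if (!is.null(correct)) fr <- correct(fr)
    s <- detect_spots(fr, movie$pixel_size, ...)
    if (nrow(s) > 0) s$frame <- f
    s
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(x_um = numeric(), y_um = numeric(),
                      photons = numeric(), background = numeric(),
                      rss = numeric(), merged = logical(),
                      frame = integer())
  out
}

#' Link detected spots into gap-free trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement
#' (Hungarian algorithm) under a hard displacement gate; conflicting
#' nearest-neighbour claims are resolved globally and deterministically.
#' Tracks are never extended across a missed frame (no gap closing);
#' fragments shorter than `min_length` localizations are discarded.
#'
#' @param spots data frame with `frame`, `x_um`, `y_um` (from
#'   [detect_spots_movie()]).
#' @param max_disp maximum frame-to-frame displacement, um.
#' @param min_length minimum number of localizations per track.
#' @return track table: `track_id`, `frame`, `x_um`, `y_um` plus any
#'   other spot columns.
#' @export
link_tracks <- function(spots, max_disp = 0.5, min_length = 4L) {
  if (max_disp <= 0) stop("max_disp must be positive")
  if (nrow(spots) == 0L)
    return(cbind(data.frame(track_id = integer()), spots))
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(spots$frame))
  prev_idx <- which(spots$frame == frames[1])
  spots$track_id[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx) + 1L
  BIG <- 1e12
  if (length(frames) > 1) for (fi in 2:length(frames)) {
    cur_idx <- which(spots$frame == frames[fi])
    if (frames[fi] != frames[fi - 1] + 1L) {
      # gap in detected frames: all current spots start new tracks
      spots$track_id[cur_idx] <- next_id + seq_along(cur_idx) - 1L
      next_id <- next_id + length(cur_idx)
      prev_idx <- cur_idx
      next
    }
    na <- length(prev_idx); nb <- length(cur_idx)
    d2 <- outer(spots$x_um[prev_idx], spots$x_um[cur_idx], "-")^2 +
          outer(spots$y_um[prev_idx], spots$y_um[cur_idx], "-")^2
    cost <- ifelse(d2 <= max_disp^2, d2, BIG)
    linked_cur <- rep(FALSE, nb)
    if (na <= nb) {
      a <- solve_assignment(cost)
      for (i in seq_len(na)) {
        j <- a[i]
        if (!is.na(j) && cost[i, j] < BIG) {
          spots$track_id[cur_idx[j]] <- spots$track_id[prev_idx[i]]
          linked_cur[j] <- TRUE
        }
      }
    } else {
      a <- solve_assignment(t(cost))
      for (j in seq_len(nb)) {
        i <- a[j]
        if (!is.na(i) && cost[i, j] < BIG) {
          spots$track_id[cur_idx[j]] <- spots$track_id[prev_idx[i]]
          linked_cur[j] <- TRUE
        }
      }
    }
    new_cur <- cur_idx[!linked_cur]
    if (length(new_cur) > 0) {
      spots$track_id[new_cur] <- next_id + seq_along(new_cur) - 1L
      next_id <- next_id + length(new_cur)
    }
    prev_idx <- cur_idx
  }
  len <- table(spots$track_id)
  keep_ids <- as.integer(names(len)[len >= min_length])
  out <- spots[spots$track_id %in% keep_ids, , drop = FALSE]
  # renumber consecutively in order of first appearance
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out[, c("track_id", setdiff(names(out), "track_id"))]
}

#' Assign localizations to cells
#'
#' Labels every localization with the id of the mesh polygon containing
#' it; localizations outside all meshes get `cell_id = NA` and are
#' excluded from per-cell statistics downstream. Overlapping meshes are
#' an error.
#'
#' @param tracks track table with `x_um`, `y_um`.
#' @param meshes mesh set (see [cell-mesh]).
#' @return `tracks` with a (re)computed `cell_id` column.
#' @export
assign_cells <- function(tracks, meshes) {
  pts <- cbind(tracks$x_um, tracks$y_um)
  cell_id <- rep(NA_integer_, nrow(tracks))
  hits <- integer(nrow(tracks))
  for (cid in mesh_cell_ids(meshes)) {
    poly <- mesh_polygon(meshes, cid)
    bb <- pts[, 1] >= min(poly[, 1]) & pts[, 1] <= max(poly[, 1]) &
          pts[, 2] >= min(poly[, 2]) & pts[, 2] <= max(poly[, 2])
    if (!any(bb)) next
    inside <- which(bb)[points_in_polygon(pts[bb, , drop = FALSE], poly)]
    clash <- inside[!is.na(cell_id[inside])]
    if (length(clash) > 0)
      stop("overlapping meshes: cells ", unique(cell_id[clash])[1], " and ",
           cid, " both contain localizations")
    cell_id[inside] <- cid
    hits[inside] <- hits[inside] + 1L
  }
  tracks$cell_id <- cell_id
  tracks
}

#' Fraction of cells without any detected track
#'
#' Mirrors the reporting of the share of cells that contain no
#' fluorescence signal at all; the complementary percentage of cells with
#' signal is attached as an attribute.
#'
#' @param tracks cell-assigned track table.
#' @param meshes mesh set.
#' @return fraction of cells with zero assigned tracks, with attribute
#'   `percent_with_signal`.
#' @export
fraction_empty_cells <- function(tracks, meshes) {
  ids <- mesh_cell_ids(meshes)
  if (length(ids) == 0L) stop("mesh set contains no cells")
  occupied <- unique(tracks$cell_id[!is.na(tracks$cell_id)])
  frac <- sum(!(ids %in% occupied)) / length(ids)
  structure(frac, percent_with_signal = 100 * (1 - frac))
}
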