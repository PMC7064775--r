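#' @title Dwell times and standardized-cell spatial maps
#' @description
#' A dwell event is a maximal run of consecutive localizations that stays
#' within a fixed radius (default 230 nm = 2.3 pixels) of the run's
#' anchor; its duration is `(n - 1) * tau`. Because the assay ends when
#' the fluorophore bleaches, detected dwell times systematically
#' underestimate the true binding lifetimes. For population maps, every
#' localization is projected through its cell mesh into a standardized
#' 3 x 1 um cell (long-axis and transverse fractions, signs preserved —
#' no axis mirroring).
#' @name dwell-spatial
NULL

#' Detect confinement (dwell) events in one track
#'
#' Scans the track for maximal runs of consecutive localizations all
#' within `radius` of the run's anchor. By default the anchor is the
#' first point of the run (deterministic); `rule = "centroid"` uses the
#' running centroid of the accumulating run instead, for sensitivity
#' analysis. Runs of at least 2 localizations are emitted and the scan
#' resumes after each event, so events within a track never share frames.
#'
#' @param track one gap-free track (`frame`, `x_um`, `y_um`) in um.
#' @param radius confinement radius, um.
#' @param tau frame interval, s.
#' @param rule `"anchor"` (default) or `"centroid"`.
#' @return data frame of events: `start_frame`, `n_loc`, `duration_s`,
#'   `anchor_x`, `anchor_y`. Zero rows if the track never dwells.
#' @examples
#' tr <- data.frame(frame = 1:10, x_um = 0, y_um = 0)
#' detect_confinement_events(tr, tau = 0.015)  # one event, 0.135 s
#' @export
detect_confinement_events <- function(track, radius = 0.230, tau,
                                      rule = c("anchor", "centroid")) {
  if (radius <= 0) stop("radius must be positive")
  rule <- match.arg(rule)
  track <- track[order(track$frame), , drop = FALSE]
  x <- track$x_um; y <- track$y_um; fr <- track$frame
  n <- length(x)
  ev <- list()
  i <- 1L
  while (i <= n) {
    ax <- x[i]; ay <- y[i]
    j <- i
    while (j + 1L <= n &&
           sqrt((x[j + 1L] - ax)^2 + (y[j + 1L] - ay)^2) <= radius) {
      j <- j + 1L
      if (rule == "centroid") {
        ax <- mean(x[i:j]); ay <- mean(y[i:j])
      }
    }
    if (j > i) {
      ev[[length(ev) + 1L]] <- data.frame(
        start_frame = fr[i], n_loc = j - i + 1L,
        duration_s = (j - i) * tau,
        anchor_x = if (rule == "anchor") x[i] else ax,
        anchor_y = if (rule == "anchor") y[i] else ay)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(start_frame = integer(), n_loc = integer(),
                      duration_s = numeric(), anchor_x = numeric(),
                      anchor_y = numeric())
  out
}

#' Dwell events for a whole track table
#'
#' Optionally restricts the analysis to slow (static-like) tracks first,
#' mirroring the convention of reporting dwell times of static
#' molecules: mobile molecules bouncing inside the narrow cell generate
#' chance confinement events that would otherwise dilute the statistic.
#'
#' @param tracks track table.
#' @inheritParams detect_confinement_events
#' @param filter `NULL`, or a list with `dmax` (um^2/s) and `r2min`
#'   applied to per-track MSD fits before event detection.
#' @return events data frame with a leading `track_id` column.
#' @export
dwell_events <- function(tracks, radius = 0.230, tau,
                         rule = c("anchor", "centroid"), filter = NULL) {
  rule <- match.arg(rule)
  if (!is.null(filter)) {
    msd <- track_msd_table(tracks, tau)
    keep <- msd$track_id[msd$D_app < filter$dmax &
                         !is.na(msd$r2) & msd$r2 > filter$r2min]
    tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  }
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    e <- detect_confinement_events(tracks[tracks$track_id == id, ],
                                   radius, tau, rule)
    if (nrow(e) > 0) cbind(track_id = id, e)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(data.frame(track_id = integer()),
                 detect_confinement_events(
                   data.frame(frame = integer(), x_um = numeric(),
                              y_um = numeric()), radius, tau))
  out
}

#' Mean dwell time with between-replicate SD
#'
#' The per-replicate statistic is the mean event duration; the reported
#' uncertainty is the SD of that mean across (typically three) replicate
#' datasets.
#'
#' @param events a single events data frame (one replicate) or a list of
#'   them.
#' @return list: `mean_s`, `sd_s` (NA for a single replicate),
#'   `replicate_means`, `n_events`.
#' @export
mean_dwell_time <- function(events) {
  if (is.data.frame(events)) events <- list(events)
  n_ev <- vapply(events, nrow, 1L)
  if (all(n_ev == 0)) stop("no dwell events: mean dwell time undefined")
  means <- vapply(events, function(e)
    if (nrow(e) > 0) mean(e$duration_s) else NA_real_, 1)
  list(mean_s = mean(means, na.rm = TRUE),
       sd_s = if (length(means) > 1) stats::sd(means, na.rm = TRUE)
              else NA_real_,
       replicate_means = means, n_events = n_ev)
}

#' Project a localization into the standardized cell
#'
#' Expresses positions in cell coordinates: the fraction along the
#' pole-to-pole axis (pole 1 at 0) times the standard length, and the
#' fraction across the local transverse chord of the mesh polygon times
#' the standard width. Pole order is taken from the mesh as given, so
#' orientation is preserved (no mirroring).
#'
#' @param points matrix or data frame of positions (`x_um`, `y_um`).
#' @param mesh a single-cell mesh or a mesh set with `cell` given.
#' @param cell cell id when `mesh` is a mesh set.
#' @param std_dims standardized cell dimensions (length, width), um.
#' @param strict error on points outside the mesh (default); otherwise
#'   they yield NA coordinates.
#' @return data frame `x_norm`, `y_norm` in um within the standard cell.
#' @export
normalize_to_standard_cell <- function(points, mesh, cell = NULL,
                                       std_dims = c(3, 1), strict = TRUE) {
  if (is.data.frame(points)) points <- cbind(points$x_um, points$y_um)
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  if (!is.null(cell)) {
    poles <- mesh_poles(mesh)
    poles <- poles[poles$cell_id == cell, ]
    poly <- mesh_polygon(mesh, cell)
  } else {
    poles <- mesh_poles(mesh)
    poly <- mesh_polygon(mesh, poles$cell_id[1])
  }
  p1 <- c(poles$x_um[poles$pole == 1], poles$y_um[poles$pole == 1])
  p2 <- c(poles$x_um[poles$pole == 2], poles$y_um[poles$pole == 2])
  u <- p2 - p1
  u <- u / sqrt(sum(u^2))
  nv <- c(-u[2], u[1])
  vl <- (poly[, 1] - p1[1]) * u[1] + (poly[, 2] - p1[2]) * u[2]
  l_min <- min(vl); l_max <- max(vl)
  inside <- points_in_polygon(points, poly)
  if (strict && !all(inside))
    stop(sum(!inside), " localization(s) outside the mesh")
  edges <- cbind(poly, rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]))
  out <- matrix(NA_real_, nrow(points), 2)
  for (k in which(inside)) {
    q <- points[k, ]
    l <- (q[1] - p1[1]) * u[1] + (q[2] - p1[2]) * u[2]
    t_q <- (q[1] - p1[1]) * nv[1] + (q[2] - p1[2]) * nv[2]
    s0 <- p1 + l * u
    # intersect the transverse line s0 + t*nv with every polygon edge
    ts <- numeric(0)
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1:2]; b <- edges[e, 3:4]
      d <- b - a
      den <- nv[1] * (-d[2]) - nv[2] * (-d[1])
      if (abs(den) < 1e-12) next
      rhs <- a - s0
      t <- (rhs[1] * (-d[2]) - rhs[2] * (-d[1])) / den
      s <- (nv[1] * rhs[2] - nv[2] * rhs[1]) / den
      if (s >= 0 && s < 1) ts <- c(ts, t)
    }
    lo <- ts[ts <= t_q + 1e-12]
    hi <- ts[ts >= t_q - 1e-12]
    xn <- (l - l_min) / (l_max - l_min) * std_dims[1]
    yn <- if (length(lo) == 0 || length(hi) == 0) {
      std_dims[2] / 2
    } else {
      t_lo <- max(lo); t_hi <- min(hi)
      if (t_hi - t_lo < 1e-9) std_dims[2] / 2
      else (t_q - t_lo) / (t_hi - t_lo) * std_dims[2]
    }
    out[k, ] <- c(min(std_dims[1], max(0, xn)),
                  min(std_dims[2], max(0, yn)))
  }
  data.frame(x_norm = out[, 1], y_norm = out[, 2])
}

#' Build a standardized-cell heat map
#'
#' Projects all (optionally slow-track-filtered) localizations into the
#' standard cell and bins them on a regular grid (default 60 x 20 bins of
#' 50 nm). The slow-track filter keeps tracks with apparent diffusion
#' `D_app < dmax` and MSD-fit `R^2 > r2min`, the criterion used for
#' spatial maps of the static subpopulation. Localizations without a cell
#' assignment, or falling outside their mesh, are dropped.
#'
#' @param tracks cell-assigned track table.
#' @param meshes mesh set.
#' @param tau frame interval, s (needed when `filter` is enabled).
#' @param filter `NULL`, or a list with `dmax` (um^2/s) and `r2min`.
#' @param bins integer length-2: bins along length and width.
#' @param std_dims standardized cell size (um).
#' @param normalize scale the map to sum to 1.
#' @return matrix of class `smt_heatmap` (`bins[2]` rows x `bins[1]`
#'   columns; columns run pole 1 -> pole 2), with attributes `n_loc`,
#'   `n_tracks`, `empty` and the binning geometry.
#' @export
build_heatmap <- function(tracks, meshes, tau = NULL,
                          filter = list(dmax = 0.5, r2min = 0.7),
                          bins = c(60L, 20L), std_dims = c(3, 1),
                          normalize = TRUE) {
  if (!is.null(filter)) {
    if (is.null(tau)) stop("tau is required for the slow-track filter")
    msd <- track_msd_table(tracks, tau)
    keep_ids <- msd$track_id[msd$D_app < filter$dmax &
                             !is.na(msd$r2) & msd$r2 > filter$r2min]
    tracks <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  }
  tracks <- tracks[!is.na(tracks$cell_id), , drop = FALSE]
  H <- matrix(0, bins[2], bins[1])
  n_loc <- 0L
  for (cid in intersect(mesh_cell_ids(meshes), unique(tracks$cell_id))) {
    tr <- tracks[tracks$cell_id == cid, , drop = FALSE]
    poly <- mesh_polygon(meshes, cid)
    ok <- points_in_polygon(cbind(tr$x_um, tr$y_um), poly)
    if (!any(ok)) next
    nz <- normalize_to_standard_cell(tr[ok, , drop = FALSE], meshes,
                                     cell = cid, std_dims = std_dims)
    bx <- pmin(bins[1], pmax(1, ceiling(nz$x_norm / std_dims[1] * bins[1])))
    by <- pmin(bins[2], pmax(1, ceiling(nz$y_norm / std_dims[2] * bins[2])))
    for (k in seq_along(bx)) H[by[k], bx[k]] <- H[by[k], bx[k]] + 1
    n_loc <- n_loc + length(bx)
  }
  empty <- sum(H) == 0
  if (empty) warning("empty heat map after filtering")
  if (normalize && !empty) H <- H / sum(H)
  structure(H, class = c("smt_heatmap", "matrix"),
            n_loc = n_loc, n_tracks = length(unique(tracks$track_id)),
            empty = empty, bins = bins, std_dims = std_dims,
            normalized = normalize && !empty)
}

#' Equalize heat maps across datasets
#'
#' Rescales a list of (count) maps so that all totals equal the mean
#' total, making intensities comparable across conditions.
#'
#' @param maps list of `smt_heatmap` matrices.
#' @return list of rescaled maps.
#' @export
equalize_heatmaps <- function(maps) {
  tot <- vapply(maps, sum, 1)
  target <- mean(tot)
  lapply(maps, function(m) {
    out <- m * (target / sum(m))
    attributes(out) <- attributes(m)
    out
  })
}

#' @export
print.smt_heatmap <- function(x, ...) {
  b <- attr(x, "bins")
  cat(sprintf("smt_heatmap: %d x %d bins, %d localizations, %s\n",
              b[1], b[2], attr(x, "n_loc"),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "counts"))
  invisible(x)
}

#' @export
plot.smt_heatmap <- function(x, main = "standardized-cell density", ...) {
  sd_ <- attr(x, "std_dims")
  graphics::image(
    x = seq(0, sd_[1], length.out = ncol(x) + 1),
    y = seq(0, sd_[2], length.out = nrow(x) + 1),
    z = t(unclass(x)), xlab = "long axis (um)", ylab = "width (um)",
    main = main, asp = 1, useRaster = TRUE, ...)
  invisible(x)
}

#' Write a heat map as a CSV matrix
#' @param map `smt_heatmap`.
#' @param path CSV path.
#' @export
write_heatmap_csv <- function(map, path) {
  utils::write.table(unclass(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
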