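#' @title Synthetic two-state tracking data with known ground truth
#' @description
#' The generator produces everything the downstream analyses consume —
#' movies, cell meshes and track tables — from a molecular model with
#' known parameters: molecules switch between a receptor-bound static
#' state (slow diffusion tethered to an anchor) and a mobile state, bleach
#' in a single step, and are rendered as vignetted Gaussian PSFs on a
#' camera with offset, read noise, diffuse background and cell
#' autofluorescence. Every stage of the pipeline can then be checked by
#' parameter recovery.
#' @name synthetic-data
NULL

# ---- state kinetics ---------------------------------------------------------

#' Simulate two-state (static/mobile) state sequences
#'
#' Stationary two-state Markov chain per molecule: the unbinding
#' probability per frame is `1 - exp(-tau / mean_bound_dwell)` and the
#' binding probability is chosen so that the stationary probability of the
#' static state equals `f_static`. `f_static` of 0 or 1 yields the
#' degenerate all-mobile / all-static chain.
#'
#' @param config a [sim_config()].
#' @param n_frames integer vector: chain length per molecule.
#' @return list of integer vectors, 1 = static, 2 = mobile.
#' @export
simulate_state_sequences <- function(config, n_frames) {
  f <- config$f_static
  p_off <- 1 - exp(-config$tau / config$mean_bound_dwell)
  if (f >= 1) {
    p_off <- 0; p_on <- 1
  } else if (f <= 0) {
    p_on <- 0
  } else {
    p_on <- f * p_off / (1 - f)
    if (p_on > 1)
      stop("degenerate chain: f_static = ", f, " cannot be stationary with ",
           "mean_bound_dwell = ", config$mean_bound_dwell,
           " s at tau = ", config$tau, " s")
  }
  lapply(n_frames, function(n) {
    s <- integer(n)
    s[1] <- if (stats::runif(1) < f) 1L else 2L
    if (n > 1) {
      u <- stats::runif(n - 1)
      for (t in 2:n) {
        s[t] <- if (s[t - 1] == 1L) {
          if (u[t - 1] < p_off) 2L else 1L
        } else {
          if (u[t - 1] < p_on) 1L else 2L
        }
      }
    }
    s
  })
}

# ---- cell-local geometry helpers -------------------------------------------

# inside test for the projected spherocylinder, cell-local coordinates
in_spherocyl <- function(x, y, L, W) {
  R <- W / 2; hl <- L / 2 - R
  (abs(x) <= hl & abs(y) <= R) |
    ((abs(x) - hl)^2 + y^2 <= R^2 & abs(x) > hl)
}

reflect_spherocyl <- function(x, y, L, W) {
  R <- W / 2; hl <- L / 2 - R
  for (i in 1:25) {
    if (abs(x) <= hl) {
      if (abs(y) <= R) return(c(x, y))
      y <- sign(y) * (2 * R - abs(y))
    } else {
      cx <- sign(x) * hl
      dx <- x - cx
      r <- sqrt(dx^2 + y^2)
      if (r <= R) return(c(x, y))
      r2 <- 2 * R - r
      if (r2 < 0) r2 <- 0.5 * R   # very large step: drop near cap center
      s <- r2 / r
      x <- cx + dx * s; y <- y * s
    }
  }
  # fall back: clamp to center line
  c(max(-hl, min(hl, x)), 0)
}

reflect_disc <- function(x, y, cx, cy, r_max) {
  for (i in 1:25) {
    dx <- x - cx; dy <- y - cy
    r <- sqrt(dx^2 + dy^2)
    if (r <= r_max) return(c(x, y))
    r2 <- 2 * r_max - r
    if (r2 < 0) r2 <- 0.5 * r_max
    s <- r2 / r
    x <- cx + dx * s; y <- cy + dy * s
  }
  c(cx, cy)
}

runif_spherocyl <- function(L, W) {
  R <- W / 2
  repeat {
    x <- stats::runif(1, -L / 2, L / 2)
    y <- stats::runif(1, -R, R)
    if (in_spherocyl(x, y, L, W)) return(c(x, y))
  }
}

# anchor draw: polar cap with probability polar_bias, else uniform
draw_anchor <- function(L, W, polar_bias) {
  R <- W / 2; hl <- L / 2 - R
  if (stats::runif(1) < polar_bias) {
    side <- if (stats::runif(1) < 0.5) -1 else 1
    repeat {
      x <- stats::runif(1, hl, hl + R) * side
      y <- stats::runif(1, -R, R)
      if (in_spherocyl(x, y, L, W)) return(c(x, y))
    }
  } else {
    runif_spherocyl(L, W)
  }
}

# ---- positions --------------------------------------------------------------

#' Simulate molecule positions given state sequences
#'
#' Mobile frames take Gaussian per-axis increments with variance
#' `2 * D_mobile * tau`; static frames take increments with variance
#' `2 * D_static * tau`, reflected inside a disc of radius
#' `anchor_radius` around the anchor of the current bound episode. All
#' positions are reflected at the projected spherocylinder boundary.
#' Anchors of episodes that start the trajectory are placed in a polar cap
#' with probability `polar_bias`; re-binding after a mobile episode
#' anchors at the current position. In `compartment = "membrane"` mode the
#' walk lives on the unrolled cylinder surface (axial, circumferential)
#' and the circumferential coordinate is projected to the focal plane.
#'
#' @param config a [sim_config()].
#' @param states list of state vectors from [simulate_state_sequences()].
#' @param cell_lengths optional per-molecule cell length (um); defaults to
#'   `config$cell_length` for all molecules.
#' @return list of n x 2 matrices of cell-local positions (um).
#' @export
simulate_positions <- function(config, states, cell_lengths = NULL) {
  if (config$D_static < 0 || config$D_mobile < 0)
    stop("diffusion coefficients must be non-negative")
  sd_s <- sqrt(2 * config$D_static * config$tau)
  sd_m <- sqrt(2 * config$D_mobile * config$tau)
  W <- config$cell_width
  R <- W / 2
  if (is.null(cell_lengths))
    cell_lengths <- rep(config$cell_length, length(states))
  membrane <- config$compartment == "membrane"
  lapply(seq_along(states), function(mi) {
    st <- states[[mi]]
    L <- cell_lengths[mi]
    hl <- L / 2 - R
    n <- length(st)
    pos <- matrix(0, n, 2)
    if (membrane) {
      # coordinates: (l axial, s circumferential arc length)
      if (st[1] == 1L) {
        polar <- stats::runif(1) < config$polar_bias
        l0 <- if (polar) sign(stats::runif(1) - 0.5) *
            stats::runif(1, hl - R, hl) else stats::runif(1, -hl, hl)
        anchor <- c(l0, stats::runif(1, 0, 2 * pi * R))
        cur <- anchor
      } else {
        cur <- c(stats::runif(1, -hl, hl), stats::runif(1, 0, 2 * pi * R))
        anchor <- cur
      }
      pos[1, ] <- cur
      if (n > 1) for (t in 2:n) {
        sdt <- if (st[t] == 1L) sd_s else sd_m
        if (st[t] == 1L && st[t - 1] == 2L) anchor <- cur
        cur <- cur + stats::rnorm(2, 0, sdt)
        if (st[t] == 1L)
          cur <- reflect_disc(cur[1], cur[2], anchor[1], anchor[2],
                              config$anchor_radius)
        # axial reflection, circumferential wrap
        if (abs(cur[1]) > hl) cur[1] <- sign(cur[1]) * (2 * hl - abs(cur[1]))
        cur[1] <- max(-hl, min(hl, cur[1]))
        pos[t, ] <- cur
      }
      cbind(pos[, 1], R * sin(pos[, 2] / R))
    } else {
      if (st[1] == 1L) {
        anchor <- draw_anchor(L, W, config$polar_bias)
        cur <- anchor
      } else {
        cur <- runif_spherocyl(L, W)
        anchor <- cur
      }
      pos[1, ] <- cur
      if (n > 1) for (t in 2:n) {
        sdt <- if (st[t] == 1L) sd_s else sd_m
        if (st[t] == 1L && st[t - 1] == 2L) anchor <- cur
        cur <- cur + stats::rnorm(2, 0, sdt)
        if (st[t] == 1L)
          cur <- reflect_disc(cur[1], cur[2], anchor[1], anchor[2],
                              config$anchor_radius)
        cur <- reflect_spherocyl(cur[1], cur[2], L, W)
        pos[t, ] <- cur
      }
      pos
    }
  })
}

# ---- experiment assembly ----------------------------------------------------

# deterministic cell-grid geometry shared by sample, blank and label-free
# movies (fields must have identical pixel dimensions for the corrections)
grid_geometry <- function(config) {
  n <- max(1L, config$n_cells)
  box_w <- config$cell_length + 3 * config$cell_length_sd + 1.2
  box_h <- config$cell_width + 1.2
  ncol <- max(1L, ceiling(sqrt(n * box_h / box_w)))
  nrow <- ceiling(n / ncol)
  list(box_w = box_w, box_h = box_h, ncol = ncol, nrow = nrow,
       field_um = c(ncol * box_w + 1.2, nrow * box_h + 1.2))
}

# grid layout of cells; returns meshes plus per-cell placement
layout_cells <- function(config, angle_jitter = 0.25) {
  n <- config$n_cells
  g <- grid_geometry(config)
  box_w <- g$box_w; box_h <- g$box_h
  ncol <- g$ncol; nrow <- g$nrow
  lengths <- pmin(config$cell_length + 3 * config$cell_length_sd,
                  pmax(config$cell_width + 0.4,
                       stats::rnorm(n, config$cell_length,
                                    config$cell_length_sd)))
  angles <- stats::runif(n, -angle_jitter, angle_jitter)
  centers <- cbind(
    ((seq_len(n) - 1) %% ncol + 0.5) * box_w + 0.6,
    ((seq_len(n) - 1) %/% ncol + 0.5) * box_h + 0.6)
  field_um <- g$field_um
  meshes <- mesh_set(lapply(seq_len(n), function(i)
    make_cell_mesh(centers[i, ], lengths[i], config$cell_width,
                   angles[i], cell_id = i)))
  list(meshes = meshes, centers = centers, angles = angles,
       lengths = lengths, field_um = field_um)
}

# molecule inventory. Per-cell counts are fluorophores; a fraction of the
# emitting units are dimers (two fluorophores diffusing and bleaching as
# one unit), chosen so that among bleaching units the dimer share equals
# dimer_fraction and monomers + 2*dimers equals the fluorophore count.
draw_molecules <- function(config) {
  n_cells <- config$n_cells
  counts <- if (!is.null(config$molecules_per_cell)) {
    config$molecules_per_cell
  } else {
    occupied <- stats::runif(n_cells) >= config$p_empty
    as.integer(occupied) * stats::rpois(n_cells, config$molecules_per_cell_mean)
  }
  p_pair <- min(1, 2 * config$dimer_fraction / (1 + config$dimer_fraction))
  units <- lapply(seq_len(n_cells), function(cid) {
    n <- counts[cid]
    if (n == 0L) return(logical(0))
    d <- stats::rbinom(1L, n %/% 2L, p_pair)
    c(rep(TRUE, d), rep(FALSE, n - 2L * d))
  })
  dimer <- unlist(units)
  n_mol <- length(dimer)
  p_bleach <- 1 - exp(-config$bleach_rate * config$tau)
  frames_alive <- if (p_bleach > 0)
    stats::rgeom(n_mol, p_bleach) + 1L
  else
    rep(config$n_frames - config$laser_on_frame + 1L, n_mol)
  frames_avail <- config$n_frames - config$laser_on_frame + 1L
  frames_alive <- pmin(frames_alive, frames_avail)
  data.frame(
    molecule_id = seq_len(n_mol),
    cell_id = rep(seq_len(n_cells), vapply(units, length, 1L)),
    dimer = dimer,
    frames_alive = frames_alive)
}

#' Run the full synthetic experiment
#'
#' Draws the molecule inventory (per-cell counts, dimer labels, bleaching
#' times), simulates state sequences and positions, lays the cells out in
#' a field of view, and (optionally) renders the camera movie. All
#' randomness derives from `config$seed`; the same seed reproduces the
#' output bit-identically.
#'
#' @param config a [sim_config()].
#' @param render logical, render the pixel movie (skip for track-level
#'   studies).
#' @return list with elements `movie` (or `NULL`), `meshes`, `tracks`
#'   (ground-truth tracks with localization error, see [emit_tracks()]),
#'   and `truth` (list: `molecules`, `states`, `positions` in global um
#'   coordinates, `bg_level`, `config`).
#' @export
simulate_experiment <- function(config, render = TRUE) {
  set.seed(config$seed)
  lay <- layout_cells(config)
  mols <- draw_molecules(config)
  states <- simulate_state_sequences(config, mols$frames_alive)
  # simulate a hair inside the outline so every true position also lies
  # inside the polygonal (chord-inscribed) mesh approximation
  inset <- 0.012
  cfg_pos <- config
  cfg_pos$cell_width <- config$cell_width - inset
  pos_local <- simulate_positions(cfg_pos, states,
                                  cell_lengths =
                                    lay$lengths[mols$cell_id] - inset)
  # transform to global coordinates of each molecule's cell
  pos_global <- lapply(seq_len(nrow(mols)), function(m) {
    cid <- mols$cell_id[m]
    a <- lay$angles[cid]
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    p <- pos_local[[m]] %*% t(rot)
    cbind(p[, 1] + lay$centers[cid, 1], p[, 2] + lay$centers[cid, 2])
  })
  truth <- list(molecules = mols, states = states, positions = pos_global,
                config = config)
  tracks <- emit_tracks(truth)
  movie <- if (render) render_movie(config, truth, lay) else NULL
  list(movie = movie, meshes = lay$meshes, tracks = tracks, truth = truth,
       layout = lay)
}

#' Emit ideal ground-truth tracks
#'
#' One trajectory per molecule from first illuminated frame to the frame
#' before its bleaching step, bypassing detection, with configurable
#' Gaussian localization error per axis.
#'
#' @param truth ground-truth list from [simulate_experiment()].
#' @param localization_error per-axis localization error (um); defaults to
#'   the generator config value.
#' @return a `TrackTable` data frame: `track_id`, `frame` (1-based),
#'   `x_um`, `y_um`, `cell_id`.
#' @export
emit_tracks <- function(truth, localization_error = NULL) {
  cfg <- truth$config
  eps <- if (is.null(localization_error)) cfg$localization_error else
    localization_error
  mols <- truth$molecules
  rows <- lapply(seq_len(nrow(mols)), function(m) {
    n <- mols$frames_alive[m]
    if (n < 1L) return(NULL)
    p <- truth$positions[[m]]
    data.frame(track_id = mols$molecule_id[m],
               frame = cfg$laser_on_frame + seq_len(n) - 1L,
               x_um = p[, 1], y_um = p[, 2],
               cell_id = mols$cell_id[m])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      cell_id = integer())
  if (!is.null(out) && nrow(out) > 0 && eps > 0) {
    out$x_um <- out$x_um + stats::rnorm(nrow(out), 0, eps)
    out$y_um <- out$y_um + stats::rnorm(nrow(out), 0, eps)
  }
  rownames(out) <- NULL
  out
}

#' Draw jump distances directly from the two-state mixture
#'
#' Samples frame-to-frame jump distances from the jump-distance mixture
#' density \eqn{p(r) = \sum_k w_k \, r/(2 D_k \tau) \exp(-r^2/(4 D_k \tau))},
#' i.e. the magnitude law of a zero-mean Gaussian displacement process
#' with per-axis variance `2 * D_k * tau (+ 2 * eps^2)`. Used to verify
#' the mixture fit by parameter recovery without track-level artefacts.
#'
#' @param n number of jumps.
#' @param weights mixture weights (summing to 1).
#' @param D diffusion coefficients, um^2/s, same length as `weights`.
#' @param tau frame interval, s.
#' @param eps per-axis localization error, um.
#' @return numeric vector of jump distances (um) with a `component`
#'   attribute holding the true component labels.
#' @export
simulate_jump_sample <- function(n, weights, D, tau, eps = 0) {
  stopifnot(length(weights) == length(D), abs(sum(weights) - 1) < 1e-8)
  comp <- sample.int(length(D), n, replace = TRUE, prob = weights)
  sigma <- sqrt(2 * D[comp] * tau + 2 * eps^2)
  r <- sqrt(stats::rnorm(n, 0, sigma)^2 + stats::rnorm(n, 0, sigma)^2)
  attr(r, "component") <- comp
  r
}
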