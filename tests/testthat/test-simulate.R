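test_that("two-state chain reaches the requested stationary occupancy", {
  cfg <- sim_config(f_static = 0.7, mean_bound_dwell = 0.05, seed = 1)
  set.seed(1)
  st <- simulate_state_sequences(cfg, 1e5)[[1]]
  expect_equal(mean(st == 1L), 0.7, tolerance = 0.015)
  # absorbing edge cases
  cfg1 <- sim_config(f_static = 1, seed = 1)
  set.seed(1)
  expect_true(all(simulate_state_sequences(cfg1, 500)[[1]] == 1L))
  cfg0 <- sim_config(f_static = 0, seed = 1)
  set.seed(1)
  expect_true(all(simulate_state_sequences(cfg0, 500)[[1]] == 2L))
})

test_that("unattainable stationarity raises a degenerate-chain error", {
  cfg <- sim_config(f_static = 0.99, mean_bound_dwell = 0.015, seed = 1)
  expect_error(simulate_state_sequences(cfg, 10), "degenerate")
})

test_that("per-axis step variance equals 2*D*tau in free diffusion", {
  # huge cell and tether so neither boundary nor anchor constrains steps
  cfg <- sim_config(D_static = 0.5, D_mobile = 0.5, cell_length = 100,
                    cell_width = 50, anchor_radius = 1e6, seed = 2)
  set.seed(2)
  p <- simulate_positions(cfg, list(rep(2L, 1e5)))[[1]]
  expect_equal(var(diff(p[, 1])), 2 * 0.5 * cfg$tau, tolerance = 0.02)
  expect_equal(var(diff(p[, 2])), 2 * 0.5 * cfg$tau, tolerance = 0.02)
  # D = 0 gives exactly zero displacements
  cfg0 <- sim_config(D_static = 0, D_mobile = 0, f_static = 1,
                     mean_bound_dwell = 1, seed = 2)
  set.seed(3)
  p0 <- simulate_positions(cfg0, list(rep(1L, 100)))[[1]]
  expect_true(all(diff(p0[, 1]) == 0) && all(diff(p0[, 2]) == 0))
  cfg_bad <- cfg
  cfg_bad$D_mobile <- -1
  expect_error(simulate_positions(cfg_bad, list(rep(2L, 10))),
               "non-negative")
})

test_that("positions stay inside the spherocylinder", {
  cfg <- sim_config(n_cells = 5, n_frames = 220, seed = 4)
  ex <- simulate_experiment(cfg, render = FALSE)
  tr <- ex$tracks
  # noiseless ground-truth positions must fall inside their cell mesh
  for (m in seq_len(nrow(ex$truth$molecules))) {
    cid <- ex$truth$molecules$cell_id[m]
    poly <- smtquant:::mesh_polygon(ex$meshes, cid)
    inside <- smtquant:::points_in_polygon(ex$truth$positions[[m]], poly)
    expect_true(all(inside))
  }
})

test_that("localization error adds 2*eps^2 to per-axis step variance", {
  cfg <- sim_config(D_static = 0.2, D_mobile = 0.2, cell_length = 100,
                    cell_width = 50, anchor_radius = 1e6,
                    bleach_rate = 0, n_cells = 1, n_frames = 50020,
                    molecules_per_cell = 1, f_static = 0, seed = 5)
  ex <- simulate_experiment(cfg, render = FALSE)
  eps <- 0.02
  set.seed(6)
  noisy <- emit_tracks(ex$truth, localization_error = eps)
  v <- var(diff(noisy$x_um))
  expect_equal(v, 2 * 0.2 * cfg$tau + 2 * eps^2, tolerance = 0.03)
})

test_that("track lengths are geometric with mean 1/(bleach_rate*tau)", {
  cfg <- sim_config(n_cells = 60, n_frames = 2020, bleach_rate = 3,
                    molecules_per_cell_mean = 8, p_empty = 0, seed = 7)
  ex <- simulate_experiment(cfg, render = FALSE)
  len <- table(ex$tracks$track_id)
  p <- 1 - exp(-cfg$bleach_rate * cfg$tau)
  expect_equal(mean(len), 1 / p, tolerance = 0.1)
})

test_that("movie photon bookkeeping matches ground truth with noise off", {
  cfg <- sim_config(n_cells = 2, n_frames = 30, molecules_per_cell = 1,
                    p_empty = 0, dimer_fraction = 0, bleach_rate = 0,
                    shot_noise = FALSE, read_noise = 0, bg_level = 0,
                    bg_level_sd = 0, autofluorescence_coeffs = c(0, 0, 0),
                    f_static = 1, D_static = 0, localization_error = 0,
                    seed = 8)
  ex <- simulate_experiment(cfg, render = TRUE)
  fr <- ex$movie$pixels[, , 25] - cfg$offset_level
  d <- dim(ex$movie$pixels)
  V <- smtquant:::vignette_matrix(d[2], d[1], cfg$pixel_size,
                                  cfg$vignette_sigma, NULL)
  expected <- sum(vapply(seq_len(nrow(ex$truth$molecules)), function(m) {
    p <- ex$truth$positions[[m]][1, ]
    j <- floor(p[1] / cfg$pixel_size) + 1
    i <- floor(p[2] / cfg$pixel_size) + 1
    cfg$unitary_photons * V[i, j]
  }, 1))
  expect_equal(sum(fr), expected, tolerance = 0.005)
})

test_that("zero molecules and zero autofluorescence leave offset x vignette", {
  cfg <- sim_config(n_cells = 2, molecules_per_cell = 0, n_frames = 25,
                    shot_noise = FALSE, read_noise = 0, bg_level = 40,
                    bg_level_sd = 0, autofluorescence_coeffs = c(0, 0, 0),
                    seed = 9)
  ex <- simulate_experiment(cfg, render = TRUE)
  d <- dim(ex$movie$pixels)
  V <- smtquant:::vignette_matrix(d[2], d[1], cfg$pixel_size,
                                  cfg$vignette_sigma, NULL)
  # outside-cell pixels: offset + bg * vignette, exactly
  post <- ex$movie$pixels[, , 25]
  mask <- matrix(TRUE, d[1], d[2])
  for (cid in 1:2) {
    px <- smtquant:::polygon_pixel_mask(
      smtquant:::mesh_polygon(ex$meshes, cid), d[2], d[1], cfg$pixel_size)
    mask[px] <- FALSE
  }
  expect_equal(post[mask], (cfg$offset_level + 40 * V)[mask],
               tolerance = 1e-12)
  # pre-laser frames contain offset only
  expect_true(all(ex$movie$pixels[, , 1:20] == cfg$offset_level))
})

test_that("rendering requires illuminated frames", {
  cfg <- sim_config(n_cells = 1, n_frames = 20, laser_on_frame = 21,
                    seed = 1)
  expect_error(simulate_experiment(cfg, render = TRUE), "n_frames")
})

test_that("same seed reproduces the experiment bit-identically", {
  cfg <- sim_config(n_cells = 4, n_frames = 60, seed = 10)
  a <- simulate_experiment(cfg, render = TRUE)
  b <- simulate_experiment(cfg, render = TRUE)
  expect_identical(a$movie$pixels, b$movie$pixels)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$meshes, b$meshes)
})

test_that("emit_tracks yields one gap-free track per surviving molecule", {
  cfg <- sim_config(n_cells = 1, n_frames = 40, molecules_per_cell = 1,
                    p_empty = 0, bleach_rate = 0, seed = 11)
  ex <- simulate_experiment(cfg, render = FALSE)
  expect_equal(length(unique(ex$tracks$track_id)), 1L)
  expect_equal(nrow(ex$tracks), 20L)  # 40 frames - 20 dark
  expect_true(all(diff(ex$tracks$frame) == 1))
})

test_that("direct jump sampling matches the closed-form mean square", {
  set.seed(12)
  r <- simulate_jump_sample(1e5, 1, 0.1, tau = 0.015)
  expect_equal(mean(r^2), 4 * 0.1 * 0.015, tolerance = 0.02)
})

test_that("movie and track tables survive a disk round trip", {
  cfg <- sim_config(n_cells = 2, n_frames = 26, seed = 13)
  ex <- simulate_experiment(cfg, render = TRUE)
  tf <- tempfile(fileext = ".tif")
  write_movie_tiff(ex$movie, tf)
  back <- read_movie_tiff(tf)
  expect_equal(back$pixels, round(pmax(ex$movie$pixels, 0)))
  expect_equal(back$tau, ex$movie$tau)
  expect_equal(back$laser_on_frame, ex$movie$laser_on_frame)
  cf <- tempfile(fileext = ".csv")
  write_tracks_csv(ex$tracks, cf)
  tb <- read_tracks_csv(cf)
  expect_equal(tb$frame, ex$tracks$frame)
  expect_equal(tb$x_um, ex$tracks$x_um, tolerance = 1e-12)
  mf <- tempfile(fileext = ".csv")
  write_mesh_csv(ex$meshes, mf)
  mm <- read_mesh_csv(mf)
  expect_equal(mm$x_um, ex$meshes$x_um, tolerance = 1e-12)
  expect_equal(attr(mm, "poles")$x_um, attr(ex$meshes, "poles")$x_um,
               tolerance = 1e-12)
  unlink(c(tf, paste0(tf, ".json"), cf, mf))
})
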