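# unit tests for the corrections and the counting protocol; heavier
# end-to-end recovery lives in test-acceptance.R on the shared fixture

noise_free_config <- function(...) {
  defaults <- list(n_cells = 1, n_frames = 40, molecules_per_cell = 1,
                   p_empty = 0, dimer_fraction = 0, bleach_rate = 0,
                   shot_noise = FALSE, read_noise = 0, f_static = 1,
                   D_static = 0, mean_bound_dwell = 1e9, polar_bias = 0,
                   localization_error = 0, bg_level = 20, bg_level_sd = 0,
                   cell_length_sd = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("offset estimation is exact on noiseless darks", {
  cfg <- noise_free_config(seed = 1)
  ex <- simulate_experiment(cfg, render = TRUE)
  off <- estimate_offset(ex$movie)
  expect_true(all(off == cfg$offset_level))
  expect_equal(estimate_offset(ex$movie, mode = "scalar"),
               cfg$offset_level)
})

test_that("offset under read noise stays within half a count", {
  cfg <- sim_config(n_cells = 2, n_frames = 40, read_noise = 2, seed = 2)
  ex <- simulate_experiment(cfg, render = TRUE)
  off <- estimate_offset(ex$movie)
  expect_lt(max(abs(off - cfg$offset_level)), 3.5)
  expect_lt(abs(mean(off) - cfg$offset_level), 0.5)
})

test_that("offset estimation demands 20 dark frames", {
  cfg <- sim_config(n_cells = 1, n_frames = 30, laser_on_frame = 10,
                    seed = 3)
  ex <- simulate_experiment(cfg, render = TRUE)
  expect_error(estimate_offset(ex$movie), "insufficient dark frames")
})

test_that("illumination ratio: uniform blanks give ratio identically 1", {
  cfg <- noise_free_config(vignette_sigma = 1e6, bg_level = 50, seed = 4)
  bl <- render_blank_movie(cfg, seed = 4)
  r <- estimate_illumination_ratio(bl)
  expect_equal(max(r), 1)
  expect_true(all(abs(r - 1) < 1e-9))
})

test_that("illumination ratio recovers the vignette within 2%", {
  cfg <- sim_config(n_cells = 12, n_frames = 220, seed = 11)
  blanks <- lapply(1:2, function(k)
    render_blank_movie(cfg, n_frames = 270, seed = 98 + k))
  ratio <- estimate_illumination_ratio(blanks)
  d <- dim(blanks[[1]]$pixels)
  V <- smtquant:::vignette_matrix(d[2], d[1], cfg$pixel_size,
                                  cfg$vignette_sigma, NULL)
  expect_equal(max(ratio), 1)
  expect_lt(max(abs(ratio - V / max(V))), 0.02)
})

test_that("the correction equation is applied bit-exactly", {
  set.seed(5)
  frame <- matrix(rpois(400, 150), 20, 20)
  offset <- matrix(100 + rnorm(400, 0, 0.5), 20, 20)
  ratio <- matrix(runif(400, 0.5, 1), 20, 20)
  expect_identical(correct_intensity(frame, offset, ratio),
                   (frame - offset) / ratio)
  mv <- smt_movie(array(frame, c(20, 20, 2)), 0.015, 0.1, 1)
  mc <- correct_intensity(mv, offset, ratio)
  expect_identical(mc$pixels[, , 1], (frame - offset) / ratio)
})

test_that("autofluorescence quadratic is recovered exactly without noise", {
  co <- c(1.5, 40, 300)
  cfg <- noise_free_config(n_cells = 4, autofluorescence_coeffs = co,
                           molecules_per_cell = 0, seed = 6)
  # vary the background level across movies to span the regressor
  movies <- list(); meshes <- list()
  for (k in 1:5) {
    c2 <- cfg
    c2$bg_level <- 10 + 6 * k
    c2$seed <- 10L + k
    ex <- simulate_experiment(c2, render = TRUE)
    movies[[k]] <- ex$movie
    meshes[[k]] <- ex$meshes
  }
  bl <- render_blank_movie(cfg, seed = 7)
  ratio <- estimate_illumination_ratio(bl)
  af <- fit_autofluorescence(movies, meshes, ratio)
  expect_equal(af$a, co[1], tolerance = 1e-3)
  expect_equal(af$b, co[2], tolerance = 1e-3)
  expect_equal(af$c, co[3], tolerance = 1e-3)
})

test_that("zero autofluorescence predicts approximately zero", {
  cfg <- noise_free_config(n_cells = 4, molecules_per_cell = 0,
                           autofluorescence_coeffs = c(0, 0, 0), seed = 8)
  movies <- list(); meshes <- list()
  for (k in 1:3) {
    c2 <- cfg; c2$bg_level <- 12 + 8 * k; c2$seed <- 20L + k
    ex <- simulate_experiment(c2, render = TRUE)
    movies[[k]] <- ex$movie; meshes[[k]] <- ex$meshes
  }
  bl <- render_blank_movie(cfg, seed = 9)
  ratio <- estimate_illumination_ratio(bl)
  af <- fit_autofluorescence(movies, meshes, ratio)
  expect_lt(abs(predict_autofluorescence(af, 20)), 5)
  expect_error(fit_autofluorescence(movies[1]$movie, meshes[1],
                                    ratio), ".")
})

test_that("spot intensity is near zero on flat background", {
  cfg <- noise_free_config(molecules_per_cell = 0, seed = 10)
  ex <- simulate_experiment(cfg, render = TRUE)
  off <- estimate_offset(ex$movie)
  bl <- render_blank_movie(cfg, seed = 10)
  ratio <- estimate_illumination_ratio(bl)
  mc <- correct_intensity(ex$movie, off, ratio)
  ctr <- attr(ex$meshes, "poles")
  si <- spot_integrated_intensity(mc$pixels[, , 25],
                                  mean(ctr$x_um), mean(ctr$y_um),
                                  ex$meshes, 1L, cfg$pixel_size)
  expect_lt(abs(as.numeric(si)), 20)
})

test_that("rendered single-fluorophore spots integrate to the PSF total", {
  for (sd_ in c(12L, 7L)) {
    cfg <- noise_free_config(seed = sd_)
    ex <- simulate_experiment(cfg, render = TRUE)
    off <- estimate_offset(ex$movie)
    bl <- render_blank_movie(cfg, seed = 7)
    ratio <- estimate_illumination_ratio(bl)
    mc <- correct_intensity(ex$movie, off, ratio)
    tr <- ex$tracks
    si <- spot_integrated_intensity(mc$pixels[, , 25], tr$x_um[1],
                                    tr$y_um[1], ex$meshes, 1L,
                                    cfg$pixel_size)
    expect_equal(as.numeric(si), cfg$unitary_photons, tolerance = 0.03)
  }
})

test_that("median filtering cleans traces without moving constants", {
  cfg <- noise_free_config(seed = 12)
  ex <- simulate_experiment(cfg, render = TRUE)
  off <- estimate_offset(ex$movie)
  bl <- render_blank_movie(cfg, seed = 7)
  ratio <- estimate_illumination_ratio(bl)
  mc <- correct_intensity(ex$movie, off, ratio)
  trace <- build_intensity_trace(mc, ex$tracks, ex$meshes)
  expect_equal(trace$filtered, trace$intensity, tolerance = 1e-9)
  # a single-frame outlier is removed by the window-3 filter
  x <- c(5, 5, 50, 5, 5)
  expect_equal(as.numeric(stats::runmed(x, 3)), rep(5, 5))
})

test_that("unitary step estimation: degenerate and mixed histograms", {
  expect_equal(estimate_unitary_step(rep(5000, 60))$I_unit, 5000)
  set.seed(13)
  steps <- c(rnorm(300, 5047, 250), rnorm(900, 8975, 250))
  iu <- estimate_unitary_step(steps)
  expect_equal(iu$I_unit, 5047, tolerance = 0.05)
  expect_equal(iu$weights[1], 0.25, tolerance = 0.05)
  expect_error(estimate_unitary_step(rnorm(10, 5000, 10)), "at least")
})

test_that("unitary step estimator is consistent as steps accumulate", {
  set.seed(14)
  errs <- vapply(c(100, 400, 1600), function(n) {
    steps <- c(rnorm(0.6 * n, 4250, 250), rnorm(0.4 * n, 8251, 250))
    abs(estimate_unitary_step(steps)$I_unit - 4250) / 4250
  }, 1)
  expect_lt(errs[3], 0.03)
  expect_lt(errs[3], errs[1] + 0.02)   # no degradation with sample size
})

test_that("bleach-step classification recovers the dimer fraction", {
  set.seed(15)
  steps <- c(rnorm(600, 5047, 300), rnorm(400, 8975, 300))
  cl <- classify_bleach_steps(steps)
  expect_equal(unname(cl$fractions["dimer"]), 0.4, tolerance = 0.05)
  expect_true(cl$ratio_ok)
  # unimodal data: the forced split is flagged as not dimer-like
  cl1 <- classify_bleach_steps(rnorm(200, 5000, 10))
  expect_false(isTRUE(cl1$ratio_ok))
  cl0 <- classify_bleach_steps(rep(5000, 100))
  expect_equal(unname(cl0$fractions["monomer"]), 1)
  expect_warning(classify_bleach_steps(rnorm(10, 5000, 100)),
                 "undersampled")
  # DgcP-like regime: means near 4,250 and 8,251
  set.seed(16)
  stp <- c(rnorm(600, 4250, 250), rnorm(400, 8251, 250))
  clp <- classify_bleach_steps(stp)
  expect_equal(unname(clp$means["monomer"]), 4250, tolerance = 0.05)
  expect_equal(unname(clp$means["dimer"]), 8251, tolerance = 0.05)
})

test_that("counting a single constant molecule returns N = 1", {
  cfg <- noise_free_config(bg_level = 0,
                           autofluorescence_coeffs = c(0, 0, 0),
                           vignette_sigma = 1e6, seed = 17)
  ex <- simulate_experiment(cfg, render = TRUE)
  off <- estimate_offset(ex$movie)
  ratio <- matrix(1, dim(ex$movie$pixels)[1], dim(ex$movie$pixels)[2])
  af <- structure(list(a = 0, b = 0, c = 0), class = "smt_af_model")
  counts <- count_fluorophores(ex$movie, ex$meshes, off, ratio, af,
                               cfg$unitary_photons)
  expect_equal(counts$N, 1, tolerance = 0.02)
  expect_false(counts$clipped)
  expect_error(count_fluorophores(ex$movie, ex$meshes, off, ratio, af, 0),
               "positive")
})

test_that("count-length correlation behaves on constructed data", {
  set.seed(18)
  ind <- data.frame(N = rpois(60, 6), length_um = rnorm(60, 3, 0.3))
  out <- count_vs_length(ind)
  expect_lt(abs(out$r), 0.3)
  expect_gt(out$p_value, 0.05)
  prop <- data.frame(length_um = ind$length_um,
                     N = 3 * ind$length_um + rnorm(60, 0, 0.5))
  expect_gt(count_vs_length(prop)$r, 0.5)
  same <- data.frame(N = rpois(10, 5), length_um = 3)
  expect_error(count_vs_length(same), "zero variance")
})
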