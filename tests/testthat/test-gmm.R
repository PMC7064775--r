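tau <- 0.015

test_that("jump computation is exact on simple tracks", {
  tr <- data.frame(track_id = 1L, frame = 1:2,
                   x_um = c(0, 0.3), y_um = c(0, 0.4))
  expect_equal(compute_jumps(tr)$r, 0.5)    # 3-4-5 triangle
  tr2 <- data.frame(track_id = 1L, frame = 1:5, x_um = 1, y_um = 2)
  expect_true(all(compute_jumps(tr2)$r == 0))
  # length-1 tracks contribute nothing; non-consecutive frames skipped
  tr3 <- data.frame(track_id = c(1L, 2L, 2L), frame = c(1L, 1L, 3L),
                    x_um = 0, y_um = 0)
  expect_equal(nrow(compute_jumps(tr3)), 0L)
})

test_that("mean squared jump equals 4*D*tau for Brownian tracks", {
  set.seed(1)
  r <- simulate_jump_sample(1e5, 1, 0.1, tau)
  expect_equal(mean(r^2), 4 * 0.1 * tau, tolerance = 0.02)
})

test_that("single-component fit matches the method-of-moments oracle", {
  set.seed(2)
  r <- simulate_jump_sample(5000, 1, 0.2, tau)
  fit <- fit_mixture(r, K = 1, tau = tau)
  d_mom <- mean(r^2) / (4 * tau)       # independent moment estimator
  expect_equal(unname(fit$weights[1, 1]), 1)
  expect_equal(fit$D, d_mom, tolerance = 1e-6)  # MLE = MoM for K = 1
  expect_equal(fit$D, 0.2, tolerance = 0.05)
})

test_that("two-component fit recovers generating parameters", {
  set.seed(3)
  r <- simulate_jump_sample(2e4, c(0.7, 0.3), c(0.079, 0.657), tau)
  fit <- fit_mixture(r, K = 2, tau = tau)
  expect_lt(abs(fit$weights[1, 1] - 0.7), 0.03)
  expect_lt(abs(fit$D[1] / 0.079 - 1), 0.10)
  expect_lt(abs(fit$D[2] / 0.657 - 1), 0.10)
  expect_true(all(diff(fit$D) > 0))     # sorted ascending, slow first
})

test_that("BIC prefers two components for two-state data", {
  set.seed(3)
  r <- simulate_jump_sample(2e4, c(0.7, 0.3), c(0.079, 0.657), tau)
  sel <- select_mixture(r, Ks = 1:3, tau = tau)
  expect_lt(sel$bic["K2"], sel$bic["K1"])
  expect_equal(sel$best$K, 2)
})

test_that("EM log-likelihood is non-decreasing and beats a grid search", {
  set.seed(4)
  r <- simulate_jump_sample(800, c(0.6, 0.4), c(0.08, 0.5), tau)
  fit <- fit_mixture(r, K = 2, tau = tau)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # brute-force grid over (w, D1, D2)
  grid_ll <- function(w, D1, D2) {
    f1 <- r / (2 * D1 * tau) * exp(-r^2 / (4 * D1 * tau))
    f2 <- r / (2 * D2 * tau) * exp(-r^2 / (4 * D2 * tau))
    sum(log(w * f1 + (1 - w) * f2))
  }
  best <- -Inf
  for (w in seq(0.05, 0.95, 0.05))
    for (D1 in seq(0.02, 0.2, 0.01))
      for (D2 in seq(0.2, 1.0, 0.05))
        best <- max(best, grid_ll(w, D1, D2))
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("joint fit shares D across conditions and frees the weights", {
  set.seed(5)
  rA <- simulate_jump_sample(2e4, c(0.703, 0.297), c(0.075, 0.383), tau)
  rB <- simulate_jump_sample(2e4, c(0.183, 0.817), c(0.075, 0.383), tau)
  fit <- fit_joint(list(WT = rA, mutant = rB), K = 2, tau = tau)
  expect_equal(nrow(fit$weights), 2L)
  expect_lt(abs(fit$weights["WT", 1] - 0.703), 0.03)
  expect_lt(abs(fit$weights["mutant", 1] - 0.183), 0.03)
  tab <- mixture_table(fit)
  expect_named(tab, c("condition", "D_static", "D_mobile", "static_pct",
                      "mobile_pct"))
  expect_equal(tab$D_static[1], tab$D_static[2])   # shared coefficients
  # identical conditions give equal weights by symmetry
  set.seed(6)
  r1 <- simulate_jump_sample(5000, c(0.5, 0.5), c(0.08, 0.5), tau)
  r2 <- simulate_jump_sample(5000, c(0.5, 0.5), c(0.08, 0.5), tau)
  f2 <- fit_joint(list(a = r1, b = r2), K = 2, tau = tau)
  expect_lt(abs(f2$weights[1, 1] - f2$weights[2, 1]), 0.05)
  # undersized conditions are excluded with a warning
  expect_warning(
    expect_error(fit_joint(list(a = r1, b = r2[1:50]), K = 2, tau = tau),
                 NA),
    "excluded")
})

test_that("axis-wise Gaussian cross-check agrees with the radial fit", {
  set.seed(7)
  n <- 2e4
  comp <- sample(1:2, n, TRUE, prob = c(0.7, 0.3))
  sd_ax <- sqrt(2 * c(0.079, 0.657)[comp] * tau)
  jumps <- data.frame(dx = rnorm(n, 0, sd_ax), dy = rnorm(n, 0, sd_ax))
  jumps$r <- sqrt(jumps$dx^2 + jumps$dy^2)
  radial <- fit_mixture(jumps$r, K = 2, tau = tau)
  axis <- fit_mixture_axis(jumps, K = 2, tau = tau)
  expect_equal(axis$D, radial$D, tolerance = 0.1)
  expect_equal(unname(axis$weights[1]), unname(radial$weights[1, 1]),
               tolerance = 0.05)
})

test_that("parameter recovery bias stays below one point at 1e5 jumps", {
  set.seed(8)
  r <- simulate_jump_sample(1e5, c(0.697, 0.303), c(0.079, 0.657), tau)
  fit <- fit_mixture(r, K = 2, tau = tau)
  expect_lt(abs(fit$weights[1, 1] - 0.697), 0.01)
})

test_that("membrane-curvature correction multiplies by 1.23", {
  out <- curvature_correct(c(0, 0.079, 0.657))
  expect_equal(out$D_corrected, c(0, 0.09717, 0.80811), tolerance = 1e-12)
  expect_equal(out$D_raw, c(0, 0.079, 0.657))
  expect_error(curvature_correct(-1))
})

test_that("per-track MSD fit classifies mobility sensibly", {
  # immobile noise-free track: D_app = 0, degenerate R^2 flagged as NA
  tr0 <- data.frame(frame = 1:20, x_um = 1, y_um = 1)
  f0 <- per_track_msd(tr0, tau)
  expect_equal(f0$D_app, 0)
  expect_true(is.na(f0$r2))
  # long Brownian track at D = 0.3 recovers D within 20%
  set.seed(9)
  n <- 3000
  tr <- data.frame(frame = 1:n,
                   x_um = cumsum(rnorm(n, 0, sqrt(2 * 0.3 * tau))),
                   y_um = cumsum(rnorm(n, 0, sqrt(2 * 0.3 * tau))))
  f <- per_track_msd(tr, tau)
  expect_equal(f$D_app, 0.3, tolerance = 0.2)
  expect_gt(f$r2, 0.9)
  expect_error(per_track_msd(tr[1:2, ], tau), "too short")
})

test_that("slow-track filter retains predominantly static tracks", {
  cfg <- sim_config(n_cells = 40, n_frames = 520, f_static = 0.5,
                    mean_bound_dwell = 0.4, bleach_rate = 2, seed = 10)
  ex <- simulate_experiment(cfg, render = FALSE)
  msd <- track_msd_table(ex$tracks, cfg$tau)
  keep <- msd$track_id[msd$D_app < 0.5 & !is.na(msd$r2) & msd$r2 > 0.7]
  # fraction of static frames among kept tracks exceeds the population's
  static_share <- function(ids) {
    s <- unlist(ex$truth$states[ids])
    mean(s == 1L)
  }
  expect_gt(static_share(keep), static_share(msd$track_id))
})

test_that("bootstrap standard errors have plausible magnitude", {
  set.seed(11)
  r <- simulate_jump_sample(4000, c(0.7, 0.3), c(0.08, 0.6), tau)
  fit <- fit_mixture(r, K = 2, tau = tau, n_boot = 20)
  expect_true(all(fit$se$D > 0))
  expect_lt(fit$se$weights[1, 1], 0.05)
})
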