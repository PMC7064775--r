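# Shared fixtures, built in code. The heavy copy-number fixture (rendered
# movies with the full offset/vignette/autofluorescence model) is cached so
# that unit and acceptance tests reuse one simulation.

rect_mesh <- function(w = 4, h = 0.8, x0 = 0, y0 = 0, cell_id = 1L) {
  poly <- matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h),
                 4, 2, byrow = TRUE)
  m <- data.frame(cell_id = cell_id, vertex_index = 1:4,
                  x_um = poly[, 1], y_um = poly[, 2])
  attr(m, "poles") <- data.frame(cell_id = cell_id, pole = 1:2,
                                 x_um = c(x0, x0 + w),
                                 y_um = y0 + h / 2)
  class(m) <- c("smt_mesh", "data.frame")
  m
}

# brute-force minimum-cost assignment over all permutations (oracle)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v, k) {
    if (k == 1) return(lapply(v, function(x) x))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (p in perms(seq_len(m), n))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

copy_number_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    base <- sim_config(n_cells = 30, n_frames = 320, seed = 101)
    blanks <- lapply(1:2, function(k)
      render_blank_movie(base, n_frames = 270, seed = 300 + k))
    ratio <- estimate_illumination_ratio(blanks)
    wt_cfg <- base
    wt_cfg$molecules_per_cell <- rep(0L, base$n_cells)
    wt_cfg$n_frames <- 30L
    wt <- lapply(1:10, function(k) {
      w <- wt_cfg; w$seed <- 400L + k
      simulate_experiment(w, render = TRUE)
    })
    af <- fit_autofluorescence(lapply(wt, `[[`, "movie"),
                               lapply(wt, `[[`, "meshes"), ratio)
    steps <- NULL
    for (k in 1:4) {
      cfg <- base; cfg$seed <- 101L + k
      ex <- simulate_experiment(cfg, render = TRUE)
      off <- estimate_offset(ex$movie)
      mc <- correct_intensity(ex$movie, off, ratio)
      st <- extract_bleach_steps(mc, ex$tracks, ex$meshes)
      st$dimer_true <- ex$truth$molecules$dimer[
        match(st$track_id, ex$truth$molecules$molecule_id)]
      steps <- rbind(steps, st)
    }
    cc <- base
    cc$molecules_per_cell <- 1:30
    cc$n_frames <- 40L
    cc$seed <- 177L
    exc <- simulate_experiment(cc, render = TRUE)
    off_c <- estimate_offset(exc$movie)
    n_true <- vapply(1:30, function(cid) {
      m <- exc$truth$molecules[exc$truth$molecules$cell_id == cid, ]
      sum(1L + m$dimer)
    }, 1L)
    cache <<- list(base = base, ratio = ratio, af = af, steps = steps,
                   count_experiment = exc, count_offset = off_c,
                   n_true = n_true)
    cache
  }
})
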