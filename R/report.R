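#' @title Condition comparison and pipeline orchestration
#' @description
#' The reporting layer compares static fractions between paired
#' conditions fitted with shared diffusion coefficients, assembles
#' per-strain tables (static/mobile D, fraction sizes, dwell times, SDs
#' across replicates), and drives the full synthetic pipeline
#' (simulate, track, mixture fit, dwell, heat map, count) from one seeded
#' configuration.
#' @name cli-report
NULL

#' Published per-strain mobility reference values
#'
#' Static/mobile diffusion coefficients, fraction sizes and dwell times
#' for the tracked diguanylate cyclases (DgcK, DgcP) and the unrelated
#' control cyclase (CdaA) in wild-type and mutant backgrounds, as
#' printed in the per-strain tables. Diffusion coefficients are shared
#' within each comparison group (`comparison`), which is why paired
#' strains list identical D values and differing fractions.
#'
#' @return data frame with columns `protein`, `comparison`, `strain`,
#'   `d_static(_sd)`, `d_mobile(_sd)`, `static_pct(_sd)`,
#'   `mobile_pct(_sd)`, `dwell_s(_sd)`.
#' @export
mobility_reference <- function() {
  utils::read.csv(system.file("extdata", "mobility_reference.csv",
                              package = "smtquant", mustWork = TRUE))
}

static_pct_of <- function(x, condition = 1L) {
  if (inherits(x, "smt_mixture_fit"))
    as.numeric(100 * x$weights[condition, 1])
  else as.numeric(x)
}

#' Compare the static fractions of two conditions
#'
#' Computes `delta = static%(A) - static%(B)` — the share of molecules
#' that lose their binding partner in the mutant — from two mixture fits
#' with the same component structure, or directly from two static
#' percentages (e.g. printed table values). The delta is reported to one
#' decimal (table style) and rounded to the nearest integer percent for
#' prose display.
#'
#' @param a,b `smt_mixture_fit` objects (their first condition is used)
#'   or numeric static fractions in percent.
#' @param label_a,label_b condition labels.
#' @param dwell_a,dwell_b optional mean dwell times (s) to difference.
#' @return object of class `smt_condition_comparison`: labels, `f_a`,
#'   `f_b`, `delta` (percentage points, 1 decimal), `delta_display`
#'   (integer percent string), optional `dwell_delta_s`.
#' @examples
#' compare_conditions(70.3, 18.3, "WT", "dgrA-")$delta_display  # "52%"
#' @export
compare_conditions <- function(a, b, label_a = "A", label_b = "B",
                               dwell_a = NULL, dwell_b = NULL) {
  if (inherits(a, "smt_mixture_fit") && inherits(b, "smt_mixture_fit") &&
      a$K != b$K)
    stop("mixture fits have different numbers of components (K = ",
         a$K, " vs ", b$K, ")")
  f_a <- static_pct_of(a)
  f_b <- static_pct_of(b)
  delta <- round(f_a - f_b, 1)
  if (abs(delta) > 100) stop("impossible static-fraction delta")
  structure(list(label_a = label_a, label_b = label_b,
                 f_a = f_a, f_b = f_b, delta = delta,
                 delta_display = sprintf("%d%%", round(f_a - f_b)),
                 dwell_delta_s = if (!is.null(dwell_a) && !is.null(dwell_b))
                   dwell_a - dwell_b),
            class = "smt_condition_comparison")
}

#' @export
print.smt_condition_comparison <- function(x, ...) {
  cat(sprintf("static fraction %s: %.1f%%  vs  %s: %.1f%%\n",
              x$label_a, x$f_a, x$label_b, x$f_b))
  cat(sprintf("  delta = %.1f points (%s of molecules lose their partner)\n",
              x$delta, x$delta_display))
  if (!is.null(x$dwell_delta_s))
    cat(sprintf("  dwell-time difference: %.3f s\n", x$dwell_delta_s))
  invisible(x)
}

# polynomial rolling hash of a string, as provenance marker for outputs
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic pipeline
#'
#' Simulates each configured condition in replicate, extracts tracks
#' (ground-truth emission by default, or detection + linking on the
#' rendered movie), fits the joint jump-distance mixture with shared
#' diffusion coefficients, measures dwell times, builds slow-track heat
#' maps, and — when the `count` stage is enabled — renders movies and
#' quantifies per-cell fluorophore numbers. Replicate SDs mirror a
#' three-biological-replicate design. The pipeline is a pure function of
#' (configs, seed); outputs written to `out_dir` carry the seed and a
#' config hash in a JSON sidecar.
#'
#' @param configs named list of [sim_config()]s, one per condition
#'   (seeds inside are overridden per replicate from `seed`).
#' @param seed master seed.
#' @param n_replicates replicate simulations per condition.
#' @param K mixture components.
#' @param stages subset of `c("gmm", "dwell", "heatmap", "count")`.
#' @param use_detection run spot detection + linking on rendered movies
#'   instead of ground-truth track emission (slower).
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @return list of class `smt_report`: `table` (per-condition summary),
#'   `fit` (joint `smt_mixture_fit`), `dwell`, `heatmaps`, `counts`,
#'   `comparison` (first vs second condition), `seed`.
#' @export
run_pipeline <- function(configs, seed = 1L, n_replicates = 3L, K = 2L,
                         stages = c("gmm", "dwell", "heatmap", "count"),
                         use_detection = FALSE, out_dir = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1,
            !is.null(names(configs)))
  conds <- names(configs)
  reps <- list()
  for (ci in seq_along(conds)) {
    for (r in seq_len(n_replicates)) {
      cfg <- configs[[ci]]
      cfg$seed <- as.integer(seed + 1000L * ci + r)
      need_movie <- use_detection || ("count" %in% stages && r == 1L)
      ex <- simulate_experiment(cfg, render = need_movie)
      if (use_detection) {
        off <- estimate_offset(ex$movie)
        spots <- detect_spots_movie(ex$movie,
                                    correct = function(fr) fr - off)
        tracks <- link_tracks(spots, max_disp = 0.5, min_length = 4L)
        tracks <- assign_cells(tracks, ex$meshes)
      } else {
        tracks <- ex$tracks
      }
      reps[[paste(conds[ci], r, sep = ".")]] <-
        list(condition = conds[ci], replicate = r, experiment = ex,
             tracks = tracks)
    }
  }
  out <- list(seed = seed, conditions = conds)
  # joint mixture fit on pooled replicates, weights per condition
  if ("gmm" %in% stages) {
    steps <- lapply(conds, function(cn) {
      jt <- do.call(rbind, lapply(reps[vapply(reps, function(x)
        x$condition == cn, TRUE)], function(x) compute_jumps(x$tracks)))
      jt$r
    })
    names(steps) <- conds
    out$fit <- if (length(conds) >= 2)
      fit_joint(steps, K = K, tau = configs[[1]]$tau)
    else fit_mixture(steps[[1]], K = K, tau = configs[[1]]$tau)
    # per-replicate weights for SDs
    rep_static <- lapply(conds, function(cn) {
      vapply(reps[vapply(reps, function(x) x$condition == cn, TRUE)],
             function(x) {
               f <- fit_mixture(compute_jumps(x$tracks)$r, K = K,
                                tau = configs[[1]]$tau)
               100 * f$weights[1, 1]
             }, 1)
    })
    names(rep_static) <- conds
    out$replicate_static_pct <- rep_static
  }
  if ("dwell" %in% stages) {
    out$dwell <- lapply(conds, function(cn) {
      evs <- lapply(reps[vapply(reps, function(x) x$condition == cn, TRUE)],
                    function(x) dwell_events(x$tracks,
                                             tau = configs[[1]]$tau))
      mean_dwell_time(evs)
    })
    names(out$dwell) <- conds
  }
  if ("heatmap" %in% stages) {
    out$heatmaps <- lapply(conds, function(cn) {
      rr <- reps[vapply(reps, function(x) x$condition == cn, TRUE)][[1]]
      build_heatmap(rr$tracks, rr$experiment$meshes,
                    tau = configs[[1]]$tau)
    })
    names(out$heatmaps) <- conds
  }
  if ("count" %in% stages) {
    out$counts <- lapply(conds, function(cn) {
      rr <- reps[vapply(reps, function(x) x$condition == cn &&
                          x$replicate == 1L, TRUE)][[1]]
      cfg <- configs[[cn]]
      blank <- render_blank_movie(cfg, n_frames = 120,
                                  seed = seed + 77L)
      ratio <- estimate_illumination_ratio(blank)
      off <- estimate_offset(rr$experiment$movie)
      wt_cfg <- cfg
      wt_cfg$molecules_per_cell <- rep(0L, cfg$n_cells)
      wt <- lapply(1:4, function(k) {
        wt_cfg$seed <- as.integer(seed + 500L + k)
        simulate_experiment(wt_cfg, render = TRUE)
      })
      af <- fit_autofluorescence(lapply(wt, `[[`, "movie"),
                                 lapply(wt, `[[`, "meshes"), ratio)
      mc <- correct_intensity(rr$experiment$movie, off, ratio)
      st <- extract_bleach_steps(mc, rr$tracks, rr$experiment$meshes)
      iu <- estimate_unitary_step(st$step[st$isolated])
      counts <- count_fluorophores(rr$experiment$movie,
                                   rr$experiment$meshes, off, ratio, af, iu)
      list(counts = counts, unitary = iu,
           classes = classify_bleach_steps(st$step[st$isolated]),
           empty_fraction = as.numeric(
             fraction_empty_cells(rr$tracks, rr$experiment$meshes)))
    })
    names(out$counts) <- conds
  }
  # summary table, per-strain-table style
  tab <- data.frame(condition = conds)
  if (!is.null(out$fit)) {
    mt <- mixture_table(out$fit)
    tab <- merge(tab, mt, by = "condition", sort = FALSE)
    tab$static_pct_sd <- vapply(tab$condition, function(cn)
      stats::sd(out$replicate_static_pct[[cn]]), 1)
  }
  if (!is.null(out$dwell)) {
    tab$dwell_s <- vapply(tab$condition, function(cn)
      out$dwell[[cn]]$mean_s, 1)
    tab$dwell_s_sd <- vapply(tab$condition, function(cn)
      out$dwell[[cn]]$sd_s, 1)
  }
  if (!is.null(out$counts)) {
    tab$mean_N <- vapply(tab$condition, function(cn)
      mean(out$counts[[cn]]$counts$N[out$counts[[cn]]$counts$N > 0]), 1)
    tab$empty_cell_fraction <- vapply(tab$condition, function(cn)
      out$counts[[cn]]$empty_fraction, 1)
  }
  out$table <- tab
  if (!is.null(out$fit) && length(conds) >= 2)
    out$comparison <- compare_conditions(
      100 * out$fit$weights[1, 1], 100 * out$fit$weights[2, 1],
      conds[1], conds[2])
  class(out) <- "smt_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "summary_table.csv"),
                     row.names = FALSE)
    for (nm in names(reps))
      write_tracks_csv(reps[[nm]]$tracks,
                       file.path(out_dir, paste0("tracks_", nm, ".csv")))
    meta <- list(seed = seed,
                 config_hash = config_hash(paste(deparse(configs), collapse = "")),
                 package = as.character(utils::packageVersion("smtquant")))
    jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' @export
print.smt_report <- function(x, ...) {
  cat("smtquant pipeline report (seed", x$seed, ")\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
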