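#' @title Two-state mobility decomposition by jump-distance mixture fitting
#' @description
#' Frame-to-frame displacements of Brownian molecules with diffusion
#' coefficient D are Gaussian per axis with variance `2*D*tau`; the jump
#' distance `r = sqrt(dx^2 + dy^2)` then follows the radial (Rayleigh-
#' form) law \eqn{p(r) = r/(2 D \tau) \exp(-r^2/(4 D \tau))}. A mixture of
#' K such components, fitted by maximum likelihood (EM) on the raw jump
#' distances, decomposes a tracked population into static and mobile
#' subpopulations. When two conditions are compared, the diffusion
#' coefficients can be shared across conditions while the mixture weights
#' stay condition-specific, so that fraction sizes are directly
#' comparable.
#' @name mobility-gmm
NULL

#' Compute frame-to-frame jumps from a track table
#'
#' One sample per consecutive localization pair within a track. Tracks
#' are assumed gap-free; pairs with non-consecutive frames are dropped.
#'
#' @param tracks track table (`track_id`, `frame`, `x_um`, `y_um`,
#'   optionally `condition`).
#' @param condition optional condition label attached to all jumps
#'   (overrides a `condition` column).
#' @return data frame: `condition`, `track_id`, `frame`, `dx`, `dy`, `r`
#'   (um over one frame interval).
#' @export
compute_jumps <- function(tracks, condition = NULL) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  same <- c(diff(tracks$track_id) == 0, FALSE)
  consec <- c(diff(tracks$frame) == 1, FALSE)
  i <- which(same & consec)
  dx <- tracks$x_um[i + 1] - tracks$x_um[i]
  dy <- tracks$y_um[i + 1] - tracks$y_um[i]
  cond <- if (!is.null(condition)) rep(condition, length(i))
    else if ("condition" %in% names(tracks)) tracks$condition[i]
    else rep(NA_character_, length(i))
  data.frame(condition = cond, track_id = tracks$track_id[i],
             frame = tracks$frame[i], dx = dx, dy = dy,
             r = sqrt(dx^2 + dy^2))
}

# component density of the jump-distance mixture; s = per-axis variance
jump_density <- function(r, s) r / s * exp(-r^2 / (2 * s))

# deterministic multi-start EM core. r_list: list of jump vectors, one per
# condition; D shared, weights per condition.
em_core <- function(r_list, K, tau, eps = 0, max_iter = 1000, tol = 1e-10) {
  r_list <- lapply(r_list, function(r) r[r > 0 & is.finite(r)])
  n_c <- vapply(r_list, length, 1L)
  if (any(n_c == 0)) stop("empty jump sample")
  r2_all <- unlist(lapply(r_list, function(r) r^2))
  n <- length(r2_all)
  if (n < K) stop("degenerate fit: fewer jumps than components")
  # starting values: quantile split of r^2 plus fixed spread/skew starts
  qsplit <- function() {
    if (K == 1) return(mean(r2_all) / 2)
    grp <- cut(rank(r2_all, ties.method = "first"), K, labels = FALSE)
    vapply(1:K, function(k) mean(r2_all[grp == k]) / 2, 1)
  }
  s_bar <- mean(r2_all) / 2
  starts <- list(qsplit(),
                 s_bar * 4^(seq_len(K) - (K + 1) / 2),
                 s_bar * 8^(seq_len(K) - (K + 1) / 2),
                 s_bar * 2^(seq_len(K) - K))
  starts <- lapply(starts, function(s) sort(pmax(s, 1e-12)))
  best <- NULL
  for (s0 in unique(starts)) {
    fit <- em_run(r_list, s0, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  D <- (best$s - 2 * eps^2) / (2 * tau)
  D <- pmax(D, 0)
  ord <- order(D)
  W <- best$W[, ord, drop = FALSE]
  rownames(W) <- names(r_list)
  k_par <- K + length(r_list) * (K - 1)
  list(K = K, D = D[ord], weights = W, s = best$s[ord], tau = tau,
       eps = eps, loglik = best$loglik,
       bic = -2 * best$loglik + k_par * log(n),
       n = n, n_by_condition = n_c, converged = best$converged,
       iterations = best$iterations, loglik_trace = best$trace)
}

em_run <- function(r_list, s, max_iter, tol) {
  K <- length(s)
  C <- length(r_list)
  W <- matrix(1 / K, C, K)
  ll_old <- -Inf
  trace <- numeric(0)
  conv <- FALSE
  it <- 0
  gam <- vector("list", C)
  for (it in seq_len(max_iter)) {
    num <- den <- numeric(K)
    ll <- 0
    for (c in seq_len(C)) {
      r <- r_list[[c]]
      f <- vapply(seq_len(K), function(k) jump_density(r, s[k]),
                  numeric(length(r)))
      wf <- sweep(f, 2, W[c, ], "*")
      rs <- rowSums(wf)
      rs[rs < 1e-300] <- 1e-300
      ll <- ll + sum(log(rs))
      g <- wf / rs
      gam[[c]] <- g
      W[c, ] <- colMeans(g)
      num <- num + colSums(g * r^2)
      den <- den + colSums(g)
    }
    s <- num / (2 * pmax(den, 1e-12))
    s <- pmax(s, 1e-12)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      conv <- TRUE
      break
    }
    ll_old <- ll
  }
  # final log-likelihood at the returned parameters
  ll <- 0
  for (c in seq_len(C)) {
    r <- r_list[[c]]
    f <- vapply(seq_len(K), function(k) jump_density(r, s[k]),
                numeric(length(r)))
    rs <- as.vector(f %*% W[c, ])
    rs[rs < 1e-300] <- 1e-300
    ll <- ll + sum(log(rs))
  }
  list(s = s, W = W, loglik = ll, converged = conv, iterations = it,
       trace = trace)
}

#' Fit a K-component jump-distance mixture
#'
#' Maximum-likelihood EM fit of
#' \eqn{p(r) = \sum_k w_k \, r/(2 D_k \tau)\exp(-r^2/(4 D_k \tau))} on raw
#' (unbinned) jump distances, with deterministic multi-start
#' initialisation. Components are reported sorted by increasing D, so
#' component 1 is the static/slow subpopulation. An optional per-axis
#' localization-error floor `eps` turns the component scale into
#' `2*D*tau + 2*eps^2`.
#'
#' @param r numeric vector of jump distances (um), or a data frame from
#'   [compute_jumps()].
#' @param K number of components (1-3).
#' @param tau frame interval, s.
#' @param eps per-axis localization error, um (0 = classic model).
#' @param n_boot bootstrap replicates for standard errors (0 = none).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return an object of class `smt_mixture_fit`: diffusion coefficients
#'   `D` (um^2/s, ascending), `weights` (conditions x components),
#'   log-likelihood, `bic`, sample sizes, and bootstrap `se` if requested.
#' @examples
#' set.seed(1)
#' r <- simulate_jump_sample(5000, c(0.7, 0.3), c(0.08, 0.66), tau = 0.015)
#' fit_mixture(r, K = 2, tau = 0.015)
#' @export
fit_mixture <- function(r, K = 2, tau, eps = 0, n_boot = 0,
                        max_iter = 1000, tol = 1e-10) {
  if (is.data.frame(r)) r <- r$r
  if (!K %in% 1:3) stop("K must be 1, 2 or 3")
  if (length(r) < 100) stop("at least 100 jumps are required")
  fit <- em_core(list(all = r), K, tau, eps, max_iter, tol)
  fit$se <- if (n_boot > 0)
    boot_se(list(all = r), K, tau, eps, n_boot, max_iter, tol)
  class(fit) <- "smt_mixture_fit"
  fit
}

#' Joint fit across conditions with shared diffusion coefficients
#'
#' Single EM over all conditions in which the component diffusion
#' coefficients are common to every condition while the mixture weights
#' are free per condition. This is the fit used when two strains or
#' treatments are compared: the resulting table lists identical D values
#' and condition-specific static/mobile fractions.
#'
#' @param steps_by_condition named list of jump-distance vectors, or a
#'   data frame from [compute_jumps()] with a `condition` column.
#' @param K number of components (1-3).
#' @inheritParams fit_mixture
#' @return `smt_mixture_fit` whose `weights` matrix has one row per
#'   condition. Conditions with fewer than 100 jumps are dropped with a
#'   warning.
#' @export
fit_joint <- function(steps_by_condition, K = 2, tau, eps = 0, n_boot = 0,
                      max_iter = 1000, tol = 1e-10) {
  if (is.data.frame(steps_by_condition))
    steps_by_condition <- split(steps_by_condition$r,
                                steps_by_condition$condition)
  if (length(steps_by_condition) < 2)
    stop("fit_joint needs at least two conditions")
  small <- vapply(steps_by_condition, length, 1L) < 100
  if (any(small)) {
    warning("conditions excluded (fewer than 100 jumps): ",
            paste(names(steps_by_condition)[small], collapse = ", "))
    steps_by_condition <- steps_by_condition[!small]
  }
  if (!K %in% 1:3) stop("K must be 1, 2 or 3")
  fit <- em_core(steps_by_condition, K, tau, eps, max_iter, tol)
  fit$se <- if (n_boot > 0)
    boot_se(steps_by_condition, K, tau, eps, n_boot, max_iter, tol)
  class(fit) <- "smt_mixture_fit"
  fit
}

boot_se <- function(r_list, K, tau, eps, n_boot, max_iter, tol) {
  Ds <- matrix(NA_real_, n_boot, K)
  Ws <- array(NA_real_, c(n_boot, length(r_list), K))
  for (b in seq_len(n_boot)) {
    rb <- lapply(r_list, function(r) sample(r, length(r), replace = TRUE))
    fb <- try(em_core(rb, K, tau, eps, max_iter, tol), silent = TRUE)
    if (inherits(fb, "try-error")) next
    Ds[b, ] <- fb$D
    Ws[b, , ] <- fb$weights
  }
  list(D = apply(Ds, 2, stats::sd, na.rm = TRUE),
       weights = apply(Ws, c(2, 3), stats::sd, na.rm = TRUE))
}

#' Fit mixtures for K = 1..3 and select by BIC
#'
#' @inheritParams fit_mixture
#' @param Ks candidate component counts.
#' @return list with `best` (the selected `smt_mixture_fit`), `bic`
#'   (named vector) and `fits`.
#' @export
select_mixture <- function(r, Ks = 1:3, tau, eps = 0, ...) {
  fits <- lapply(Ks, function(K) fit_mixture(r, K, tau, eps, ...))
  bic <- vapply(fits, function(f) f$bic, 1)
  names(bic) <- paste0("K", Ks)
  list(best = fits[[which.min(bic)]], bic = bic, fits = fits)
}

#' @export
print.smt_mixture_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Jump-distance mixture fit: K = %d, n = %d jumps, tau = %g s\n",
              x$K, x$n, x$tau))
  cat(sprintf("  logLik = %.2f, BIC = %.2f, converged: %s (%d iter)\n",
              x$loglik, x$bic, x$converged, x$iterations))
  tab <- mixture_table(x)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Tabulate a mixture fit in reporting form
#'
#' One row per condition with static/mobile D (um^2/s) and fraction
#' sizes in percent, mirroring the layout of per-strain diffusion tables.
#'
#' @param fit an `smt_mixture_fit`.
#' @return data frame: `condition`, `D_static`, `D_mobile` (fastest
#'   component when K > 2), `static_pct`, `mobile_pct`.
#' @export
mixture_table <- function(fit) {
  conds <- rownames(fit$weights)
  if (is.null(conds)) conds <- paste0("cond", seq_len(nrow(fit$weights)))
  data.frame(
    condition = conds,
    D_static = fit$D[1],
    D_mobile = fit$D[fit$K],
    static_pct = 100 * fit$weights[, 1],
    mobile_pct = 100 * rowSums(fit$weights[, -1, drop = FALSE]),
    row.names = NULL)
}

#' Membrane-curvature correction of a diffusion coefficient
#'
#' Diffusion coefficients of membrane proteins measured on the 2-D
#' projection of a curved (cylindrical) membrane underestimate the true
#' in-membrane coefficient; multiplying by 1.23 corrects for the
#' curvature. Reported tables conventionally print the raw values, so
#' both are returned.
#'
#' @param D raw diffusion coefficient(s), um^2/s.
#' @param factor correction factor.
#' @return data frame `D_raw`, `D_corrected`.
#' @examples
#' curvature_correct(c(0.079, 0.657))
#' @export
curvature_correct <- function(D, factor = 1.23) {
  stopifnot(all(D >= 0))
  data.frame(D_raw = D, D_corrected = factor * D)
}

#' Apparent diffusion coefficient from a single track's MSD
#'
#' Time-averaged mean squared displacement at lags `1..n_lags`, fitted by
#' least squares with the linear model `MSD(t) = 4 D t + b` (the offset
#' absorbs localization error). R-squared of that line measures how
#' Brownian the track looks; the slow-track spatial filter keeps tracks
#' with `D_app < 0.5` um^2/s and `R^2 > 0.7`.
#'
#' @param track one track (`frame`, `x_um`, `y_um`), gap-free.
#' @param tau frame interval, s.
#' @param n_lags number of MSD lags (track must have at least
#'   `n_lags + 1` localizations; fewer lags are used if not, minimum 2).
#' @return data frame `D_app`, `r2`, `n_lags`. An immobile noise-free
#'   track returns `D_app = 0` with `r2 = NA` (degenerate fit).
#' @export
per_track_msd <- function(track, tau, n_lags = 4) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  lags <- seq_len(min(n_lags, n - 1))
  if (length(lags) < 2)
    stop("track too short for an MSD fit (need at least 2 usable lags)")
  msd <- vapply(lags, function(l) {
    i <- seq_len(n - l)
    mean((track$x_um[i + l] - track$x_um[i])^2 +
         (track$y_um[i + l] - track$y_um[i])^2)
  }, 1)
  t <- lags * tau
  if (all(msd == 0))
    return(data.frame(D_app = 0, r2 = NA_real_, n_lags = length(lags)))
  fit <- stats::lm(msd ~ t)
  data.frame(D_app = max(0, unname(stats::coef(fit)[2]) / 4),
             r2 = summary(fit)$r.squared, n_lags = length(lags))
}

#' Per-track MSD fits for a whole track table
#'
#' @param tracks track table.
#' @inheritParams per_track_msd
#' @param min_length tracks shorter than this are skipped.
#' @return data frame with one row per track: `track_id`, `D_app`, `r2`,
#'   `n_lags`.
#' @export
track_msd_table <- function(tracks, tau, n_lags = 4, min_length = 4) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < max(3, min_length)) return(NULL)
    cbind(track_id = id, per_track_msd(tr, tau, n_lags))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = integer(), D_app = numeric(),
                      r2 = numeric(), n_lags = integer())
  out
}

#' Cross-check fit on pooled per-axis displacements
#'
#' The same two-state model viewed per axis: `dx` and `dy` pooled follow
#' a zero-mean Gaussian mixture with per-axis variances `2*D_k*tau`.
#' Fitting that mixture provides an independent route to the same D and
#' weight estimates as the radial fit.
#'
#' @param jumps data frame from [compute_jumps()] (needs `dx`, `dy`).
#' @param K components.
#' @param tau frame interval, s.
#' @return list `D`, `weights`, `loglik` (components sorted by D).
#' @export
fit_mixture_axis <- function(jumps, K = 2, tau) {
  x <- c(jumps$dx, jumps$dy)
  x <- x[is.finite(x)]
  # EM for zero-mean Gaussian mixture in variance only
  s <- stats::var(x) * 4^(seq_len(K) - (K + 1) / 2)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in 1:1000) {
    f <- vapply(seq_len(K), function(k) stats::dnorm(x, 0, sqrt(s[k])),
                numeric(length(x)))
    wf <- sweep(f, 2, w, "*")
    rs <- rowSums(wf); rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    g <- wf / rs
    w <- colMeans(g)
    s <- colSums(g * x^2) / colSums(g)
    if (abs(ll - ll_old) < 1e-10 * (abs(ll) + 1)) break
    ll_old <- ll
  }
  ord <- order(s)
  list(D = (s[ord] / (2 * tau)), weights = w[ord], loglik = ll)
}
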