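#' Mean square displacement of water molecules
#'
#' Time-origin-averaged MSD: for each lag, the squared displacement is
#' averaged over all valid origins (default) or over the single origin t = 0,
#' and over molecules for the ensemble curve. Requested lags that are not
#' multiples of the frame interval are moved to the nearest frame with a
#' warning.
#'
#' @param traj A `trajectory_set`.
#' @param lags Lag times (ps); default 25 log-spaced lags up to half the span.
#' @param average `"origins"` (all time origins) or `"t0"` (single origin).
#' @return An `msd_series`: list with `lag` (ps), `msd` (ensemble, A^2) and
#'   `per_molecule` (matrix, lags x molecules).
#' @export
compute_msd <- function(traj, lags = NULL, average = c("origins", "t0")) {
  stopifnot(inherits(traj, "trajectory_set"))
  average <- match.arg(average)
  dt <- traj$frame_interval
  nf <- dim(traj$positions)[1]
  nm <- dim(traj$positions)[3]
  span <- (nf - 1) * dt
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(log(1), log((nf - 1) / 2),
                                 length.out = 25)))) * dt
  }
  if (any(lags > span) || any(lags <= 0)) {
    stop("lags must lie in (0, trajectory span]", call. = FALSE)
  }
  lag_frames <- lags / dt
  if (any(abs(lag_frames - round(lag_frames)) > 1e-9)) {
    warning("lags not multiples of the frame interval moved to nearest frame")
  }
  lag_frames <- pmax(round(lag_frames), 1L)
  per_mol <- matrix(NA_real_, nrow = length(lag_frames), ncol = nm)
  for (il in seq_along(lag_frames)) {
    l <- lag_frames[il]
    if (average == "origins") {
      d <- traj$positions[(1L + l):nf, , , drop = FALSE] -
        traj$positions[1L:(nf - l), , , drop = FALSE]
      per_mol[il, ] <- apply(d^2, 3L, sum) / (nf - l)
    } else {
      d <- traj$positions[1L + l, , ] - traj$positions[1L, , ]
      per_mol[il, ] <- colSums(matrix(d^2, nrow = 3L))
    }
  }
  structure(list(lag = lag_frames * dt, msd = rowMeans(per_mol),
                 per_molecule = per_mol, average = average,
                 frame_interval = dt),
            class = "msd_series")
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("<msd_series> %d lags (%g-%g ps), %d molecules, %s-averaged\n",
              length(x$lag), min(x$lag), max(x$lag), ncol(x$per_molecule),
              x$average))
  invisible(x)
}

#' Elastic intensity from an MSD (Gaussian approximation)
#'
#' `S_el = exp(-Q^2 * msd / 3)` with proportionality constant 1; the inverse
#' of the `ln S_el` versus `Q^2` slope used by [msd_from_elastic()].
#'
#' @param msd Mean square displacement (A^2), >= 0.
#' @param Q Momentum transfer (1/A).
#' @return Dimensionless elastic intensity.
#' @export
#' @examples
#' elastic_intensity_gaussian(3, 1)  # exp(-1)
elastic_intensity_gaussian <- function(msd, Q) {
  stopifnot_positive(msd, "msd", strict = FALSE)
  exp(-outer(Q^2, msd) / 3)[, , drop = TRUE]
}

#' Per-molecule diffusion coefficients from trajectories
#'
#' Least-squares slope of each molecule's time-origin-averaged MSD versus lag
#' over a fit window (default 10–400 ps, excluding the short-time
#' non-diffusive regime), with `D = slope / 6` converted to 1e-10 m^2/s.
#' Negative fitted slopes are clipped to 0 and flagged; a per-molecule fit
#' quality (R^2 of the linear fit) is reported, low values marking
#' non-diffusive trajectories.
#'
#' @param traj A `trajectory_set`.
#' @param window Lag window (ps), within the trajectory span.
#' @param n_lags Number of evenly spaced lags evaluated inside the window.
#' @return A `diffusion_samples` object with `D` (1e-10 m^2/s), `quality`
#'   (R^2 of the linear fit), `nonlinear` (systematic-curvature flag marking
#'   non-diffusive, e.g. ballistic, MSD shapes), `clipped` flags and the fit
#'   `window`.
#' @export
per_molecule_diffusion <- function(traj, window = c(10, 400), n_lags = 20) {
  stopifnot(inherits(traj, "trajectory_set"))
  dt <- traj$frame_interval
  nf <- dim(traj$positions)[1]
  span <- (nf - 1) * dt
  if (window[2] > span || window[1] <= 0) {
    stop("fit window must lie within the trajectory span", call. = FALSE)
  }
  lag_frames <- unique(round(seq(max(window[1] / dt, 1), window[2] / dt,
                                 length.out = n_lags)))
  if (length(lag_frames) < 5) {
    stop("need >= 5 lag points inside the window", call. = FALSE)
  }
  msd <- compute_msd(traj, lags = lag_frames * dt)
  x <- msd$lag
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ydev <- sweep(msd$per_molecule, 2L, colMeans(msd$per_molecule))
  slopes <- drop(crossprod(xc, ydev)) / sxx
  res <- ydev - outer(xc, slopes)
  ss_tot <- colSums(ydev^2)
  ss_res <- colSums(res^2)
  quality <- 1 - ss_res / pmax(ss_tot, .Machine$double.eps)
  # systematic curvature flag: fraction of the linear-fit residual captured
  # by a quadratic term; ~1 for ballistic (MSD ~ t^2) trajectories
  x2 <- xc^2 - mean(xc^2)
  x2 <- x2 - xc * sum(x2 * xc) / sxx       # orthogonalise against the line
  curv <- drop(crossprod(x2, res)) / sum(x2^2)
  ss_res_quad <- colSums((res - outer(x2, curv))^2)
  nonlinear <- (ss_res - ss_res_quad) / pmax(ss_res, .Machine$double.eps) > 0.95
  clipped <- slopes < 0
  d <- pmax(slopes, 0) / 6 * qens_constants$A2ps_to_1e10m2s
  structure(list(D = d, quality = quality, nonlinear = nonlinear,
                 clipped = clipped,
                 window = window, temperature = traj$temperature,
                 component = traj$component, truth = traj$truth),
            class = "diffusion_samples")
}

#' Fit a one- or two-component Gaussian mixture to diffusion coefficients
#'
#' Maximum-likelihood decomposition of per-molecule diffusion coefficients
#' into slow and fast populations. Fitting runs expectation-maximization with
#' multiple restarts (a fixed internal seed stream) and, because sampled D
#' values are truncated at zero, polishes the result by direct maximum
#' likelihood under the left-truncated two-Gaussian model, so the reported
#' weights/means/SDs refer to the untruncated parent components. A
#' histogram-curve least-squares mode (bin width 0.1 x 1e-10 m^2/s) is
#' available to mirror the way such distributions are usually displayed.
#'
#' @param samples A `diffusion_samples` object or numeric vector of D values
#'   (1e-10 m^2/s).
#' @param n_components 1 or 2.
#' @param method `"ml"` (default) or `"histogram"`.
#' @param restarts Number of EM restarts (>= 10 by default).
#' @param truncated If `TRUE` (default) apply the truncated-likelihood polish.
#' @param bin_width Histogram bin width for `method = "histogram"`.
#' @return A `mixture_fit`: `w1`, `m1`, `s1`, `w2`, `m2`, `s2` (components
#'   ordered by mean), `loglik`, `n`, `degenerate` flag and `method`.
#' @export
fit_bimodal_gaussian <- function(samples, n_components = 2,
                                 method = c("ml", "histogram"),
                                 restarts = 10, truncated = TRUE,
                                 bin_width = 0.1) {
  method <- match.arg(method)
  d <- if (inherits(samples, "diffusion_samples")) samples$D else as.numeric(samples)
  d <- d[is.finite(d)]
  if (length(d) < 50) stop("need >= 50 samples", call. = FALSE)
  stopifnot(n_components %in% c(1L, 2L))
  if (n_components == 1L) {
    s_hat <- max(stats::sd(d), 1e-12)
    out <- list(w1 = 1, m1 = mean(d), s1 = s_hat,
                w2 = 0, m2 = NA_real_, s2 = NA_real_,
                loglik = sum(stats::dnorm(d, mean(d), s_hat, log = TRUE)),
                n = length(d), degenerate = FALSE, method = method)
    class(out) <- "mixture_fit"
    return(out)
  }
  if (method == "histogram") {
    return(fit_mixture_histogram(d, bin_width))
  }
  em <- with_seed(20231L, em_best_of(d, restarts))
  if (em$degenerate) {
    out <- fit_bimodal_gaussian(d, n_components = 1L)
    out$degenerate <- TRUE
    return(out)
  }
  par <- c(em$w1, em$m1, em$s1, em$m2, em$s2)
  if (truncated) {
    par <- polish_truncated_mixture(d, par)
  }
  w1 <- par[1]
  ord <- if (par[2] <= par[4]) c(2, 3, 4, 5) else c(4, 5, 2, 3)
  if (par[2] > par[4]) w1 <- 1 - w1
  out <- list(w1 = w1, m1 = par[ord[1]], s1 = par[ord[2]],
              w2 = 1 - w1, m2 = par[ord[3]], s2 = par[ord[4]],
              loglik = trunc_mix_loglik(d, par, truncated),
              n = length(d), degenerate = FALSE, method = method,
              truncated = truncated)
  # near-degenerate single component: one weight ~ 1
  if (max(out$w1, out$w2) >= 0.99 ||
      abs(out$m1 - out$m2) < 1e-6 * (abs(out$m1) + abs(out$m2) + 1e-12)) {
    out$degenerate <- TRUE
  }
  # BIC comparison against a single Gaussian: flags data with no evidence
  # for two components (both models scored on the untruncated likelihood)
  n <- length(d)
  ll1 <- sum(stats::dnorm(d, mean(d), max(stats::sd(d), 1e-12), log = TRUE))
  ll2 <- trunc_mix_loglik(d, par, truncated = FALSE)
  out$prefers_single <- (-2 * ll1 + 2 * log(n)) <= (-2 * ll2 + 5 * log(n))
  class(out) <- "mixture_fit"
  out
}

# log-likelihood of a two-component Gaussian mixture, optionally
# left-truncated at zero per component (matching the generator's sampling)
trunc_mix_loglik <- function(d, par, truncated) {
  w1 <- par[1]; m1 <- par[2]; s1 <- par[3]; m2 <- par[4]; s2 <- par[5]
  if (truncated) {
    z1 <- stats::pnorm(0, m1, s1, lower.tail = FALSE)
    z2 <- stats::pnorm(0, m2, s2, lower.tail = FALSE)
  } else {
    z1 <- z2 <- 1
  }
  f <- w1 * stats::dnorm(d, m1, s1) / z1 + (1 - w1) * stats::dnorm(d, m2, s2) / z2
  sum(log(pmax(f, 1e-300)))
}

# EM with multiple restarts; returns the best (untruncated) solution,
# preferring non-degenerate fits by log-likelihood.
em_best_of <- function(d, restarts) {
  best <- NULL
  qs <- as.numeric(stats::quantile(d, c(0.25, 0.75)))
  s0 <- max(stats::sd(d) / 2, 1e-9)
  for (r in seq_len(restarts)) {
    m <- if (r == 1L) qs else sort(sample(d, 2))
    par <- c(stats::runif(1, 0.3, 0.7), m[1], s0, m[2], s0)
    fit <- em_run(d, par)
    better <- is.null(best) ||
      (best$degenerate && !fit$degenerate) ||
      (best$degenerate == fit$degenerate && fit$loglik > best$loglik)
    if (better) best <- fit
  }
  best
}

em_run <- function(d, par, max_iter = 500, tol = 1e-10) {
  w1 <- par[1]; m1 <- par[2]; s1 <- par[3]; m2 <- par[4]; s2 <- par[5]
  ll_old <- -Inf
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- w1 * stats::dnorm(d, m1, s1)
    f2 <- (1 - w1) * stats::dnorm(d, m2, s2)
    tot <- f1 + f2
    if (any(tot <= 0) || any(!is.finite(tot))) { degenerate <- TRUE; break }
    g <- f1 / tot
    ll <- sum(log(tot))
    w1 <- mean(g)
    if (w1 < 1e-8 || w1 > 1 - 1e-8) { degenerate <- TRUE; break }
    m1 <- sum(g * d) / sum(g)
    m2 <- sum((1 - g) * d) / sum(1 - g)
    s1 <- sqrt(sum(g * (d - m1)^2) / sum(g))
    s2 <- sqrt(sum((1 - g) * (d - m2)^2) / sum(1 - g))
    if (s1 < 1e-8 || s2 < 1e-8) { degenerate <- TRUE; break }
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(w1 = w1, m1 = m1, s1 = s1, m2 = m2, s2 = s2, loglik = ll_old,
       degenerate = degenerate)
}

# Direct MLE polish under the left-truncated mixture model.
polish_truncated_mixture <- function(d, par) {
  obj <- function(theta) {
    p <- c(stats::plogis(theta[1]), theta[2], exp(theta[3]), theta[4],
           exp(theta[5]))
    -trunc_mix_loglik(d, p, truncated = TRUE)
  }
  theta0 <- c(stats::qlogis(min(max(par[1], 1e-4), 1 - 1e-4)),
              par[2], log(par[3]), par[4], log(par[5]))
  opt <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(opt)) return(par)
  c(stats::plogis(opt$par[1]), opt$par[2], exp(opt$par[3]), opt$par[4],
    exp(opt$par[5]))
}

# Histogram-curve least-squares mode: bin the samples and fit the sum of two
# Gaussian curves to the empirical density.
fit_mixture_histogram <- function(d, bin_width) {
  brk <- seq(0, max(d) + bin_width, by = bin_width)
  hh <- graphics::hist(d, breaks = brk, plot = FALSE)
  xs <- hh$mids; ys <- hh$density
  qs <- stats::quantile(d, c(0.25, 0.75))
  fn <- function(p, x) {
    p[1] * stats::dnorm(x, p[2], p[3]) + (1 - p[1]) * stats::dnorm(x, p[4], p[5])
  }
  ft <- wls_fit(fn, start = c(w1 = 0.5, m1 = as.numeric(qs[1]),
                              s1 = stats::sd(d) / 2,
                              m2 = as.numeric(qs[2]), s2 = stats::sd(d) / 2),
                lower = c(0, -Inf, 1e-6, -Inf, 1e-6),
                upper = c(1, Inf, Inf, Inf, Inf),
                y = ys, sigma = rep(1, length(ys)), x = xs)
  par <- unname(ft$estimate)
  w1 <- par[1]
  if (par[2] > par[4]) {
    par <- par[c(1, 4, 5, 2, 3)]; w1 <- 1 - w1
  }
  out <- list(w1 = w1, m1 = par[2], s1 = par[3],
              w2 = 1 - w1, m2 = par[4], s2 = par[5],
              loglik = NA_real_, n = length(d),
              degenerate = !ft$converged, method = "histogram")
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> (%s)%s\n", x$method,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  slow: w = %.3f, m = %.3f, sd = %.3f (x 1e-10 m^2/s)\n",
              x$w1, x$m1, x$s1))
  if (x$w2 > 0) {
    cat(sprintf("  fast: w = %.3f, m = %.3f, sd = %.3f\n", x$w2, x$m2, x$s2))
  }
  invisible(x)
}
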