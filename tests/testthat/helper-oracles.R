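# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of FFT convolution, explicit
# loops instead of vectorised algebra, direct normal equations instead of lm.

# Voigt profile by adaptive quadrature: Lorentzian (unit area, HWHM gamma)
# convolved with a Gaussian of FWHM fwhm, evaluated at energies e.
voigt_quadrature <- function(e, gamma, fwhm) {
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(e, function(e0) {
    stats::integrate(function(t) {
      (gamma / pi) / (t^2 + gamma^2) * stats::dnorm(e0 - t, sd = sg)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Brute-force time-origin-averaged MSD: double loop over origins and lags.
msd_bruteforce <- function(positions, lag_frames) {
  nf <- dim(positions)[1]
  nm <- dim(positions)[3]
  out <- matrix(0, length(lag_frames), nm)
  for (il in seq_along(lag_frames)) {
    l <- lag_frames[il]
    for (m in seq_len(nm)) {
      acc <- 0
      for (t0 in 1:(nf - l)) {
        acc <- acc + sum((positions[t0 + l, , m] - positions[t0, , m])^2)
      }
      out[il, m] <- acc / (nf - l)
    }
  }
  out
}

# Exhaustive segmented-regression search: for each breakpoint pair from the
# candidate grid, solve the continuous piecewise-linear least squares by
# direct normal equations and return the RSS-minimising pair.
segmented_bruteforce <- function(tt, y) {
  n <- length(tt)
  cand <- tt[3:(n - 2)]
  best <- list(rss = Inf, breaks = c(NA, NA))
  for (i in seq_len(length(cand) - 2)) {
    for (k in (i + 2):length(cand)) {
      X <- cbind(1, tt, pmax(tt - cand[i], 0), pmax(tt - cand[k], 0))
      beta <- solve(t(X) %*% X, t(X) %*% y)
      rss <- sum((y - X %*% beta)^2)
      if (rss < best$rss) best <- list(rss = rss, breaks = c(cand[i], cand[k]))
    }
  }
  best
}

# Exhaustive (D, tau0) grid search for the jump-diffusion dispersion with its
# own evaluation of the model (hbar written out explicitly).
jump_gridsearch_oracle <- function(pts, d_range, tau_range, n_grid = 200) {
  hbar <- 658.212
  ds <- exp(seq(log(d_range[1]), log(d_range[2]), length.out = n_grid))
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  best <- list(rss = Inf, D = NA, tau0 = NA)
  for (tau in taus) {
    g_inf <- hbar / tau
    for (d in ds) {
      model <- g_inf * (1 - 1 / (1 + d * pts$Q^2 * tau))
      rss <- sum(((pts$gamma - model) / pts$sigma)^2)
      if (rss < best$rss) best <- list(rss = rss, D = d, tau0 = tau)
    }
  }
  best
}

# Dense grid search for a single pseudo-Voigt peak centre on a pattern with
# linear background: profile over centre, solving amplitude+background by
# linear least squares at fixed centre/width/eta.
pv_center_gridsearch <- function(tth, y, fwhm, eta, centers) {
  best <- list(rss = Inf, center = NA)
  for (c0 in centers) {
    u <- (tth - c0) / (fwhm / 2)
    shape <- eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
    X <- cbind(shape, 1, tth)
    beta <- qr.solve(X, y)
    rss <- sum((y - X %*% beta)^2)
    if (rss < best$rss) best <- list(rss = rss, center = c0)
  }
  best
}

default_resolution <- function() resolution_model(fwhm = 3.5)

e_grid_default <- function(step = 0.4) seq(-100, 100, by = step)
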