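#' Fit the elastic + Lorentzian spectral model per Q
#'
#' For each momentum transfer, fits
#' `I(E) = amp * [x R(E) + (1-x) S(E) (x) R(E)] + C1 E + C2` by weighted
#' least squares, where `S` is one Lorentzian or a two-Lorentzian mixture
#' with narrow-component weight `p`. The spectrum is treated as symmetric in
#' energy transfer (classical approximation). Components are relabelled after
#' every fit so that `g1 <= g2` and `p` always reports the narrow component's
#' weight. A small-sample-corrected information criterion (AICc) is reported
#' for 1- versus 2-component comparison.
#'
#' @param spectrum A `qens_spectrum` (see [generate_qens_spectrum()] or
#'   [read_qens_spectrum()]).
#' @param resolution A [resolution_model()].
#' @param n_lorentzians 1 or 2 quasielastic components.
#' @param fit_window Energy window (ueV) used for fitting, default
#'   `c(-100, 100)`.
#' @return A `spectral_fit` object whose `table` element is a data frame with
#'   one row per Q: `Q`, `x`, `p`, `g1`, `g2`, `c1`, `c2`, `amplitude`, their
#'   standard errors, `chisq_red` (reduced chi-square), `aicc`, and a
#'   `converged` flag. Non-converged Q values are flagged with `NA`
#'   parameters; other Q values are unaffected.
#' @export
fit_spectrum <- function(spectrum, resolution, n_lorentzians = 2,
                         fit_window = c(-100, 100)) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  stopifnot(n_lorentzians %in% c(1L, 2L))
  sel <- spectrum$E >= fit_window[1] & spectrum$E <= fit_window[2]
  if (sum(sel) < 50) stop("need >= 50 energy points inside the fit window",
                          call. = FALSE)
  e <- spectrum$E[sel]
  r_peak <- max(resolution_line_shape(e, resolution))
  nq <- length(spectrum$Q)
  rows <- vector("list", nq)
  for (j in seq_len(nq)) {
    y <- spectrum$I[sel, j]
    sg <- spectrum$sigma[sel, j]
    if (any(sg <= 0)) stop("uncertainties must be > 0", call. = FALSE)
    rows[[j]] <- fit_spectrum_one_q(e, y, sg, resolution, n_lorentzians,
                                    r_peak, spectrum$Q[j])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_lorentzians = n_lorentzians,
                 temperature = spectrum$temperature,
                 fit_window = fit_window),
            class = "spectral_fit")
}

fit_spectrum_one_q <- function(e, y, sg, resolution, n_lor, r_peak, q) {
  h <- e[2] - e[1]
  area <- sum(y) * h
  # initial elastic fraction from the peak-height ratio against a pure
  # resolution line of the same area
  x0 <- min(max(max(y) / (r_peak * max(area, 1e-12)), 0.05), 0.95)
  amp0 <- max(area, 1e-12)
  if (n_lor == 2L) {
    start <- c(x = x0, p = 0.5, g1 = 1, g2 = 20, c1 = 0, c2 = 0, amp = amp0)
    lower <- c(0, 0, 1e-4, 1e-4, -Inf, -Inf, 1e-12)
    upper <- c(1, 1, 5e3, 5e3, Inf, Inf, Inf)
    fn <- function(p, e, resolution) {
      qens_model_curve(e, p[1], p[2], p[3], p[4], p[5], p[6], p[7], resolution)
    }
  } else {
    start <- c(x = x0, g1 = 5, c1 = 0, c2 = 0, amp = amp0)
    lower <- c(0, 1e-4, -Inf, -Inf, 1e-12)
    upper <- c(1, 5e3, Inf, Inf, Inf)
    fn <- function(p, e, resolution) {
      qens_model_curve(e, p[1], 1, p[2], p[2], p[3], p[4], p[5], resolution)
    }
  }
  ft <- wls_fit(fn, start, lower, upper, y, sg, e = e, resolution = resolution)
  k <- length(start)
  n <- length(y)
  if (!ft$converged) {
    return(data.frame(Q = q, x = NA_real_, p = NA_real_, g1 = NA_real_,
                      g2 = NA_real_, c1 = NA_real_, c2 = NA_real_,
                      amplitude = NA_real_,
                      x_se = NA_real_, p_se = NA_real_, g1_se = NA_real_,
                      g2_se = NA_real_, chisq_red = NA_real_,
                      aicc = NA_real_, converged = FALSE))
  }
  est <- ft$estimate; se <- ft$se
  if (n_lor == 2L) {
    p_nar <- est[["p"]]; g1 <- est[["g1"]]; g2 <- est[["g2"]]
    p_se <- se[["p"]]; g1_se <- se[["g1"]]; g2_se <- se[["g2"]]
    if (g1 > g2) {  # relabel so g1 is the narrow component
      tmp <- g1; g1 <- g2; g2 <- tmp
      tmp <- g1_se; g1_se <- g2_se; g2_se <- tmp
      p_nar <- 1 - p_nar
    }
  } else {
    p_nar <- 1; g1 <- est[["g1"]]; g2 <- est[["g1"]]
    p_se <- NA_real_; g1_se <- se[["g1"]]; g2_se <- se[["g1"]]
  }
  if (est[["c2"]] < -1e-8 * max(abs(y))) {
    warning("negative fitted background offset at Q = ", signif(q, 3),
            call. = FALSE)
  }
  data.frame(Q = q, x = est[["x"]], p = p_nar, g1 = g1, g2 = g2,
             c1 = est[["c1"]], c2 = est[["c2"]], amplitude = est[["amp"]],
             x_se = se[["x"]], p_se = p_se, g1_se = g1_se, g2_se = g2_se,
             chisq_red = ft$rss / (n - k),
             aicc = aicc_from_rss(ft$rss, n, k),
             converged = TRUE)
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> %d-Lorentzian model, T = %g K, %d Q values\n",
              x$n_lorentzians, x$temperature, nrow(x$table)))
  print(x$table[, c("Q", "x", "p", "g1", "g2", "chisq_red", "converged")],
        digits = 4)
  invisible(x)
}

#' Convert a QENS spectrum to the dynamic susceptibility
#'
#' `chi''(Q, E) = S(Q, E) * (exp(E / (kB T)) - 1)` on the positive-energy
#' side, with `kB = 86.173 ueV/K`; the Bose-factor proportionality constant
#' is fixed to 1, so the result is in arbitrary units.
#'
#' @param spectrum A `qens_spectrum` with temperature > 0.
#' @param e_max Upper energy-transfer bound (ueV), default 100.
#' @return A `susceptibility_curve`: list with `Q`, `E` (restricted to
#'   `(0, e_max]`), matrix `chi` and `temperature`.
#' @export
compute_susceptibility <- function(spectrum, e_max = 100) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  if (is.null(spectrum$temperature) || spectrum$temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  sel <- spectrum$E > 0 & spectrum$E <= e_max
  if (!any(sel)) stop("energy grid has no points in (0, e_max]", call. = FALSE)
  e <- spectrum$E[sel]
  bose <- expm1(e / (qens_constants$kB_ueV_K * spectrum$temperature))
  chi <- spectrum$I[sel, , drop = FALSE] * bose
  structure(list(Q = spectrum$Q, E = e, chi = chi,
                 temperature = spectrum$temperature),
            class = "susceptibility_curve")
}

#' @export
print.susceptibility_curve <- function(x, ...) {
  cat(sprintf("<susceptibility_curve> %d Q values, E in (0, %g] ueV, T = %g K (arbitrary units)\n",
              length(x$Q), max(x$E), x$temperature))
  invisible(x)
}

#' Mean square displacement from elastic intensities (Gaussian approximation)
#'
#' Fits `ln S_el` versus `Q^2` with free intercept over a Q window and
#' returns `MSD = -3 * slope` with the propagated uncertainty. Because the
#' intercept is free, any overall positive scaling of the intensities leaves
#' the MSD unchanged.
#'
#' @param scan An `elastic_scan`.
#' @param T Temperature (K) at which to evaluate; the nearest grid point is
#'   used.
#' @param q_window Q interval (1/A), default `c(0.5, 0.9)`.
#' @return List with `msd` (A^2), `msd_se`, `temperature_used`, `n_points`.
#' @export
msd_from_elastic <- function(scan, T, q_window = c(0.5, 0.9)) {
  stopifnot(inherits(scan, "elastic_scan"))
  it <- which.min(abs(scan$T - T))
  sel <- scan$Q >= q_window[1] & scan$Q <= q_window[2]
  if (sum(sel) < 3) stop("need >= 3 Q points inside the window", call. = FALSE)
  s_el <- scan$I[it, sel]
  if (any(s_el <= 0)) stop("non-positive elastic intensities in window",
                           call. = FALSE)
  q2 <- scan$Q[sel]^2
  y <- log(s_el)
  xc <- q2 - mean(q2)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  resid <- y - mean(y) - slope * xc
  n <- length(y)
  slope_se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else NA_real_
  list(msd = -3 * slope, msd_se = 3 * slope_se,
       temperature_used = scan$T[it], n_points = n)
}

#' Locate dynamical transitions in an elastic temperature scan
#'
#' Fits continuous piecewise-linear (segmented) models with 0 to
#' `max_transitions` breakpoints placed on the temperature grid, choosing the
#' number of breakpoints by BIC, and returns the breakpoint temperatures
#' sorted. Intensities are averaged over Q (the scan shape is shared across
#' Q up to scale). The quoted uncertainty is half the local grid spacing —
#' the resolution of the on-grid breakpoint search.
#'
#' @param scan An `elastic_scan`.
#' @param max_transitions Maximum number of breakpoints (default 2).
#' @return List with `transitions` (K, possibly empty), `uncertainties`,
#'   `n_breakpoints`, and the per-model `bic` vector.
#' @export
detect_transitions <- function(scan, max_transitions = 2) {
  stopifnot(inherits(scan, "elastic_scan"))
  tt <- scan$T
  n <- length(tt)
  if (n < 10) stop("need >= 10 temperature points", call. = FALSE)
  # average over Q after normalising each Q column to its first point
  imat <- scan$I
  y <- rowMeans(sweep(imat, 2L, imat[1, ], "/"))
  if (n < 2 * (max_transitions + 2)) {
    stop("too few points for the requested number of segments", call. = FALSE)
  }
  scale2 <- stats::var(y)
  rss_floor <- 1e-12 * scale2 + 1e-300

  seg_rss <- function(breaks) {
    xmat <- cbind(1, tt)
    for (b in breaks) xmat <- cbind(xmat, pmax(tt - b, 0))
    ft <- stats::lm.fit(xmat, y)
    sum(ft$residuals^2)
  }
  # candidate breakpoints: interior grid points leaving >= 2 points per segment
  cand <- tt[3:(n - 2)]
  models <- list(list(breaks = numeric(0), rss = seg_rss(numeric(0))))
  if (max_transitions >= 1) {
    rss1 <- vapply(cand, function(b) seg_rss(b), numeric(1))
    i1 <- which.min(rss1)
    models[[2]] <- list(breaks = cand[i1], rss = rss1[i1])
  }
  if (max_transitions >= 2) {
    best <- list(breaks = NULL, rss = Inf)
    nc <- length(cand)
    for (i in seq_len(nc - 2)) {
      for (k in (i + 2):nc) {  # keep >= 2 grid points between breakpoints
        r <- seg_rss(c(cand[i], cand[k]))
        if (r < best$rss) best <- list(breaks = c(cand[i], cand[k]), rss = r)
      }
    }
    models[[3]] <- best
  }
  bic <- vapply(seq_along(models), function(i) {
    k <- 2 + 2 * (i - 1)  # intercept+slope, plus slope change & location per break
    n * log((models[[i]]$rss + rss_floor) / n) + k * log(n)
  }, numeric(1))
  ibest <- which.min(bic)
  breaks <- sort(models[[ibest]]$breaks)
  unc <- vapply(breaks, function(b) {
    i <- which.min(abs(tt - b))
    mean(diff(tt[max(1, i - 1):min(n, i + 1)])) / 2
  }, numeric(1))
  list(transitions = breaks, uncertainties = unc,
       n_breakpoints = length(breaks), bic = bic)
}
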