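#' Fit pseudo-Voigt diffraction peaks
#'
#' Simultaneous weighted least-squares fit of a set of pseudo-Voigt peaks
#' (see [pseudo_voigt()]) plus a linear background to a powder diffraction
#' pattern. Peaks are returned sorted by centre. Per-peak non-convergence is
#' flagged with the initial values echoed rather than raising an error.
#'
#' @param pattern An `xrd_pattern`.
#' @param initial_peaks Data frame with columns `center`, `fwhm`, `eta`,
#'   `amplitude` (optional `hkl` labels); centres must lie inside the grid.
#' @return A `diffraction_peak_fit` whose `peaks` element is a data frame
#'   with per-peak `hkl`, `center`, `fwhm_deg`, `fwhm_rad`, `eta`,
#'   `amplitude`, standard errors and a `converged` flag; plus `background`
#'   (intercept, slope) and `chisq_red`.
#' @export
fit_diffraction_peaks <- function(pattern, initial_peaks = default_cellulose_peaks()) {
  stopifnot(inherits(pattern, "xrd_pattern"))
  pk <- as.data.frame(initial_peaks)
  if (nrow(pk) < 1) stop("need at least one initial peak", call. = FALSE)
  tth <- pattern$two_theta
  if (any(pk$center <= min(tth)) || any(pk$center >= max(tth))) {
    stop("initial peak centers must lie inside the 2-theta grid", call. = FALSE)
  }
  y <- pattern$counts
  sg <- if (!is.null(pattern$sigma)) pattern$sigma else
    rep(stats::sd(diff(y)) / sqrt(2) + 1e-9, length(y))
  np <- nrow(pk)
  hkl <- if (!is.null(pk$hkl)) as.character(pk$hkl) else
    paste0("peak", seq_len(np))

  # parameter vector: [center_i, fwhm_i, eta_i, amp_i] x np, then b0, b1
  start <- c(rbind(pk$center, pk$fwhm, pk$eta, pmax(pk$amplitude, 1e-9)),
             min(y), 0)
  span <- diff(range(tth))
  lower <- c(rbind(pk$center - 0.2 * span, rep(1e-4, np), rep(0, np),
                   rep(0, np)), -Inf, -Inf)
  upper <- c(rbind(pk$center + 0.2 * span, rep(span, np), rep(1, np),
                   rep(Inf, np)), Inf, Inf)
  fn <- function(p, tth, np) {
    out <- p[4 * np + 1] + p[4 * np + 2] * tth
    for (i in seq_len(np)) {
      j <- 4 * (i - 1)
      out <- out + pseudo_voigt(tth, p[j + 1], p[j + 2], p[j + 3], p[j + 4])
    }
    out
  }
  ft <- wls_fit(fn, start = stats::setNames(start, paste0("p", seq_along(start))),
                lower = lower, upper = upper,
                y = y, sigma = sg, tth = tth, np = np)
  est <- unname(ft$estimate); se <- unname(ft$se)
  rows <- lapply(seq_len(np), function(i) {
    j <- 4 * (i - 1)
    data.frame(hkl = hkl[i],
               center = est[j + 1], fwhm_deg = est[j + 2],
               fwhm_rad = est[j + 2] * pi / 180,
               eta = est[j + 3], amplitude = est[j + 4],
               center_se = se[j + 1], fwhm_se = se[j + 2],
               eta_se = se[j + 3], amplitude_se = se[j + 4],
               converged = ft$converged)
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$center), ]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks,
                 background = c(intercept = est[[4 * np + 1]],
                                slope = est[[4 * np + 2]]),
                 converged = ft$converged,
                 chisq_red = if (ft$converged) ft$rss / (ft$n - length(start))
                             else NA_real_,
                 wavelength = pattern$wavelength),
            class = "diffraction_peak_fit")
}

#' @export
print.diffraction_peak_fit <- function(x, ...) {
  cat(sprintf("<diffraction_peak_fit> %d peaks%s\n", nrow(x$peaks),
              if (!x$converged) " (NOT converged; initial values echoed)" else ""))
  print(x$peaks[, c("hkl", "center", "fwhm_deg", "eta", "amplitude")],
        digits = 4)
  invisible(x)
}

#' Bragg spacing from a diffraction angle
#'
#' `d = lambda / (2 sin(theta))` with `theta` equal to half the scattering
#' angle 2-theta, converted to radians internally.
#'
#' @param two_theta Scattering angle (degrees), in (0, 180).
#' @param wavelength X-ray wavelength (A), Cu K-alpha by default.
#' @return Lattice spacing d (A).
#' @export
#' @examples
#' bragg_spacing(22.9)  # ~3.88 A
bragg_spacing <- function(two_theta, wavelength = 1.542) {
  if (any(two_theta <= 0) || any(two_theta > 180)) {
    stop("two_theta must lie in (0, 180] degrees", call. = FALSE)
  }
  theta <- two_theta / 2 * pi / 180
  wavelength / (2 * sin(theta))
}

#' Scherrer crystallite size from peak broadening
#'
#' `L = 0.9 lambda / (beta cos(theta))` with the angular FWHM `beta` in
#' radians and `theta` half the scattering angle. The Scherrer constant is
#' fixed at 0.9. Degrees-to-radians conversion is handled here when the peak
#' comes from [fit_diffraction_peaks()] (which carries both). No instrument
#' broadening is deconvolved, so sizes are lower bounds.
#'
#' @param peak Either a one-row data frame from a `diffraction_peak_fit`
#'   (uses `fwhm_rad` and `center`) or a numeric FWHM.
#' @param two_theta Scattering angle (degrees); required when `peak` is
#'   numeric.
#' @param wavelength X-ray wavelength (A).
#' @param fwhm_unit `"radians"` or `"degrees"` when `peak` is numeric.
#' @return Crystallite size L (A).
#' @export
#' @examples
#' scherrer_size(0.02832, two_theta = 22.9)  # ~50 A
scherrer_size <- function(peak, two_theta = NULL, wavelength = 1.542,
                          fwhm_unit = c("radians", "degrees")) {
  fwhm_unit <- match.arg(fwhm_unit)
  if (is.data.frame(peak)) {
    beta <- peak$fwhm_rad
    two_theta <- peak$center
  } else {
    beta <- if (fwhm_unit == "degrees") peak * pi / 180 else peak
    if (is.null(two_theta)) stop("'two_theta' required for numeric input",
                                 call. = FALSE)
  }
  stopifnot_positive(beta, "FWHM")
  if (any(two_theta <= 0) || any(two_theta >= 180)) {
    stop("two_theta must lie in (0, 180) degrees", call. = FALSE)
  }
  theta <- two_theta / 2 * pi / 180
  0.9 * wavelength / (beta * cos(theta))
}

#' Interfibrillar gap from SANS repeat distance and crystallite width
#'
#' `gap = d - L`: the centre-to-centre microfibril repeat from the SANS
#' correlation peak minus the crystallite width from diffraction, with
#' uncertainties combined in quadrature. A negative gap signals inconsistent
#' inputs and raises an error.
#'
#' @param repeat_distance Centre-to-centre distance d (A), > 0.
#' @param crystallite_width Microfibril width L (A), > 0.
#' @param d_se,L_se Optional uncertainties (A).
#' @return List with `gap` (A) and `gap_se`.
#' @export
#' @examples
#' interfibril_gap(67, 50, d_se = 0.6, L_se = 1)
interfibril_gap <- function(repeat_distance, crystallite_width,
                            d_se = NA_real_, L_se = NA_real_) {
  stopifnot_positive(repeat_distance, "repeat_distance")
  stopifnot_positive(crystallite_width, "crystallite_width")
  gap <- repeat_distance - crystallite_width
  if (gap < 0) {
    stop("crystallite width exceeds repeat distance: inconsistent inputs",
         call. = FALSE)
  }
  gap_se <- if (is.finite(d_se) || is.finite(L_se)) {
    sqrt(sum(c(d_se, L_se)^2, na.rm = TRUE))
  } else NA_real_
  list(gap = gap, gap_se = gap_se)
}
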