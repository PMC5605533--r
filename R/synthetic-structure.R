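# Synthetic small-angle scattering profiles and powder diffraction patterns.

#' Lorentzian correlation-peak form used for SANS analysis
#'
#' `A * (1/pi) * (w/2) / ((w/2)^2 + (Q - center)^2)`: a Lorentzian of full
#' width `w` centred at `center` with integrated area `A`. At `Q = center`
#' the peak height is `2A/(pi*w)`.
#'
#' @param Q Momentum transfer (1/A).
#' @param A Scale (area) factor.
#' @param w Full peak width (1/A).
#' @param center Peak centre (1/A).
#' @return Intensities at `Q`.
#' @export
correlation_peak_curve <- function(Q, A, w, center) {
  stopifnot_positive(w, "w")
  A * (1 / pi) * (w / 2) / ((w / 2)^2 + (Q - center)^2)
}

#' Generate a synthetic SANS profile
#'
#' `I(Q) = (P*Q)^(-alpha) + B`, optionally plus the Lorentzian correlation
#' peak of [correlation_peak_curve()], with relative Gaussian noise. The
#' uncertainty column is the noise model sigma with a small positive floor.
#'
#' @param P Power-law scale factor (set `P = 0` with `alpha = 0` unused; to
#'   suppress the power law entirely pass `power_law = FALSE`).
#' @param alpha Power-law exponent (>= 0).
#' @param B Flat background.
#' @param peak Optional list/vector with elements `A`, `w`, `center`.
#' @param q_grid Strictly positive Q grid (1/A) within 0.003–0.4; default
#'   250 log-spaced points.
#' @param noise Relative noise level.
#' @param seed Integer RNG seed.
#' @param power_law If `FALSE` the power-law term is omitted.
#' @param label Sample label (`"dry"`, `"hydrated"` or `"synthetic"`).
#' @return A `sans_profile` object with `Q`, `I`, `sigma`, `label`, `truth`.
#' @export
#' @examples
#' pr <- generate_sans_profile(P = 2.4, alpha = 3.55, B = 0.5,
#'                             peak = list(A = 1, w = 0.04, center = 0.094),
#'                             noise = 0.01, seed = 5)
#' pr
generate_sans_profile <- function(P = 2.4, alpha = 3.55, B = 0.5,
                                  peak = NULL,
                                  q_grid = exp(seq(log(0.003), log(0.4),
                                                   length.out = 250)),
                                  noise = 0.01, seed = 1L,
                                  power_law = TRUE,
                                  label = "synthetic") {
  if (any(q_grid <= 0)) stop("Q grid must be strictly positive", call. = FALSE)
  if (any(diff(q_grid) <= 0)) stop("Q grid must be strictly increasing", call. = FALSE)
  stopifnot_positive(alpha, "alpha", strict = FALSE)
  intens <- rep(B, length(q_grid))
  if (power_law) intens <- intens + (P * q_grid)^(-alpha)
  if (!is.null(peak)) {
    peak <- as.list(peak)
    intens <- intens + correlation_peak_curve(q_grid, peak$A, peak$w, peak$center)
  }
  sig <- pmax(noise * pmax(intens, .Machine$double.eps), 1e-10)
  if (noise > 0) {
    intens <- intens + with_seed(seed, stats::rnorm(length(intens))) * sig
  }
  structure(list(Q = as.numeric(q_grid), I = intens, sigma = sig,
                 label = label,
                 truth = list(P = P, alpha = alpha, B = B, peak = peak,
                              noise = noise, seed = seed,
                              power_law = power_law)),
            class = "sans_profile")
}

#' @export
print.sans_profile <- function(x, ...) {
  cat(sprintf("<sans_profile> %s, %d points, Q = %.4g-%.4g 1/A\n",
              x$label, length(x$Q), min(x$Q), max(x$Q)))
  invisible(x)
}

#' Pseudo-Voigt peak profile
#'
#' `amplitude * (eta * L + (1 - eta) * G)` where the Lorentzian `L` and
#' Gaussian `G` share the same full width at half maximum and unit peak
#' height, so `amplitude` is the peak height and `fwhm` the FWHM for any
#' mixing `eta` in \[0, 1\].
#'
#' @param x Abscissa (e.g. scattering angle 2-theta in degrees).
#' @param center Peak centre.
#' @param fwhm Full width at half maximum (> 0).
#' @param eta Lorentzian fraction in \[0, 1\].
#' @param amplitude Peak height.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta, amplitude = 1) {
  stopifnot_positive(fwhm, "fwhm")
  stopifnot_fraction(eta, "eta")
  u <- (x - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  amplitude * (eta * lor + (1 - eta) * gau)
}

#' Generate a synthetic powder X-ray diffraction pattern
#'
#' Sum of pseudo-Voigt peaks plus a linear background plus relative Gaussian
#' noise. Defaults reproduce the four reflections of a cellulose I-alpha
#' microfibril: (100) 14.8 deg, (010) 16.9 deg, (1 1 -2) 20.7 deg and
#' (110) 22.9 deg.
#'
#' @param peaks Data frame with columns `center` (2-theta, degrees), `fwhm`
#'   (degrees), `eta`, `amplitude`; optional `hkl` labels.
#' @param background Length-2 numeric `c(intercept, slope)` of a linear
#'   background in 2-theta.
#' @param two_theta_grid Increasing 2-theta grid (degrees) within 5–90.
#' @param wavelength X-ray wavelength (A); Cu K-alpha by default.
#' @param noise Relative noise level.
#' @param seed Integer RNG seed.
#' @return An `xrd_pattern` object with `two_theta`, `counts`, `sigma`,
#'   `wavelength`, `truth`.
#' @export
generate_xrd_pattern <- function(peaks = default_cellulose_peaks(),
                                 background = c(5, -0.02),
                                 two_theta_grid = seq(5, 40, by = 0.02),
                                 wavelength = 1.542,
                                 noise = 0.01, seed = 1L) {
  peaks <- as.data.frame(peaks)
  if (any(diff(two_theta_grid) <= 0)) {
    stop("two_theta_grid must be increasing", call. = FALSE)
  }
  if (min(two_theta_grid) < 5 - 1e-9 || max(two_theta_grid) > 90 + 1e-9) {
    stop("two_theta_grid must lie within 5-90 degrees", call. = FALSE)
  }
  if (any(peaks$center <= min(two_theta_grid)) ||
      any(peaks$center >= max(two_theta_grid))) {
    stop("peak centers must lie inside the 2-theta grid", call. = FALSE)
  }
  stopifnot_positive(peaks$fwhm, "fwhm")
  stopifnot_fraction(peaks$eta, "eta")
  counts <- background[1] + background[2] * two_theta_grid
  for (i in seq_len(nrow(peaks))) {
    counts <- counts + pseudo_voigt(two_theta_grid, peaks$center[i],
                                    peaks$fwhm[i], peaks$eta[i],
                                    peaks$amplitude[i])
  }
  sig <- pmax(noise * pmax(counts, .Machine$double.eps), 1e-10)
  if (noise > 0) {
    counts <- counts + with_seed(seed, stats::rnorm(length(counts))) * sig
  }
  structure(list(two_theta = as.numeric(two_theta_grid), counts = counts,
                 sigma = sig, wavelength = wavelength,
                 truth = list(peaks = peaks, background = background,
                              noise = noise, seed = seed)),
            class = "xrd_pattern")
}

#' Default cellulose I-alpha reflection list
#'
#' Four pseudo-Voigt peaks at the characteristic microfibril reflections.
#' The (110) width default of 1.622 degrees corresponds to a crystallite
#' width of 50 A at Cu K-alpha via the Scherrer relation.
#'
#' @return Data frame with columns `hkl`, `center`, `fwhm`, `eta`, `amplitude`.
#' @export
default_cellulose_peaks <- function() {
  data.frame(
    hkl = c("100", "010", "11-2", "110"),
    center = c(14.8, 16.9, 20.7, 22.9),
    fwhm = c(1.5, 1.6, 1.4, 1.622),
    eta = c(0.5, 0.5, 0.5, 0.5),
    amplitude = c(60, 30, 20, 100)
  )
}

#' @export
print.xrd_pattern <- function(x, ...) {
  cat(sprintf("<xrd_pattern> %d points, 2theta = %.3g-%.3g deg, lambda = %g A\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$wavelength))
  invisible(x)
}
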