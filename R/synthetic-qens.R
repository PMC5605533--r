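#' Ground truth for a synthetic QENS spectrum
#'
#' Bundles the per-Q generating parameters of the elastic + two-Lorentzian
#' spectral model. The narrow component's half-width can either be fixed
#' (`g1`) or derived per Q from the jump-diffusion dispersion (`D`, `tau0`),
#' which is how temperature series with a known translational diffusion
#' coefficient are produced.
#'
#' @param x Elastic fraction in \[0, 1\]; scalar or one value per Q.
#' @param p Spectral weight of the narrow quasielastic component in \[0, 1\].
#' @param g1 Narrow Lorentzian HWHM (ueV), ignored when `D` is given.
#' @param g2 Broad Lorentzian HWHM (ueV).
#' @param D Optional translational diffusion coefficient (A^2/ps); together
#'   with `tau0` it sets the narrow HWHM per Q via the jump-diffusion law.
#' @param tau0 Residence time (ps) when `D` is given.
#' @param c1,c2 Linear background slope (counts/ueV) and offset (counts).
#' @param amplitude Overall intensity scale.
#' @param resolution_fwhm Gaussian resolution FWHM (ueV).
#' @param temperature Sample temperature label (K).
#' @param noise Relative Gaussian noise level (0 disables noise).
#' @param coherent_above_Q If finite, adds an elastic-only contamination term
#'   for Q above this value, mimicking coherent scattering from crystalline
#'   cellulose. Off (`Inf`) by default.
#' @param seed Integer RNG seed used at generation time.
#' @return An object of class `qens_ground_truth`.
#' @export
qens_ground_truth <- function(x = 0.6, p = 0.5, g1 = 2, g2 = 20,
                              D = NULL, tau0 = NULL,
                              c1 = 0, c2 = 0, amplitude = 1,
                              resolution_fwhm = 3.5, temperature = 250,
                              noise = 0.01, coherent_above_Q = Inf,
                              seed = 1L) {
  stopifnot_fraction(x, "x")
  stopifnot_fraction(p, "p")
  stopifnot_positive(g2, "g2")
  stopifnot_positive(resolution_fwhm, "resolution_fwhm")
  if (is.null(D)) {
    stopifnot_positive(g1, "g1")
  } else {
    stopifnot_positive(D, "D", strict = FALSE)
    stopifnot_positive(tau0, "tau0")
  }
  structure(list(x = x, p = p, g1 = g1, g2 = g2, D = D, tau0 = tau0,
                 c1 = c1, c2 = c2, amplitude = amplitude,
                 resolution_fwhm = resolution_fwhm,
                 temperature = temperature, noise = noise,
                 coherent_above_Q = coherent_above_Q, seed = seed),
            class = "qens_ground_truth")
}

truth_field_per_q <- function(value, nq, name) {
  if (length(value) == 1L) rep(value, nq)
  else if (length(value) == nq) value
  else stop("'", name, "' must be scalar or one value per Q", call. = FALSE)
}

#' Generate a synthetic QENS spectrum with known ground truth
#'
#' Evaluates the elastic + two-Lorentzian model convolved with a Gaussian
#' resolution on a uniform energy grid, per Q, and adds zero-mean Gaussian
#' noise with standard deviation `noise * pmax(I, floor)`. The returned
#' object carries the generating truth so fitting stages can be tested
#' against it.
#'
#' @param truth A [qens_ground_truth()].
#' @param q_grid Momentum-transfer values (1/A), within 0.2–2.0.
#' @param e_grid Uniform energy-transfer grid (ueV) spanning at least
#'   -100..100 ueV.
#' @return A `qens_spectrum` object: list with `Q`, `E`, `I` and `sigma`
#'   matrices (rows = E, columns = Q), `temperature`, and the echoed `truth`.
#' @export
#' @examples
#' tr <- qens_ground_truth(x = 0.3, p = 0.6, g1 = 1, g2 = 10, noise = 0)
#' sp <- generate_qens_spectrum(tr, q_grid = 0.5, e_grid = seq(-100, 100, 0.5))
#' sp
generate_qens_spectrum <- function(truth, q_grid,
                                   e_grid = seq(-100, 100, by = 0.4)) {
  stopifnot(inherits(truth, "qens_ground_truth"))
  stopifnot_uniform_grid(e_grid, "energy grid")
  if (min(e_grid) > -100 || max(e_grid) < 100) {
    stop("energy grid must span at least -100..100 ueV", call. = FALSE)
  }
  if (any(q_grid < 0.2 - 1e-9) || any(q_grid > 2.0 + 1e-9)) {
    stop("q_grid must lie within 0.2-2.0 1/A", call. = FALSE)
  }
  nq <- length(q_grid)
  x <- truth_field_per_q(truth$x, nq, "x")
  p <- truth_field_per_q(truth$p, nq, "p")
  g2 <- truth_field_per_q(truth$g2, nq, "g2")
  amp <- truth_field_per_q(truth$amplitude, nq, "amplitude")
  c1 <- truth_field_per_q(truth$c1, nq, "c1")
  c2 <- truth_field_per_q(truth$c2, nq, "c2")
  g1 <- if (is.null(truth$D)) {
    truth_field_per_q(truth$g1, nq, "g1")
  } else {
    gamma_jump(q_grid, truth$D, truth$tau0)
  }
  res <- resolution_model(fwhm = truth$resolution_fwhm)

  intens <- matrix(NA_real_, nrow = length(e_grid), ncol = nq)
  for (j in seq_len(nq)) {
    yj <- qens_model_curve(e_grid, x[j], p[j], max(g1[j], 1e-6), g2[j],
                           c1[j], c2[j], amp[j], res)
    if (q_grid[j] > truth$coherent_above_Q) {
      yj <- yj + 0.5 * amp[j] * resolution_line_shape(e_grid, res)
    }
    intens[, j] <- yj
  }
  floor_i <- 1e-3 * max(intens)
  sig <- truth$noise * pmax(intens, floor_i)
  if (truth$noise > 0) {
    intens <- intens + with_seed(truth$seed, {
      matrix(stats::rnorm(length(intens)), nrow = nrow(intens))
    }) * sig
  } else {
    # uncertainties must stay positive even for noise-free fixtures
    sig <- matrix(floor_i * 1e-3 + 1e-12, nrow = nrow(intens), ncol = nq)
  }
  structure(list(Q = as.numeric(q_grid), E = as.numeric(e_grid),
                 I = intens, sigma = sig,
                 temperature = truth$temperature,
                 truth = c(truth, list(g1_per_q = g1))),
            class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf("<qens_spectrum> %d Q values (%.2g-%.2g 1/A), %d energy points (%g..%g ueV), T = %g K\n",
              length(x$Q), min(x$Q), max(x$Q), length(x$E), min(x$E), max(x$E),
              x$temperature))
  invisible(x)
}

#' Generate a synthetic elastic-intensity temperature scan
#'
#' Per-Q elastic intensity that is piecewise linear in temperature with slope
#' changes at two dynamical transition temperatures; the drop beyond the upper
#' transition is sharper than beyond the lower one when `step_depths` are
#' given in increasing order. The curve is monotonically non-increasing in T
#' before noise.
#'
#' @param q_grid Momentum-transfer values (1/A).
#' @param T_grid Increasing temperature grid (K).
#' @param transition_temps Numeric pair of transition temperatures (K) inside
#'   the range of `T_grid`.
#' @param step_depths Numeric pair of additional downward slopes (intensity
#'   per K) switched on above each transition; `c(0, 0)` gives a single-slope
#'   scan with no transitions.
#' @param base_slope Downward slope below both transitions (per K).
#' @param noise Relative Gaussian noise level.
#' @param seed Integer RNG seed.
#' @return An `elastic_scan` object: `T`, `Q`, intensity matrix `I`
#'   (rows = T), `sigma`, plus the generating truth.
#' @export
generate_elastic_scan <- function(q_grid = 0.9,
                                  T_grid = seq(100, 292, by = 4),
                                  transition_temps = c(220, 260),
                                  step_depths = c(0.004, 0.012),
                                  base_slope = 5e-4,
                                  noise = 0.01, seed = 1L) {
  if (any(diff(T_grid) <= 0)) stop("T_grid must be increasing", call. = FALSE)
  if (length(transition_temps) != 2L ||
      any(transition_temps <= min(T_grid)) ||
      any(transition_temps >= max(T_grid))) {
    stop("transition temperatures must lie inside the T grid range",
         call. = FALSE)
  }
  stopifnot_positive(c(step_depths, base_slope), "slopes", strict = FALSE)
  t1 <- min(transition_temps); t2 <- max(transition_temps)
  nT <- length(T_grid); nq <- length(q_grid)
  base <- 1 - base_slope * (T_grid - T_grid[1]) -
    step_depths[1] * pmax(T_grid - t1, 0) -
    step_depths[2] * pmax(T_grid - t2, 0)
  if (any(base <= 0)) stop("step depths drive intensity non-positive; reduce them",
                           call. = FALSE)
  intens <- outer(base, exp(-q_grid^2 * 0.15))  # mild per-Q attenuation
  sig <- pmax(noise, 1e-4) * pmax(intens, 1e-6)
  if (noise > 0) {
    intens <- intens + with_seed(seed, {
      matrix(stats::rnorm(length(intens)), nrow = nT)
    }) * sig
  }
  structure(list(T = as.numeric(T_grid), Q = as.numeric(q_grid),
                 I = intens, sigma = sig,
                 truth = list(transition_temps = c(t1, t2),
                              step_depths = step_depths,
                              base_slope = base_slope, noise = noise,
                              seed = seed)),
            class = "elastic_scan")
}

#' @export
print.elastic_scan <- function(x, ...) {
  cat(sprintf("<elastic_scan> %d temperatures (%g-%g K), %d Q values\n",
              length(x$T), min(x$T), max(x$T), length(x$Q)))
  invisible(x)
}
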