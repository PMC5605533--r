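# Synthetic water dynamics: two-population diffusion-coefficient samples and
# Brownian surrogate trajectories.

#' Two-population water diffusion specification
#'
#' Parameters of a two-Gaussian mixture of per-molecule translational
#' diffusion coefficients, in the conventional reporting unit of
#' 1e-10 m^2/s, plus trajectory-generation settings. The default rows of the
#' bimodal decomposition at 213, 243 and 263 K are available via
#' [water_population_table()].
#'
#' @param w1,w2 Component weights (must sum to 1).
#' @param m1,m2 Component means (1e-10 m^2/s).
#' @param s1,s2 Component standard deviations (1e-10 m^2/s, > 0).
#' @param n_molecules Number of molecules (>= 2).
#' @param frame_interval Trajectory frame spacing (ps).
#' @param n_frames Number of trajectory frames (>= 10 in trajectory mode).
#' @param temperature Temperature label (K).
#' @param seed Integer RNG seed.
#' @return An object of class `water_population_spec`.
#' @export
water_population_spec <- function(w1 = 0.85, m1 = 0.25, s1 = 0.07,
                                  w2 = 0.15, m2 = 0.52, s2 = 0.18,
                                  n_molecules = 1000,
                                  frame_interval = 2, n_frames = 2500,
                                  temperature = 213, seed = 1L) {
  if (abs(w1 + w2 - 1) > 1e-9) stop("w1 + w2 must equal 1", call. = FALSE)
  if (w1 < 0 || w2 < 0) stop("weights must be >= 0", call. = FALSE)
  stopifnot_positive(c(s1, s2), "sigma")
  if (n_molecules < 2) stop("n_molecules must be >= 2", call. = FALSE)
  stopifnot_positive(frame_interval, "frame_interval")
  structure(list(w1 = w1, m1 = m1, s1 = s1, w2 = w2, m2 = m2, s2 = s2,
                 n_molecules = n_molecules, frame_interval = frame_interval,
                 n_frames = n_frames, temperature = temperature, seed = seed),
            class = "water_population_spec")
}

#' Slow/fast water population parameters at three temperatures
#'
#' Mixture parameters (weights, means and standard deviations, in
#' 1e-10 m^2/s) describing the bimodal distribution of per-molecule water
#' diffusion coefficients at 213, 243 and 263 K. The slow-population weight
#' drops from 0.85 to 0.18 as the interfibrillar water melts.
#'
#' @return Data frame with columns `temperature`, `w1`, `m1`, `s1`, `w2`,
#'   `m2`, `s2`.
#' @export
water_population_table <- function() {
  data.frame(
    temperature = c(213, 243, 263),
    w1 = c(0.85, 0.45, 0.18),
    m1 = c(0.25, 0.27, 0.44),
    s1 = c(0.07, 0.07, 0.24),
    w2 = c(0.15, 0.55, 0.82),
    m2 = c(0.52, 0.74, 2.21),
    s2 = c(0.18, 0.43, 1.76)
  )
}

# Draw per-molecule D (in 1e-10 m^2/s) from the two-Gaussian mixture,
# truncated at zero per component (labels retained).
sample_mixture_D <- function(spec) {
  n <- spec$n_molecules
  comp <- 1L + (stats::runif(n) > spec$w1)
  mu <- ifelse(comp == 1L, spec$m1, spec$m2)
  sd <- ifelse(comp == 1L, spec$s1, spec$s2)
  d <- stats::rnorm(n, mu, sd)
  bad <- which(d < 0)
  while (length(bad)) {
    d[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[d[bad] < 0]
  }
  list(D = d, component = comp)
}

#' Generate synthetic water dynamics (diffusion samples or trajectories)
#'
#' In `"samples"` mode, per-molecule diffusion coefficients are drawn from
#' the two-Gaussian mixture, truncated at zero (redrawn within their
#' component), with component labels retained. In `"trajectories"` mode each
#' molecule follows a 3-D Brownian path with per-axis step variance
#' `2 * D * dt`, its `D` drawn from the same mixture.
#'
#' @param spec A [water_population_spec()].
#' @param mode `"samples"` or `"trajectories"`.
#' @return In samples mode a `diffusion_samples` object (`D` in 1e-10 m^2/s,
#'   `component`, `temperature`, `truth`); in trajectory mode a
#'   `trajectory_set` (`positions` array of dim n_frames x 3 x n_molecules in
#'   A, `frame_interval` in ps, per-molecule `D_true` in A^2/ps).
#' @export
#' @examples
#' sm <- generate_water_dynamics(water_population_spec(n_molecules = 500))
#' mean(sm$D)
generate_water_dynamics <- function(spec, mode = c("samples", "trajectories")) {
  stopifnot(inherits(spec, "water_population_spec"))
  mode <- match.arg(mode)
  if (mode == "samples") {
    drawn <- with_seed(spec$seed, sample_mixture_D(spec))
    return(structure(list(D = drawn$D, component = drawn$component,
                          temperature = spec$temperature, truth = spec),
                     class = "diffusion_samples"))
  }
  if (spec$n_frames < 10) {
    stop("trajectory mode needs n_frames >= 10", call. = FALSE)
  }
  with_seed(spec$seed, {
    drawn <- sample_mixture_D(spec)
    d_a2ps <- drawn$D / qens_constants$A2ps_to_1e10m2s   # A^2/ps
    nf <- spec$n_frames
    nm <- spec$n_molecules
    pos <- array(0, dim = c(nf, 3L, nm))
    step_sd <- sqrt(2 * d_a2ps * spec$frame_interval)    # per axis
    for (m in seq_len(nm)) {
      steps <- matrix(stats::rnorm((nf - 1L) * 3L, sd = step_sd[m]),
                      ncol = 3L)
      pos[, , m] <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    }
    structure(list(positions = pos, frame_interval = spec$frame_interval,
                   temperature = spec$temperature,
                   D_true = d_a2ps, component = drawn$component,
                   truth = spec),
              class = "trajectory_set")
  })
}

#' @export
print.diffusion_samples <- function(x, ...) {
  cat(sprintf("<diffusion_samples> %d molecules, T = %g K, mean D = %.3g x 1e-10 m^2/s\n",
              length(x$D), x$temperature, mean(x$D)))
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory_set> %d molecules, %d frames, dt = %g ps, T = %g K\n",
              d[3], d[1], x$frame_interval, x$temperature))
  invisible(x)
}
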