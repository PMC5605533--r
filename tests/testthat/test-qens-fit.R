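test_that("noiseless spectra round-trip through the spectral fit (<= 0.1%)", {
  res <- default_resolution()
  sets <- expand.grid(x = c(0.1, 0.3, 0.6, 0.85),
                      p = c(0.3, 0.65),
                      g1 = c(0.8, 2.5),
                      g2 = c(12, 35))
  sets <- sets[seq(1, nrow(sets), by = 3), ]   # 11 diverse parameter sets
  sets$amp <- seq(0.5, 3, length.out = nrow(sets))
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    tr <- qens_ground_truth(x = s$x, p = s$p, g1 = s$g1, g2 = s$g2,
                            amplitude = s$amp, noise = 0)
    sp <- generate_qens_spectrum(tr, q_grid = 0.7)
    ft <- suppressWarnings(fit_spectrum(sp, res, 2))$table
    expect_true(ft$converged)
    got <- c(ft$x, ft$p, ft$g1, ft$g2, ft$amplitude)
    want <- c(s$x, s$p, s$g1, s$g2, s$amp)
    expect_lt(max(abs(got - want) / want), 1e-3)
  }
})

test_that("a spectrum equal to the resolution is fitted as purely elastic", {
  tr <- qens_ground_truth(x = 1, g1 = 1, g2 = 10, noise = 0)
  sp <- generate_qens_spectrum(tr, q_grid = 0.5)
  ft <- suppressWarnings(fit_spectrum(sp, default_resolution(), 2))$table
  expect_gte(ft$x, 0.99)
  # quasielastic amplitude (1 - x) * amp consistent with zero
  expect_lt((1 - ft$x) * ft$amplitude, 1e-4)
})

test_that("the information criterion prefers two components when two exist", {
  tr <- qens_ground_truth(x = 0.3, p = 0.5, g1 = 1.5, g2 = 25, noise = 0.005,
                          seed = 3)
  sp <- generate_qens_spectrum(tr, q_grid = 0.7)
  res <- default_resolution()
  ft1 <- suppressWarnings(fit_spectrum(sp, res, 1))$table
  ft2 <- suppressWarnings(fit_spectrum(sp, res, 2))$table
  expect_lt(ft2$aicc, ft1$aicc)
})

test_that("non-convergence at one Q leaves other Q values intact", {
  tr <- qens_ground_truth(x = 0.5, g1 = 2, g2 = 20, noise = 0.01, seed = 2)
  sp <- generate_qens_spectrum(tr, q_grid = c(0.4, 0.8))
  # poison one Q with non-finite-safe but absurd uncertainties
  sp$sigma[, 1] <- 1e-300
  ft <- suppressWarnings(fit_spectrum(sp, default_resolution(), 2))$table
  expect_true(ft$converged[2])
  expect_lt(abs(ft$g1[2] - 2) / 2, 0.05)
})

test_that("susceptibility applies the Bose factor on the positive-energy side", {
  e <- e_grid_default(0.5)
  sp <- structure(list(Q = 0.5, E = e,
                       I = matrix(0, length(e), 1),
                       sigma = matrix(1, length(e), 1),
                       temperature = 250),
                  class = "qens_spectrum")
  chi0 <- compute_susceptibility(sp)
  expect_true(all(chi0$chi == 0))
  expect_true(all(chi0$E > 0 & chi0$E <= 100))
  # S = 1: direct Bose-factor evaluation at E = 21.543 ueV, T = 250 K
  sp$I[] <- 1
  chi <- compute_susceptibility(sp)
  i <- which.min(abs(chi$E - 21.543))
  kbt <- 86.173 * 250
  expect_equal(chi$chi[i, 1], exp(chi$E[i] / kbt) - 1, tolerance = 1e-12)
  expect_equal(exp(21.543 / kbt) - 1, 1.0005e-3, tolerance = 1e-4)
  # strictly increasing in E for constant S
  expect_true(all(diff(chi$chi[, 1]) > 0))
  sp$temperature <- -5
  expect_error(compute_susceptibility(sp), "temperature")
})

test_that("susceptibility maxima shift to higher energy with broader Lorentzians", {
  gammas <- c(1, 3, 10, 30)
  pos <- vapply(gammas, function(g) {
    tr <- qens_ground_truth(x = 0, p = 1, g1 = g, g2 = g, noise = 0,
                            temperature = 250)
    sp <- generate_qens_spectrum(tr, q_grid = 0.7, e_grid = e_grid_default(0.2))
    chi <- compute_susceptibility(sp)
    chi$E[which.max(chi$chi[, 1])]
  }, numeric(1))
  expect_true(all(diff(pos) > 0))
  # single maximum: chi rises then falls
  tr <- qens_ground_truth(x = 0, p = 1, g1 = 10, g2 = 10, noise = 0,
                          temperature = 250)
  sp <- generate_qens_spectrum(tr, q_grid = 0.7, e_grid = e_grid_default(0.2))
  chi <- compute_susceptibility(sp)$chi[, 1]
  imax <- which.max(chi)
  expect_true(all(diff(chi[1:imax]) > 0))
  expect_true(all(diff(chi[imax:length(chi)]) < 0))
})

test_that("msd_from_elastic inverts the Gaussian approximation", {
  qs <- seq(0.5, 0.9, 0.1)
  mk_scan <- function(sel) {
    structure(list(T = c(100, 150), Q = qs,
                   I = rbind(sel, sel), sigma = rbind(sel, sel) * 0 + 1e-6),
              class = "elastic_scan")
  }
  # immobile limit
  expect_equal(msd_from_elastic(mk_scan(rep(1, 5)), 100)$msd, 0,
               tolerance = 1e-12)
  # exact inversion of exp(-Q^2 * 1.2 / 3)
  got <- msd_from_elastic(mk_scan(exp(-qs^2 * 1.2 / 3)), 100)
  expect_equal(got$msd, 1.2, tolerance = 1e-9)
  # scale invariance (intercept absorbs the proportionality constant)
  got_scaled <- msd_from_elastic(mk_scan(7.3 * exp(-qs^2 * 1.2 / 3)), 100)
  expect_equal(got_scaled$msd, got$msd, tolerance = 1e-9)
  # identity with the md-module forward model to 1e-6
  for (msd_true in c(0.4, 1.7, 3.2)) {
    sel <- elastic_intensity_gaussian(msd_true, qs)
    expect_lt(abs(msd_from_elastic(mk_scan(sel), 100)$msd - msd_true), 1e-6)
  }
  expect_error(msd_from_elastic(mk_scan(c(-1, 1, 1, 1, 1)), 100),
               "non-positive")
})

test_that("segmented fitting matches the exhaustive brute-force oracle", {
  tt <- seq(100, 240, by = 10)  # 15 temperature points
  y0 <- 1 - 0.001 * (tt - 100) - 0.004 * pmax(tt - 160, 0) -
    0.008 * pmax(tt - 200, 0)
  set.seed(5)
  y <- y0 + rnorm(length(tt), sd = 0.004)
  scan <- structure(list(T = tt, Q = 0.9, I = matrix(y, ncol = 1),
                         sigma = matrix(0.004, length(tt), 1)),
                    class = "elastic_scan")
  det <- detect_transitions(scan)
  oracle <- segmented_bruteforce(tt, y / y[1])
  expect_equal(det$n_breakpoints, 2)
  expect_equal(det$transitions, sort(oracle$breaks))
})

test_that("detect_transitions enforces its preconditions", {
  sc <- generate_elastic_scan(T_grid = seq(100, 130, 5), noise = 0,
                              transition_temps = c(110, 120))
  expect_error(detect_transitions(sc), ">= 10 temperature points")
})
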