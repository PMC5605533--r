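test_that("pseudo-Voigt limits are pure Lorentzian / Gaussian with shared FWHM", {
  x <- seq(10, 20, by = 0.001)
  for (eta in c(0, 1)) {
    y <- pseudo_voigt(x, center = 15, fwhm = 1.4, eta = eta, amplitude = 3)
    above <- x[y > max(y) / 2]
    expect_equal(diff(range(above)), 1.4, tolerance = 0.01)
    expect_equal(max(y), 3, tolerance = 1e-9)
  }
  # eta = 1 is exactly Lorentzian
  y1 <- pseudo_voigt(x, 15, 1.4, 1, 1)
  expect_equal(y1, 1 / (1 + ((x - 15) / 0.7)^2), tolerance = 1e-12)
  expect_error(pseudo_voigt(x, 15, -1, 0.5), "fwhm")
  expect_error(pseudo_voigt(x, 15, 1, 1.5), "eta")
})

test_that("four-peak patterns round-trip through the simultaneous fit", {
  pat <- generate_xrd_pattern(noise = 0.01, seed = 6)
  fit <- fit_diffraction_peaks(pat)
  expect_true(fit$converged)
  truth <- default_cellulose_peaks()
  truth <- truth[order(truth$center), ]
  expect_lt(max(abs(fit$peaks$center - truth$center)), 0.05)
  expect_lt(max(abs(fit$peaks$fwhm_deg - truth$fwhm) / truth$fwhm), 0.05)
})

test_that("noiseless patterns round-trip to <= 0.1%", {
  pat <- generate_xrd_pattern(noise = 0)
  fit <- fit_diffraction_peaks(pat)
  truth <- default_cellulose_peaks()
  truth <- truth[order(truth$center), ]
  expect_lt(max(abs(fit$peaks$center - truth$center) / truth$center), 1e-3)
  expect_lt(max(abs(fit$peaks$fwhm_deg - truth$fwhm) / truth$fwhm), 1e-3)
  expect_lt(max(abs(fit$peaks$amplitude - truth$amplitude) / truth$amplitude),
            1e-3)
})

test_that("shape identification: a pure-Gaussian peak fits with eta < 0.05", {
  pk <- data.frame(center = 17, fwhm = 1.2, eta = 0, amplitude = 80)
  pat <- generate_xrd_pattern(peaks = pk, noise = 0.005, seed = 8)
  fit <- fit_diffraction_peaks(pat, initial_peaks = data.frame(
    center = 17.1, fwhm = 1.0, eta = 0.5, amplitude = 60))
  expect_lt(fit$peaks$eta, 0.05)
})

test_that("zero-amplitude peaks on a flat background fit to ~ zero amplitude", {
  pk <- data.frame(center = 17, fwhm = 1.2, eta = 0.5, amplitude = 0)
  pat <- generate_xrd_pattern(peaks = pk, background = c(10, 0), noise = 0.002,
                              seed = 9)
  fit <- fit_diffraction_peaks(pat, initial_peaks = data.frame(
    center = 17, fwhm = 1.2, eta = 0.5, amplitude = 1))
  # consistent with zero at the noise scale (background 10, 0.2% noise)
  expect_lt(fit$peaks$amplitude,
            3 * max(c(fit$peaks$amplitude_se, 0.05), na.rm = TRUE))
})

test_that("single-peak fitting matches a dense centre grid-search oracle", {
  pk <- data.frame(center = 16.43, fwhm = 1.3, eta = 0.5, amplitude = 50)
  pat <- generate_xrd_pattern(peaks = pk, noise = 0, two_theta_grid = seq(10, 24, 0.02))
  fit <- fit_diffraction_peaks(pat, initial_peaks = data.frame(
    center = 16.2, fwhm = 1.0, eta = 0.5, amplitude = 40))
  oracle <- pv_center_gridsearch(pat$two_theta, pat$counts, fwhm = 1.3,
                                 eta = 0.5, centers = seq(16.2, 16.6, 0.02))
  expect_lt(abs(fit$peaks$center - oracle$center), 0.02)  # one grid step
})

test_that("Bragg spacings follow lambda / (2 sin theta)", {
  expect_equal(bragg_spacing(22.9), 3.88, tolerance = 1e-2)
  expect_equal(bragg_spacing(14.8), 5.99, tolerance = 1e-2)
  expect_equal(bragg_spacing(180), 1.542 / 2, tolerance = 1e-12)
  tth <- seq(5, 175, 5)
  expect_true(all(diff(bragg_spacing(tth)) < 0))
  expect_error(bragg_spacing(0), "two_theta")
  expect_error(bragg_spacing(190), "two_theta")
})

test_that("Scherrer sizes convert widths correctly in both unit conventions", {
  expect_equal(scherrer_size(0.02832, two_theta = 22.9), 50.0, tolerance = 1e-3)
  # degrees are converted to radians internally (classic failure mode)
  expect_equal(scherrer_size(0.02832 * 180 / pi, two_theta = 22.9,
                             fwhm_unit = "degrees"),
               scherrer_size(0.02832, two_theta = 22.9), tolerance = 1e-12)
  # inverse proportionality
  expect_equal(scherrer_size(2 * 0.02832, two_theta = 22.9),
               scherrer_size(0.02832, two_theta = 22.9) / 2, tolerance = 1e-12)
  # identity: L -> beta -> L to 1e-9
  for (L in c(30, 50, 120)) {
    beta <- 0.9 * 1.542 / (L * cos(22.9 / 2 * pi / 180))
    expect_lt(abs(scherrer_size(beta, two_theta = 22.9) - L), 1e-9)
  }
  expect_error(scherrer_size(-0.01, two_theta = 22.9), "FWHM")
})

test_that("the default (110) width reproduces a 50 A crystallite", {
  pat <- generate_xrd_pattern(noise = 0.01, seed = 10)
  fit <- fit_diffraction_peaks(pat)
  pk110 <- fit$peaks[fit$peaks$hkl == "110", ]
  L <- scherrer_size(pk110, wavelength = pat$wavelength)
  expect_lt(abs(L - 50), 1)
})

test_that("interfibrillar gap arithmetic and propagation", {
  expect_equal(interfibril_gap(67, 50)$gap, 17)
  expect_equal(interfibril_gap(50, 50)$gap, 0)
  g <- interfibril_gap(67.0, 50, d_se = 0.6, L_se = 1)
  expect_equal(g$gap_se, sqrt(0.6^2 + 1^2), tolerance = 1e-9)
  expect_equal(g$gap_se, 1.17, tolerance = 1e-2)
  expect_error(interfibril_gap(45, 50), "inconsistent")
})

test_that("pattern generation validates its inputs", {
  expect_error(generate_xrd_pattern(two_theta_grid = seq(2, 40, 0.05)),
               "5-90")
  pk <- data.frame(center = 50, fwhm = 1, eta = 0.5, amplitude = 1)
  expect_error(generate_xrd_pattern(peaks = pk,
                                    two_theta_grid = seq(5, 40, 0.05)),
               "inside")
})
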