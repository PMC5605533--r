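test_that("flat-limit profiles generate and fit to alpha ~ 0", {
  pr <- generate_sans_profile(P = 1, alpha = 0, B = 0, noise = 0)
  expect_true(all(abs(pr$I - 1) < 1e-12))
  pl <- fit_power_law(pr)
  # alpha ~ 0: the flat limit is parameter-degenerate ((P Q)^0 and B trade
  # off), so only closeness to zero is meaningful
  expect_lt(pl$alpha, 0.1)
  expect_lt(max(abs(pl$model(pr$Q) - 1)), 1e-6)
})

test_that("noiseless power laws round-trip (<= 0.1%) and match the log-log oracle", {
  sets <- data.frame(P = c(2.4, 1.1, 5, 0.8, 3.2),
                     alpha = c(3.20, 3.55, 2.5, 4.0, 1.8),
                     B = c(0.5, 0, 0.2, 1.0, 0))
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    pr <- generate_sans_profile(P = s$P, alpha = s$alpha, B = s$B, noise = 0)
    pl <- fit_power_law(pr)
    expect_lt(abs(pl$alpha - s$alpha) / s$alpha, 1e-3)
    expect_lt(abs(pl$P - s$P) / s$P, 1e-3)
    if (s$B == 0) {
      # independent slope oracle on the background-free curve
      slope <- -coef(lm(log(pr$I) ~ log(pr$Q)))[[2]]
      expect_lt(abs(pl$alpha - slope), 1e-3)
    }
  }
})

test_that("noiseless alpha = 3.20 recovery reaches 1e-4", {
  pr <- generate_sans_profile(P = 2.4, alpha = 3.20, B = 0.5, noise = 0)
  pl <- fit_power_law(pr)
  expect_lt(abs(pl$alpha - 3.20), 1e-4)
})

test_that("the power-law fit is scale-equivariant in the intensity", {
  pr <- generate_sans_profile(P = 2.4, alpha = 3.2, B = 0.5, noise = 0.01,
                              seed = 9)
  pl1 <- fit_power_law(pr)
  pr2 <- pr
  pr2$I <- pr2$I * 100
  pr2$sigma <- pr2$sigma * 100
  pl2 <- fit_power_law(pr2)
  expect_equal(pl2$alpha, pl1$alpha, tolerance = 1e-8)
})

test_that("the correlation peak evaluates to 2A/(pi w) at its centre", {
  expect_equal(correlation_peak_curve(0.094, A = 1, w = 0.04, center = 0.094),
               2 / (pi * 0.04), tolerance = 1e-12)
  expect_equal(2 / (pi * 0.04), 15.915, tolerance = 1e-4)
  pr <- generate_sans_profile(peak = list(A = 1, w = 0.04, center = 0.094),
                              power_law = FALSE, B = 0, noise = 0)
  expect_equal(max(pr$I), 2 / (pi * 0.04), tolerance = 1e-3)
  expect_lt(abs(pr$Q[which.max(pr$I)] - 0.094), 0.002)  # nearest grid point
})

test_that("peak-only noiseless profiles round-trip through the peak fit", {
  pr <- generate_sans_profile(peak = list(A = 1, w = 0.04, center = 0.094),
                              power_law = FALSE, B = 0, noise = 0)
  cp <- fit_correlation_peak(pr, powerlaw = NULL, offset = FALSE)
  expect_true(cp$peak_found)
  expect_lt(abs(cp$center - 0.094), 1e-6)
  expect_lt(abs(cp$w - 0.04) / 0.04, 1e-3)
  expect_lt(abs(cp$A - 1), 1e-3)
})

test_that("hydrated-type profiles yield the correlation peak after subtraction", {
  pr <- generate_sans_profile(P = 2.4, alpha = 3.55, B = 0.5,
                              peak = list(A = 1, w = 0.04, center = 0.094),
                              noise = 0)
  pl <- fit_power_law(pr, q_range = c(0, 0.08))
  cp <- fit_correlation_peak(pr, pl)
  expect_true(cp$peak_found)
  expect_lt(abs(cp$center - 0.094), 0.001)
})

test_that("dry-type profiles are flagged as peak-free, not an error", {
  pr <- generate_sans_profile(P = 2.4, alpha = 3.20, B = 0.5, noise = 0.01,
                              seed = 2, label = "dry")
  pl <- fit_power_law(pr, q_range = c(0, 0.08))
  cp <- fit_correlation_peak(pr, pl)
  expect_false(cp$peak_found)
  expect_true(is.na(cp$center))
})

test_that("peak-centre recovery bias stays below half a grid step over 20 seeds", {
  centers <- vapply(1:20, function(s) {
    pr <- generate_sans_profile(P = 2.4, alpha = 3.55, B = 0.5,
                                peak = list(A = 1, w = 0.04, center = 0.094),
                                noise = 0.01, seed = s)
    pl <- fit_power_law(pr, q_range = c(0, 0.08))
    fit_correlation_peak(pr, pl)$center
  }, numeric(1))
  grid_step <- 0.094 * (log(0.4 / 0.003) / 249)  # local log-grid spacing
  expect_lt(abs(mean(centers) - 0.094), 0.5 * grid_step)
})

test_that("peak positions convert to repeat distances via d = 2 pi / Q", {
  got <- peak_to_distance(0.094, 0.001)
  expect_equal(got$d, 2 * pi / 0.094, tolerance = 1e-12)
  expect_lt(abs(got$d - 67.0), 0.6 + 0.05)   # printed value & uncertainty
  expect_equal(got$d_se, got$d * 0.001 / 0.094, tolerance = 1e-12)
  expect_equal(peak_to_distance(2 * pi)$d, 1, tolerance = 1e-12)
  expect_equal(peak_to_distance(0.1)$d, 62.83, tolerance = 1e-4)
  # inverse-pair identity
  for (d in c(10, 67, 150)) {
    expect_equal(peak_to_distance(2 * pi / d)$d, d, tolerance = 1e-9)
  }
  expect_error(peak_to_distance(0), "center")
})

test_that("profile generation rejects non-positive Q grids", {
  expect_error(generate_sans_profile(q_grid = c(-0.01, 0.1, 0.2)),
               "positive")
})

test_that("pre-subtraction background mode fits the exponent too", {
  pr <- generate_sans_profile(P = 2.4, alpha = 3.2, B = 0.8, noise = 0.005,
                              seed = 4)
  pl <- suppressWarnings(fit_power_law(pr, background = "pre-subtract"))
  expect_lt(abs(pl$alpha - 3.2), 0.05)
})
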