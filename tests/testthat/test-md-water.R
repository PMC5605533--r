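make_traj <- function(positions, dt = 2, temperature = 250) {
  structure(list(positions = positions, frame_interval = dt,
                 temperature = temperature, D_true = NULL, component = NULL,
                 truth = NULL),
            class = "trajectory_set")
}

test_that("MSD is zero for static molecules and v^2 t^2 for linear drift", {
  pos <- array(5, dim = c(50, 3, 4))
  msd <- compute_msd(make_traj(pos), lags = c(10, 40))
  expect_true(all(msd$msd == 0))
  # ballistic: r = v t with |v| = 0.3 A/ps along x
  nf <- 60; dt <- 2
  pos2 <- array(0, dim = c(nf, 3, 2))
  pos2[, 1, ] <- 0.3 * (seq_len(nf) - 1) * dt
  lags <- c(20, 60, 100)
  msd2 <- compute_msd(make_traj(pos2, dt = dt), lags = lags)
  expect_equal(msd2$msd, (0.3 * lags)^2, tolerance = 1e-12)
})

test_that("vectorised MSD equals the brute-force double-loop oracle exactly", {
  spec <- water_population_spec(n_molecules = 5, n_frames = 20, seed = 12)
  traj <- generate_water_dynamics(spec, mode = "trajectories")
  lags_f <- c(1, 3, 7)
  got <- compute_msd(traj, lags = lags_f * traj$frame_interval)
  want <- msd_bruteforce(traj$positions, lags_f)
  expect_equal(got$per_molecule, want, tolerance = 1e-12)
  expect_equal(got$msd, rowMeans(want), tolerance = 1e-12)
})

test_that("Brownian trajectories obey the Einstein relation at 800 ps", {
  spec <- water_population_spec(w1 = 1 - 1e-12, m1 = 1, s1 = 1e-6,
                                w2 = 1e-12, m2 = 1, s2 = 1e-6,
                                n_molecules = 400, n_frames = 501, seed = 3)
  traj <- generate_water_dynamics(spec, mode = "trajectories")  # D = 0.01 A^2/ps
  msd <- compute_msd(traj, lags = 800)
  se <- sd(msd$per_molecule[1, ]) / sqrt(400)
  expect_lt(abs(msd$msd - 48), 3 * se)
})

test_that("sample mode reproduces the analytic mixture mean and converges ~ n^-1/2", {
  mix_mean <- 0.85 * 0.25 + 0.15 * 0.52
  expect_equal(mix_mean, 0.2905, tolerance = 1e-12)
  spec <- water_population_spec(n_molecules = 1e5, seed = 1)
  sm <- generate_water_dynamics(spec)
  mix_sd <- sqrt(0.85 * (0.07^2 + 0.25^2) + 0.15 * (0.18^2 + 0.52^2) -
                   mix_mean^2)
  expect_lt(abs(mean(sm$D) - mix_mean), 3 * mix_sd / sqrt(1e5))
  # error shrinks roughly as n^(-1/2) across three decades
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    s <- water_population_spec(n_molecules = n, seed = 17)
    abs(mean(generate_water_dynamics(s)$D) - mix_mean)
  }, numeric(1))
  expect_true(all(errs < 4 * mix_sd / sqrt(c(1e3, 1e4, 1e5))))
})

test_that("generation is reproducible and validates weights", {
  spec <- water_population_spec(n_molecules = 200, seed = 5)
  a <- generate_water_dynamics(spec)
  b <- generate_water_dynamics(spec)
  expect_identical(a$D, b$D)
  expect_error(water_population_spec(w1 = 0.6, w2 = 0.5), "must equal 1")
  expect_error(water_population_spec(s1 = 0), "sigma")
  expect_true(all(generate_water_dynamics(
    water_population_spec(n_molecules = 5000, seed = 2))$D >= 0))
})

test_that("per-molecule diffusion recovers a single population with units", {
  # D = 0.005 A^2/ps = 0.5 x 1e-10 m^2/s
  spec <- water_population_spec(w1 = 1 - 1e-12, m1 = 0.5, s1 = 1e-6,
                                w2 = 1e-12, m2 = 0.5, s2 = 1e-6,
                                n_molecules = 300, n_frames = 1001, seed = 21)
  traj <- generate_water_dynamics(spec, mode = "trajectories")
  ds <- per_molecule_diffusion(traj, window = c(10, 400))
  se <- sd(ds$D) / sqrt(length(ds$D))
  expect_lt(abs(mean(ds$D) - 0.5), 3 * se)
  expect_error(per_molecule_diffusion(traj, window = c(10, 5000)), "span")
})

test_that("ballistic trajectories raise the nonlinear-MSD flag", {
  nf <- 201; dt <- 2
  pos <- array(0, dim = c(nf, 3, 3))
  pos[, 1, ] <- 0.1 * ((seq_len(nf) - 1) * dt)
  ds <- per_molecule_diffusion(make_traj(pos, dt = dt), window = c(10, 200))
  expect_true(all(ds$nonlinear))  # MSD ~ t^2: pure curvature
  spec <- water_population_spec(w1 = 1 - 1e-12, m1 = 0.5, s1 = 1e-6,
                                w2 = 1e-12, m2 = 0.5, s2 = 1e-6,
                                n_molecules = 40, n_frames = 201, seed = 33)
  traj_diff <- generate_water_dynamics(spec, mode = "trajectories")
  ds_diff <- per_molecule_diffusion(traj_diff, window = c(10, 200))
  expect_lt(mean(ds_diff$nonlinear), 0.9)  # genuine diffusion mostly unflagged
})

test_that("mixture fits recover the slow-population weight at n = 1000", {
  spec <- water_population_spec(n_molecules = 1000, temperature = 213, seed = 1)
  sm <- generate_water_dynamics(spec)
  mf <- fit_bimodal_gaussian(sm)
  expect_lt(abs(mf$w1 - 0.85), 0.05)
  expect_lt(abs(mf$m1 - 0.25), 0.03)
})

test_that("mixture parameters are consistent at large n", {
  tab <- water_population_table()
  row <- tab[tab$temperature == 243, ]
  spec <- water_population_spec(w1 = row$w1, m1 = row$m1, s1 = row$s1,
                                w2 = row$w2, m2 = row$m2, s2 = row$s2,
                                n_molecules = 2e4, temperature = 243, seed = 7)
  mf <- fit_bimodal_gaussian(generate_water_dynamics(spec))
  expect_lt(abs(mf$w1 - row$w1), 0.03)
  expect_lt(abs(mf$m1 - row$m1), 0.03)
  expect_lt(abs(mf$m2 - row$m2), 0.05)
  expect_lt(abs(mf$s1 - row$s1), 0.03)
  expect_lt(abs(mf$s2 - row$s2), 0.05)
})

test_that("single-Gaussian samples fitted with two components are flagged", {
  d <- cellwater:::with_seed(101L, rnorm(2000, 1.2, 0.3))
  mf <- fit_bimodal_gaussian(d, truncated = FALSE)
  expect_true(max(mf$w1, mf$w2) >= 0.95 || mf$degenerate || mf$prefers_single)
})

test_that("identical samples degenerate to a flagged single component", {
  d <- rep(0.5, 200) + cellwater:::with_seed(1L, rnorm(200, 0, 1e-12))
  mf <- fit_bimodal_gaussian(d, truncated = FALSE)
  expect_true(mf$degenerate)
})

test_that("histogram-mode fitting mirrors the sample-mode decomposition", {
  spec <- water_population_spec(n_molecules = 5000, seed = 19)
  sm <- generate_water_dynamics(spec)
  mf_h <- fit_bimodal_gaussian(sm, method = "histogram")
  expect_lt(abs(mf_h$w1 - 0.85), 0.08)
  expect_lt(abs(mf_h$m1 - 0.25), 0.05)
})

test_that("the EM decomposition agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  spec <- water_population_spec(n_molecules = 3000, seed = 23)
  sm <- generate_water_dynamics(spec)
  mf <- fit_bimodal_gaussian(sm, truncated = FALSE)
  mc <- mclust::Mclust(sm$D, G = 2, modelNames = "V", verbose = FALSE)
  mc_means <- sort(mc$parameters$mean)
  expect_lt(abs(mf$m1 - mc_means[1]), 0.02)
  expect_lt(abs(mf$m2 - mc_means[2]), 0.05)
  w_slow_mc <- mc$parameters$pro[which.min(mc$parameters$mean)]
  expect_lt(abs(mf$w1 - w_slow_mc), 0.03)
})

test_that("trajectory-derived diffusion coefficients reproduce the weights", {
  spec <- water_population_spec(n_molecules = 1000, n_frames = 2500,
                                temperature = 213, seed = 5)
  traj <- generate_water_dynamics(spec, mode = "trajectories")
  ds <- per_molecule_diffusion(traj)
  mf <- fit_bimodal_gaussian(ds)
  expect_lt(abs(mf$w1 - 0.85), 0.08)
})

test_that("slow-population weights stay ordered across the temperature series", {
  tab <- water_population_table()
  w_hat <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    spec <- water_population_spec(w1 = r$w1, m1 = r$m1, s1 = r$s1,
                                  w2 = r$w2, m2 = r$m2, s2 = r$s2,
                                  n_molecules = 1000,
                                  temperature = r$temperature, seed = 40 + i)
    fit_bimodal_gaussian(generate_water_dynamics(spec))$w1
  }, numeric(1))
  expect_true(all(diff(w_hat) < 0))  # 0.85 -> 0.45 -> 0.18 ordering preserved
})
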